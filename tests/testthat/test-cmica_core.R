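test_that("temporal normalization centers, scales and flags dead voxels", {
  expect_equal(as.numeric(temporal_normalize(matrix(c(1, 2, 3)))),
               c(-1, 0, 1))

  expect_warning(out <- temporal_normalize(matrix(c(5, 5, 5))),
                 "zero-variance")
  expect_equal(as.numeric(out), c(0, 0, 0))
  expect_equal(attr(out, "zero_variance"), 1L)

  withr::with_seed(1, {
    x <- matrix(rnorm(50 * 20), 50)
    xn <- temporal_normalize(x)
    expect_lt(max(abs(colMeans(xn))), 1e-12)
    expect_lt(max(abs(apply(xn, 2, sd) - 1)), 1e-12)
  })

  expect_error(temporal_normalize(matrix(1, 1, 3)), "2 timepoints")
})

test_that("explicit FC matrix matches brute-force pairwise correlation", {
  withr::with_seed(2, {
    x <- matrix(rnorm(50 * 5), 50)
    xn <- temporal_normalize(x)
    cm <- explicit_fc_matrix(xn)
    oracle <- cor(x)     # independent pairwise-correlation computation
    expect_equal(cm, oracle, tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(abs(diag(cm) - 1) < 1e-12))
    expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))
  })

  # identical columns -> off-diagonal 1; orthogonal zero-mean columns -> 0
  a <- temporal_normalize(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(explicit_fc_matrix(a)[1, 2], 1)
  b <- temporal_normalize(cbind(c(1, -1, 1, -1), c(1, 1, -1, -1)))
  expect_equal(explicit_fc_matrix(b)[1, 2], 0)

  expect_error(explicit_fc_matrix(matrix(rnorm(20), 5)), "not temporally")
})

test_that("FC reduction reproduces the eigen-truncated correlation matrix", {
  withr::with_seed(3, {
    x <- matrix(rnorm(60 * 100), 60)
    xn <- temporal_normalize(x)
    r <- 10
    red <- reduce_subject_fc(xn, r)
    expect_equal(red$n_samples, 60)
    expect_lt(max(abs(crossprod(red$basis_u) - diag(r))), 1e-8)
    expect_true(all(diff(red$sing_vals) <= 1e-10))

    # oracle: eigendecomposition of the explicit correlation matrix
    cm <- explicit_fc_matrix(xn)
    e <- eigen(cm, symmetric = TRUE)
    oracle <- e$vectors[, 1:r] %*% (e$values[1:r] * t(e$vectors[, 1:r]))
    shortcut <- red$basis_u %*% (red$sing_vals^2 / (60 - 1) * t(red$basis_u))
    expect_lt(norm(shortcut - oracle, "F") / norm(oracle, "F"), 1e-8)
  })
})

test_that("full-rank FC reduction reconstructs the data", {
  withr::with_seed(4, {
    x <- matrix(rnorm(20 * 12), 20)
    xn <- temporal_normalize(x)
    r <- min(19, 12)
    red <- reduce_subject_fc(xn, r)
    recon <- red$basis_v %*% (red$sing_vals * t(red$basis_u))
    expect_lt(norm(recon - xn, "F") / norm(xn, "F"), 1e-10)
  })
  expect_error(reduce_subject_fc(temporal_normalize(matrix(rnorm(40), 10)),
                                 r = 20), "r must be")
})

test_that("rank-1 input yields a single surviving singular value", {
  withr::with_seed(5, {
    tau <- rnorm(40)
    m <- runif(15)
    xn <- temporal_normalize(tau %o% m)
    red <- reduce_subject_fc(xn, 5)
    expect_gt(red$sing_vals[1], 1e-8)
    expect_lt(max(red$sing_vals[-1]), 1e-8)
  })
})

test_that("SC reduction matches a dense SVD oracle and handles transforms", {
  withr::with_seed(6, {
    m0 <- matrix(rpois(40 * 25, 0.8), 40)
    red <- reduce_subject_sc(m0, r = 5)
    sv <- svd(m0)   # independent dense SVD
    expect_equal(red$sing_vals, sv$d[1:5], tolerance = 1e-8)
    for (j in 1:5) {
      expect_equal(abs(sum(red$basis_u[, j] * sv$u[, j])), 1,
                   tolerance = 1e-8)
    }
  })

  # rank-1 count matrix a b' -> dominant singular vector proportional to a
  a <- c(4, 0, 2, 1)
  b <- c(1, 3, 0, 0, 2)
  red1 <- reduce_subject_sc(a %o% b, r = 2)
  expect_lt(red1$sing_vals[2] / red1$sing_vals[1], 1e-12)
  expect_equal(abs(cor(red1$basis_u[, 1], a)), 1, tolerance = 1e-10)

  # all-zero matrix is degenerate under log1p
  red0 <- reduce_subject_sc(matrix(0, 4, 5), r = 2, transform = "log1p")
  expect_true(red0$degenerate)
  expect_true(all(red0$sing_vals == 0))
  expect_true(all(red0$basis_u == 0))

  expect_error(reduce_subject_sc(matrix(-1, 2, 2), r = 1), "nonnegative")
  expect_error(reduce_subject_sc(matrix(1, 2, 2), r = 5), "r must be")
})

test_that("scaling all counts scales singular values, not the spatial basis", {
  withr::with_seed(7, {
    m0 <- matrix(rpois(30 * 20, 1), 30)
    r1 <- reduce_subject_sc(m0, r = 4)
    r2 <- reduce_subject_sc(7 * m0, r = 4)
    expect_equal(r2$sing_vals, 7 * r1$sing_vals, tolerance = 1e-10)
    expect_equal(abs(r2$basis_u), abs(r1$basis_u), tolerance = 1e-8)
  })
})

test_that("identity-demixing bypass returns the raw PCA factors", {
  withr::with_seed(8, {
    xn <- temporal_normalize(matrix(rnorm(50 * 30), 50))
    red <- reduce_subject_fc(xn, 6)
    dec <- single_subject_cmica(red, c = 4, algorithm = "identity")
    expect_identical(dec$S, t(red$basis_u[, 1:4]))
    expect_equal(dec$R,
                 red$basis_u[, 1:4] %*% diag(red$sing_vals[1:4]^2) / 49,
                 tolerance = 1e-12)
  })
})

test_that("R.S reproduces the rank-c truncated connectivity matrix", {
  withr::with_seed(9, {
    xn <- temporal_normalize(matrix(rnorm(80 * 60), 80))
    red <- reduce_subject_fc(xn, 10)
    for (cc in c(3, 7, 10)) {
      dec <- single_subject_cmica(red, c = cc, seed = 2)
      oracle <- truncated_connectivity(red, cc)
      expect_lt(norm(dec$R %*% dec$S - oracle, "F") / norm(oracle, "F"),
                1e-6)
    }
    # SC branch too
    m0 <- matrix(rpois(60 * 40, 1.2), 60)
    red_sc <- reduce_subject_sc(m0, r = 6)
    dec_sc <- single_subject_cmica(red_sc, c = 4, seed = 2)
    oracle_sc <- truncated_connectivity(red_sc, 4)
    expect_lt(norm(dec_sc$R %*% dec_sc$S - oracle_sc, "F") /
                norm(oracle_sc, "F"), 1e-6)
  })
})

test_that("noiseless synthetic subject recovers the planted sources", {
  truth <- make_ground_truth(grid_gm = c(12, 12, 4), grid_wm = c(8, 8, 4),
                             k_shared = 3, k_fc_only = 0, k_sc_only = 0,
                             n_subj = 1, seed = 21)
  sub <- simulate_subject_fmri(truth, 1, t_len = 200, noise_sd = 0)
  xn <- suppressWarnings(temporal_normalize(sub$data))
  red <- reduce_subject_fc(xn, r = 3)
  dec <- single_subject_cmica(red, c = 3, seed = 4)
  # temporal normalization rescales every voxel to unit variance, so the
  # recoverable maps are the planted maps divided by each voxel's
  # time-course sd (the normalized-space mixing)
  w <- truth$subject_strengths[1, as.integer(rownames(truth$M_fc))]
  m_w <- w * truth$M_fc
  m_eff <- sweep(m_w, 2, pmax(sqrt(colSums(m_w^2)), 1e-12), `/`)
  al <- align_components(dec$S, m_eff)
  expect_true(all(al$correlations > 0.99))
})

test_that("shortcut and explicit-matrix ICA routes agree", {
  withr::with_seed(10, {
    truth <- make_ground_truth(grid_gm = c(8, 8, 3), grid_wm = c(6, 6, 3),
                               k_shared = 3, k_fc_only = 0, k_sc_only = 0,
                               n_subj = 1, seed = 22)
    sub <- simulate_subject_fmri(truth, 1, t_len = 150, noise_sd = 0.2)
    xn <- temporal_normalize(sub$data)
    cc <- 3
    red <- reduce_subject_fc(xn, r = cc)
    dec <- single_subject_cmica(red, c = cc, seed = 17)

    # explicit route: build the correlation matrix, PCA, same-seeded ICA
    cm <- explicit_fc_matrix(xn)
    e <- eigen(cm, symmetric = TRUE)
    u_exp <- e$vectors[, 1:cc, drop = FALSE]
    u_exp <- sweep(u_exp, 2, vapply(seq_len(cc), function(j) {
      i <- which.max(abs(u_exp[, j])); if (u_exp[i, j] < 0) -1 else 1
    }, numeric(1)), `*`)
    v <- nrow(u_exp)
    run <- run_ica(sqrt(v) * t(u_exp), seed = 17)
    s_explicit <- run$demix_w %*% (sqrt(v) * t(u_exp))

    al <- align_components(dec$S, s_explicit)
    expect_true(all(al$correlations > 0.999))

    # matching subspaces: principal angles below 1e-6 rad
    qa <- qr.Q(qr(t(dec$S)))
    qb <- qr.Q(qr(t(s_explicit)))
    cos_angles <- svd(crossprod(qa, qb))$d
    expect_lt(max(acos(pmin(1, cos_angles))), 1e-6)
  })
})
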