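# Small fixtures shared across test files; everything is generated in code.

# compact ground truth + cohort for fast pipeline tests
small_truth <- function(seed = 5, n_subj = 4) {
  make_ground_truth(grid_gm = c(12, 12, 4), grid_wm = c(8, 8, 4),
                    k_shared = 3, k_fc_only = 1, k_sc_only = 1,
                    n_subj = n_subj, seed = seed)
}

# the standard study-condition cohort: 12x12x6 GM, 10x10x6 WM,
# 4 shared + 2 FC-only + 2 SC-only, 10 subjects, T = 300
default_truth <- function(seed = 1) {
  make_ground_truth(seed = seed)
}

fit_default <- function(truth, seed = truth$seed, icasso_runs = 5,
                        t_len = 300) {
  coh <- simulate_cohort(truth, t_len = t_len)
  fit_joint_cmica(coh$fmri, coh$sc, subject_r = 4, m_per_modality = 4,
                  icasso_runs = icasso_runs, seed = seed)
}

# random whitened matrix: rows exactly orthonormal scaled to ZZ'/m = I
random_whitened <- function(c_dim, m, seed = 1) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(m * c_dim), m, c_dim)))
    sqrt(m) * t(q)
  })
}

# mix sparse super-Gaussian sources and whiten; returns list(z, sources)
whitened_mixture <- function(c_dim = 4, m = 1500, seed = 1) {
  withr::with_seed(seed, {
    s <- matrix(0, c_dim, m)
    for (j in seq_len(c_dim)) {
      idx <- ((j - 1) * floor(m / c_dim) + 1):(j * floor(m / c_dim))
      s[j, idx] <- abs(rnorm(length(idx))) + 0.5
    }
    a <- matrix(rnorm(c_dim^2), c_dim) + diag(c_dim)
    x <- a %*% s
    e <- eigen(tcrossprod(x) / m, symmetric = TRUE)
    z <- (t(e$vectors) / sqrt(e$values)) %*% x
    list(z = z, sources = s, mixing = a)
  })
}
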