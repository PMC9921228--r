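#' ICA unmixing, stability reruns and component alignment
#'
#' The default unmixing algorithm is Infomax with natural-gradient updates
#' and a logistic nonlinearity (with bias term), suited to the
#' super-Gaussian, sparse spatial sources this pipeline extracts; a
#' deflationary fastICA (tanh contrast) is available behind a flag. Runs are
#' deterministic given a seed. Stability analysis reruns ICA with derived
#' seeds, clusters components across runs by absolute similarity
#' (minimum-spanning-tree/single linkage), scores each cluster's
#' compactness, and picks the run closest to the cluster exemplars.
#'
#' @name ica-engine
NULL

check_whitened <- function(z, tol = 1e-6) {
  m <- ncol(z)
  gram <- tcrossprod(z) / m
  dev <- max(abs(gram - diag(nrow(z))))
  if (dev > tol) {
    stop("input is not whitened: max |ZZ'/m - I| = ", signif(dev, 3),
         " exceeds ", tol, call. = FALSE)
  }
  invisible(dev)
}

# Symmetric decorrelation: W <- (W W')^{-1/2} W. For whitened input this
# makes the source rows exactly orthogonal, pinning the stability index's
# degenerate case and making run-to-run similarity well defined.
sym_decorrelate <- function(w) {
  e <- eigen(tcrossprod(w), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% (t(e$vectors) / sqrt(vals)) %*% w
}

infomax_ica <- function(z, seed, max_iter, tol, lrate = NULL) {
  c_dim <- nrow(z)
  m <- ncol(z)
  if (is.null(lrate)) lrate <- 0.015 / log(c_dim + 2)
  withr::with_seed(seed, {
    w <- qr.Q(qr(matrix(stats::rnorm(c_dim^2), c_dim)))
    bias <- rep(0, c_dim)
    converged <- FALSE
    iter <- 0L
    w0 <- w
    while (iter < max_iter) {
      iter <- iter + 1L
      u <- w %*% z + bias
      y <- 1 / (1 + exp(-u))
      grad <- (diag(c_dim) + ((1 - 2 * y) %*% t(u)) / m)
      dw <- lrate * grad %*% w
      dbias <- lrate * rowSums(1 - 2 * y) / m
      if (!all(is.finite(dw)) || max(abs(dw)) > 1e6) {
        # blowup: anneal and restart from the seeded initial point
        lrate <- lrate * 0.5
        w <- w0
        bias <- rep(0, c_dim)
        next
      }
      w <- w + dw
      bias <- bias + dbias
      wchange <- sqrt(sum(dw^2)) / sqrt(sum(w^2))
      if (wchange < tol) { converged <- TRUE; break }
    }
    list(w = w, converged = converged, n_iter = iter)
  })
}

fastica_deflation <- function(z, seed, max_iter, tol) {
  c_dim <- nrow(z)
  m <- ncol(z)
  withr::with_seed(seed, {
    w_all <- matrix(0, c_dim, c_dim)
    total_iter <- 0L
    converged <- TRUE
    for (p in seq_len(c_dim)) {
      w <- stats::rnorm(c_dim)
      w <- w / sqrt(sum(w^2))
      ok <- FALSE
      for (it in seq_len(max_iter)) {
        total_iter <- total_iter + 1L
        wx <- drop(crossprod(w, z))
        g <- tanh(wx)
        gp <- 1 - g^2
        w_new <- (z %*% g) / m - mean(gp) * w
        if (p > 1) {
          prev <- w_all[seq_len(p - 1), , drop = FALSE]
          w_new <- w_new - t(prev) %*% (prev %*% w_new)
        }
        w_new <- w_new / sqrt(sum(w_new^2))
        if (abs(abs(sum(w_new * w)) - 1) < tol) {
          w <- drop(w_new); ok <- TRUE; break
        }
        w <- drop(w_new)
      }
      if (!ok) converged <- FALSE
      w_all[p, ] <- w
    }
    list(w = w_all, converged = converged, n_iter = total_iter)
  })
}

#' Run one ICA decomposition on whitened data
#'
#' @param whitened c x m matrix whose rows are uncorrelated with unit
#'   variance (`ZZ'/m = I` within `white_tol`).
#' @param seed seed determining the random initial unmixing matrix.
#' @param max_iter iteration cap.
#' @param tol relative weight-change convergence tolerance.
#' @param algorithm `"infomax"` (natural gradient, logistic nonlinearity,
#'   bias term) or `"fastica"` (deflationary, tanh contrast).
#' @param white_tol tolerance for the whiteness contract check.
#' @return Object of class `ica_run`: `demix_w` (c x c, finished with a
#'   symmetric decorrelation so source rows are exactly orthogonal),
#'   `sources` (c x m, unit variance rows), `converged`, `n_iter`, `seed`.
#' @export
run_ica <- function(whitened, seed = 1, max_iter = 2000, tol = 1e-6,
                    algorithm = c("infomax", "fastica"), white_tol = 1e-6) {
  algorithm <- match.arg(algorithm)
  z <- as.matrix(whitened)
  check_whitened(z, white_tol)
  fit <- switch(algorithm,
    infomax = infomax_ica(z, seed, max_iter, tol),
    fastica = fastica_deflation(z, seed, max_iter, tol)
  )
  w <- sym_decorrelate(fit$w)
  s <- w %*% z
  # unit-variance scaling convention (rows already have unit uncentered
  # second moment for whitened input and orthogonal w)
  structure(
    list(demix_w = w, sources = s, converged = fit$converged,
         n_iter = fit$n_iter, seed = seed, algorithm = algorithm),
    class = "ica_run"
  )
}

#' @export
print.ica_run <- function(x, ...) {
  cat("<ica_run>", x$algorithm, "|", nrow(x$sources), "components |",
      if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations\n")
  invisible(x)
}

# |uncentered cosine| similarity between rows of a and rows of b
abs_cosine <- function(a, b = a) {
  an <- a / sqrt(rowSums(a^2))
  bn <- b / sqrt(rowSums(b^2))
  abs(tcrossprod(an, bn))
}

#' ICASSO-style stability analysis
#'
#' Reruns ICA `n_runs` times with seeds `base_seed + run index` (or an
#' explicit `seeds` vector), pools all components, clusters them by absolute
#' similarity under minimum-spanning-tree (single) linkage into c clusters,
#' scores each cluster as mean intra-cluster minus mean inter-cluster
#' similarity (clipped to `[0, 1]`), and selects the best run as the one
#' whose components are closest in total to the cluster exemplars
#' (centrotypes); ties break to the lowest run index.
#'
#' @inheritParams run_ica
#' @param n_runs number of reruns (>= 2; 20 is the conventional default).
#' @param base_seed seed from which rerun seeds are derived.
#' @param seeds optional explicit vector of `n_runs` seeds.
#' @return List with `best_run` (an `ica_run`) and `stability` (class
#'   `stability_report`: `cluster_quality` aligned to the best run's
#'   components, `best_run_index`, `run_count`).
#' @export
icasso <- function(whitened, n_runs = 20, base_seed = 1, seeds = NULL,
                   algorithm = c("infomax", "fastica"), max_iter = 2000,
                   tol = 1e-6) {
  algorithm <- match.arg(algorithm)
  if (n_runs < 2) stop("n_runs must be at least 2", call. = FALSE)
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_runs)
  stopifnot(length(seeds) == n_runs)
  z <- as.matrix(whitened)
  c_dim <- nrow(z)
  runs <- lapply(seeds, function(s)
    run_ica(z, seed = s, algorithm = algorithm, max_iter = max_iter,
            tol = tol))
  pool <- do.call(rbind, lapply(runs, `[[`, "sources"))
  run_of <- rep(seq_len(n_runs), each = c_dim)
  comp_of <- rep(seq_len(c_dim), times = n_runs)

  sim <- abs_cosine(pool)
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = "single")   # MST linkage
  cl <- stats::cutree(hc, k = c_dim)

  n_pool <- nrow(pool)
  quality <- numeric(c_dim)
  centrotype <- integer(c_dim)
  for (j in seq_len(c_dim)) {
    members <- which(cl == j)
    others <- setdiff(seq_len(n_pool), members)
    intra <- if (length(members) > 1) {
      sm <- sim[members, members, drop = FALSE]
      mean(sm[upper.tri(sm)])
    } else 1
    inter <- if (length(others)) mean(sim[members, others, drop = FALSE]) else 0
    quality[j] <- min(1, max(0, intra - inter))
    tot <- rowSums(sim[members, members, drop = FALSE])
    centrotype[j] <- members[which.max(tot)]
  }

  # best run: maximize summed similarity of its components to the exemplars
  score <- vapply(seq_len(n_runs), function(rn) {
    rows <- which(run_of == rn)
    sum(vapply(centrotype, function(ct) max(sim[rows, ct]), numeric(1)))
  }, numeric(1))
  best <- which.max(score)   # which.max returns the first (lowest) maximizer

  # align cluster qualities to the best run's component indices
  best_rows <- which(run_of == best)
  comp_quality <- vapply(seq_len(c_dim), function(i) {
    quality[cl[best_rows[i]]]
  }, numeric(1))

  stability <- structure(
    list(cluster_quality = comp_quality, best_run_index = best,
         run_count = n_runs, cluster_sizes = tabulate(cl, c_dim)),
    class = "stability_report"
  )
  list(best_run = runs[[best]], stability = stability)
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>", x$run_count, "runs | best run:",
      x$best_run_index, "| cluster quality:",
      paste(sprintf("%.3f", x$cluster_quality), collapse = " "), "\n")
  invisible(x)
}

#' Export a stability report as TSV
#'
#' @param stability a `stability_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stability <- function(stability, path) {
  utils::write.table(
    data.frame(component = seq_along(stability$cluster_quality),
               cluster_quality = stability$cluster_quality),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# Hungarian algorithm (shortest augmenting path, O(n^3)) for a square cost
# matrix; returns assignment: column j assigned to row perm[j].
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_row <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) assign_row[j - 1] <- p[j]
  assign_row
}

#' Align estimated components to reference maps
#'
#' Finds the one-to-one assignment maximizing the summed absolute Pearson
#' correlation (Hungarian algorithm), plus signs flipping each estimated row
#' to positive correlation with its match. Zero-variance rows are excluded
#' from matching and reported.
#'
#' @param est K x V matrix of estimated maps.
#' @param ref K x V matrix of reference maps.
#' @return List with `permutation` (for each ref row, the matched est row;
#'   NA for excluded rows), `signs`, `correlations` (matched |corr|), and
#'   `degenerate` (indices of zero-variance rows).
#' @export
align_components <- function(est, ref) {
  est <- as.matrix(est)
  ref <- as.matrix(ref)
  if (!all(dim(est) == dim(ref))) {
    stop("est and ref must have identical dimensions", call. = FALSE)
  }
  k <- nrow(est)
  sd_e <- apply(est, 1, stats::sd)
  sd_r <- apply(ref, 1, stats::sd)
  degen <- list(est = which(sd_e == 0), ref = which(sd_r == 0))
  ok_e <- sd_e > 0
  ok_r <- sd_r > 0
  cmat <- matrix(0, k, k)
  if (any(ok_e) && any(ok_r)) {
    cc <- stats::cor(t(est[ok_e, , drop = FALSE]),
                     t(ref[ok_r, , drop = FALSE]))
    cmat[which(ok_e), which(ok_r)] <- cc
  }
  # maximize sum |corr| == minimize sum (1 - |corr|); degenerate rows carry
  # zero weight so they absorb the leftover assignments. Cost rows index the
  # estimated maps, columns the references, so the assignment returned for
  # reference column j is the matched estimated row.
  permutation <- hungarian(1 - abs(cmat))
  signs <- numeric(k)
  correlations <- numeric(k)
  for (j in seq_len(k)) {
    i <- permutation[j]
    correlations[j] <- abs(cmat[i, j])
    signs[j] <- if (cmat[i, j] < 0) -1 else 1
  }
  excluded <- !ok_r | !ok_e[permutation]
  permutation[excluded] <- NA_integer_
  signs[excluded] <- NA_real_
  correlations[excluded] <- NA_real_
  list(permutation = permutation, signs = signs,
       correlations = correlations, degenerate = degen)
}
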