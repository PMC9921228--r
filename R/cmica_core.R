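#' Single-subject connectivity-matrix ICA machinery
#'
#' The functional connectivity matrix of one subject is the voxel-pair
#' temporal correlation `C = X'X / (T - 1)` of the temporally normalized
#' series `X`. It is never formed at full scale: an SVD of `X` yields the
#' same spatial eigenbasis (`C = U S^2 U' / (T - 1)`), so PCA/ICA can run on
#' the reduced spatial representation directly. Structural connectivity
#' matrices are reduced by a plain truncated SVD. The explicit-matrix route
#' is retained as a test oracle.
#'
#' @name cmica-core
NULL

#' Temporally normalize voxel time courses
#'
#' Each voxel column is centered and scaled to unit sample standard
#' deviation (n - 1 denominator). Zero-variance columns are replaced by
#' all-zeros, reported via a warning and a `zero_variance` attribute.
#'
#' @param data T x V matrix (timepoints by voxels).
#' @return Normalized T x V matrix with attribute `zero_variance` (column
#'   indices zeroed, possibly empty).
#' @export
temporal_normalize <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 2) {
    stop("need at least 2 timepoints to normalize", call. = FALSE)
  }
  mu <- colMeans(data)
  xc <- sweep(data, 2, mu)
  sd_v <- sqrt(colSums(xc^2) / (nrow(data) - 1))
  zv <- which(sd_v == 0)
  sd_safe <- sd_v
  sd_safe[zv] <- 1
  out <- sweep(xc, 2, sd_safe, `/`)
  if (length(zv)) {
    out[, zv] <- 0
    warning(length(zv), " zero-variance voxel column(s) set to zero",
            call. = FALSE)
  }
  attr(out, "zero_variance") <- zv
  out
}

#' Explicit voxel-by-voxel correlation matrix (test oracle)
#'
#' Builds `C = X'X / (T - 1)` from already-normalized input. Used only to
#' verify the SVD shortcut on small instances; never called by the pipeline.
#'
#' @param x_norm normalized T x V matrix (see [temporal_normalize()]).
#' @param tol tolerance for checking the normalization contract.
#' @return V x V symmetric matrix with unit diagonal for nonzero columns.
#' @export
explicit_fc_matrix <- function(x_norm, tol = 1e-8) {
  x_norm <- as.matrix(x_norm)
  n <- nrow(x_norm)
  ss <- colSums(x_norm^2) / (n - 1)
  nonzero <- ss > tol
  if (any(abs(ss[nonzero] - 1) > 1e-6)) {
    stop("input is not temporally normalized (column sd != 1)", call. = FALSE)
  }
  cmat <- crossprod(x_norm) / (n - 1)
  (cmat + t(cmat)) / 2
}

# Orient each column of u so its maximum-magnitude entry is positive;
# apply the same flips to the paired co-basis v. Deterministic across
# platforms (ties broken by the first index, which.max's behavior).
sign_fix <- function(u, v = NULL) {
  flips <- vapply(seq_len(ncol(u)), function(j) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) -1 else 1
  }, numeric(1))
  u <- sweep(u, 2, flips, `*`)
  if (is.null(v)) return(list(u = u))
  list(u = u, v = sweep(v, 2, flips, `*`))
}

new_reduced_subject <- function(modality, basis_u, sing_vals, basis_v,
                                n_samples, subject_id, transform = "none",
                                degenerate = FALSE) {
  structure(
    list(modality = modality, basis_u = basis_u, sing_vals = sing_vals,
         basis_v = basis_v, n_samples = n_samples, subject_id = subject_id,
         transform = transform, degenerate = degenerate,
         r = length(sing_vals)),
    class = "reduced_subject"
  )
}

#' @export
print.reduced_subject <- function(x, ...) {
  cat("<reduced_subject>", x$modality, "| subject:", x$subject_id,
      "| r =", x$r, "| V_A =", nrow(x$basis_u), "\n")
  invisible(x)
}

#' Reduce one subject's normalized fMRI by truncated SVD
#'
#' `X = V S U'` with `U` the spatial basis over gray voxels; the top `r`
#' components satisfy `U S^2 U' / (T - 1) =` the rank-r eigen-truncation of
#' the explicit correlation matrix.
#'
#' @param x_norm normalized T x V matrix.
#' @param r target rank, `1 <= r <= min(T - 1, V)`.
#' @param subject_id optional identifier.
#' @return A `reduced_subject` with `modality = "FC"`, `basis_u` (V x r),
#'   `sing_vals`, `basis_v` (T x r), `n_samples = T`.
#' @export
reduce_subject_fc <- function(x_norm, r, subject_id = NA_character_) {
  x_norm <- as.matrix(x_norm)
  t_len <- nrow(x_norm)
  v <- ncol(x_norm)
  if (r < 1 || r > min(t_len - 1, v)) {
    stop("r must be in [1, ", min(t_len - 1, v), "]", call. = FALSE)
  }
  sv <- svd(x_norm, nu = r, nv = r)
  fixed <- sign_fix(sv$v, sv$u)
  new_reduced_subject("FC", basis_u = fixed$u, sing_vals = sv$d[seq_len(r)],
                      basis_v = fixed$v, n_samples = t_len,
                      subject_id = subject_id)
}

#' Reduce one subject's structural connectivity by truncated SVD
#'
#' Optionally applies an elementwise `log1p` transform first (fiber-count
#' distributions are heavy-tailed). `basis_u` spans gray (Region A) voxels,
#' `basis_v` white (Region B) voxels.
#'
#' @param c_sc a `structural_connectivity` or a nonnegative matrix.
#' @param r target rank, `1 <= r <= min(V_A, V_B)`.
#' @param transform `"none"` (default) or `"log1p"`.
#' @param subject_id optional identifier (taken from `c_sc` if available).
#' @return A `reduced_subject` with `modality = "SC"` and
#'   `n_samples = V_B`.
#' @export
reduce_subject_sc <- function(c_sc, r, transform = c("none", "log1p"),
                              subject_id = NULL) {
  transform <- match.arg(transform)
  if (inherits(c_sc, "structural_connectivity")) {
    if (is.null(subject_id)) subject_id <- c_sc$subject_id
    mat <- as.matrix(c_sc$mat)
  } else {
    if (is.null(subject_id)) subject_id <- NA_character_
    mat <- as.matrix(c_sc)
  }
  if (any(mat < 0)) stop("fiber counts must be nonnegative", call. = FALSE)
  if (r < 1 || r > min(dim(mat))) {
    stop("r must be in [1, ", min(dim(mat)), "]", call. = FALSE)
  }
  if (transform == "log1p") mat <- log1p(mat)
  if (all(mat == 0)) {
    return(new_reduced_subject(
      "SC", basis_u = matrix(0, nrow(mat), r), sing_vals = rep(0, r),
      basis_v = matrix(0, ncol(mat), r), n_samples = ncol(mat),
      subject_id = subject_id, transform = transform, degenerate = TRUE
    ))
  }
  sv <- svd(mat, nu = r, nv = r)
  fixed <- sign_fix(sv$u, sv$v)
  new_reduced_subject("SC", basis_u = fixed$u, sing_vals = sv$d[seq_len(r)],
                      basis_v = fixed$v, n_samples = ncol(mat),
                      subject_id = subject_id, transform = transform)
}

# Connectivity co-factor P such that the subject's (rank-r, Region B x
# Region A oriented) connectivity matrix equals P %*% (Sigma U') :
# FC: C = U S^2 U'/(T-1) = [U S/(T-1)] Y ;  SC: C' = V S U' = [V] Y.
connectivity_cofactor <- function(red, c = red$r) {
  idx <- seq_len(c)
  if (red$modality == "FC") {
    sweep(red$basis_u[, idx, drop = FALSE], 2, red$sing_vals[idx], `*`) /
      (red$n_samples - 1)
  } else {
    red$basis_v[, idx, drop = FALSE]
  }
}

#' Rank-c truncation of a subject's connectivity matrix (oracle helper)
#'
#' Returns the Region-B x Region-A rank-c truncation `P (Sigma U')` implied
#' by the subject's reduced factors. For FC this is the eigen-truncated
#' correlation matrix; for SC the truncated (transposed) count matrix.
#'
#' @param red a `reduced_subject`.
#' @param c truncation rank (<= `red$r`).
#' @return V_B x V_A matrix.
#' @export
truncated_connectivity <- function(red, c = red$r) {
  idx <- seq_len(c)
  p <- connectivity_cofactor(red, c)
  y <- red$sing_vals[idx] * t(red$basis_u[, idx, drop = FALSE])
  p %*% y
}

#' Single-subject connectivity-matrix ICA
#'
#' Runs spatial ICA on the c-dimensional whitened spatial representation
#' `sqrt(V) U_c'` and returns sources `S = W U_c'` (scaled to unit variance
#' over voxels) together with connectivity maps `R` such that `R %*% S`
#' equals the rank-c truncation of the subject's connectivity matrix.
#' `algorithm = "identity"` bypasses ICA (`W = I`), giving `S = U'` and, for
#' FC, `R = U S^2 / (n - 1)` exactly.
#'
#' @param red a `reduced_subject`.
#' @param c model order (<= `red$r`).
#' @param seed seed for the ICA initialization.
#' @param algorithm `"infomax"` (default), `"fastica"`, or `"identity"`.
#' @param ... further arguments passed to [run_ica()].
#' @return Object of class `subject_decomposition` with `S` (c x V_A), `R`
#'   (V_B x c), `demix_w`, `modality`, `subject_id`, `ica` (the `ica_run`,
#'   or NULL in bypass mode).
#' @export
single_subject_cmica <- function(red, c, seed = 1,
                                 algorithm = c("infomax", "fastica",
                                               "identity"), ...) {
  stopifnot(inherits(red, "reduced_subject"))
  algorithm <- match.arg(algorithm)
  if (c < 1 || c > red$r) {
    stop("c must be in [1, ", red$r, "]", call. = FALSE)
  }
  u_c <- red$basis_u[, seq_len(c), drop = FALSE]
  p <- connectivity_cofactor(red, c)
  if (algorithm == "identity") {
    s <- t(u_c)
    r_maps <- if (red$modality == "FC") {
      sweep(u_c, 2, red$sing_vals[seq_len(c)]^2, `*`) / (red$n_samples - 1)
    } else {
      sweep(red$basis_v[, seq_len(c), drop = FALSE], 2,
            red$sing_vals[seq_len(c)], `*`)
    }
    return(structure(
      list(S = s, R = r_maps, demix_w = diag(c), modality = red$modality,
           subject_id = red$subject_id, ica = NULL),
      class = "subject_decomposition"
    ))
  }
  v_a <- nrow(u_c)
  z <- sqrt(v_a) * t(u_c)              # whitened: Z Z' / V = I exactly
  run <- run_ica(z, seed = seed, algorithm = algorithm, ...)
  w_eff <- sqrt(v_a) * run$demix_w     # acts on U': S = W_eff U'
  s <- w_eff %*% t(u_c)
  # scale sources to unit variance over voxels; R absorbs the scale
  d <- apply(s, 1, stats::sd)
  d[d == 0] <- 1
  s <- s / d
  w_eff <- w_eff / d
  r_maps <- p %*% (red$sing_vals[seq_len(c)] * solve(w_eff))
  structure(
    list(S = s, R = r_maps, demix_w = w_eff, modality = red$modality,
         subject_id = red$subject_id, ica = run),
    class = "subject_decomposition"
  )
}

#' @export
print.subject_decomposition <- function(x, ...) {
  cat("<subject_decomposition>", x$modality, "| subject:", x$subject_id,
      "|", nrow(x$S), "components x", ncol(x$S), "voxels\n")
  invisible(x)
}
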