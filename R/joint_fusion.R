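#' Joint connectivity-matrix ICA: group reduction, balanced concatenation,
#' joint unmixing and back-reconstruction
#'
#' Two PCA stages per modality (subject-level truncated SVD, then group-level
#' SVD of the concatenated reduced representations), balanced concatenation
#' of the two modality bases along the gray-voxel dimension so neither
#' modality dominates the variance, joint spatial ICA for shared gray-matter
#' sources, and GICA-style back-reconstruction of subject- and
#' modality-specific source maps S_k and connectivity maps R_k.
#'
#' @name joint-fusion
NULL

#' Group-level PCA of subject reductions (second reduction stage)
#'
#' Stacks the subject-level reduced representations `Sigma_k U_k'` along the
#' sample dimension and takes a truncated SVD, recording the per-subject
#' partitions of the co-basis used later for back-reconstruction.
#'
#' @param subjects list of `reduced_subject` objects, all of one modality
#'   with identical Region-A voxel counts and subject-level rank.
#' @param m group model order (<= n_subjects x r).
#' @return Object of class `group_reduction`: `modality`, `group_basis`
#'   (V_A x m, orthonormal), `group_sing` (m singular values),
#'   `subject_partitions` (list of r x m co-basis blocks), `m`, `r`,
#'   `n_subjects`, `subject_ids`.
#' @export
group_reduce <- function(subjects, m) {
  stopifnot(length(subjects) >= 1)
  mods <- unique(vapply(subjects, `[[`, character(1), "modality"))
  if (length(mods) != 1) {
    stop("all subjects must share one modality, got: ",
         paste(mods, collapse = ", "), call. = FALSE)
  }
  va <- unique(vapply(subjects, function(s) nrow(s$basis_u), integer(1)))
  rr <- unique(vapply(subjects, `[[`, integer(1), "r"))
  if (length(va) != 1 || length(rr) != 1) {
    stop("subjects must share Region-A voxel count and rank", call. = FALSE)
  }
  n <- length(subjects)
  if (m < 1 || m > n * rr) {
    stop("m must be in [1, ", n * rr, "]", call. = FALSE)
  }
  g <- do.call(rbind, lapply(subjects, function(s)
    s$sing_vals * t(s$basis_u)))          # each block: Sigma_k U_k'
  sv <- svd(g, nu = m, nv = m)
  fixed <- sign_fix(sv$v, sv$u)           # group_basis over voxels, co-basis
  parts <- lapply(seq_len(n), function(k) {
    fixed$v[((k - 1) * rr + 1):(k * rr), , drop = FALSE]
  })
  structure(
    list(modality = mods, group_basis = fixed$u,
         group_sing = sv$d[seq_len(m)], subject_partitions = parts,
         m = m, r = rr, n_subjects = n,
         subject_ids = vapply(subjects, `[[`, character(1), "subject_id")),
    class = "group_reduction"
  )
}

#' @export
print.group_reduction <- function(x, ...) {
  cat("<group_reduction>", x$modality, "|", x$n_subjects, "subjects | m =",
      x$m, "| V_A =", nrow(x$group_basis), "\n")
  invisible(x)
}

#' Balanced concatenation of the two modality reductions
#'
#' Stacks the modality-level whitened spatial representations
#' (`sqrt(V) * group_basis'`) along the gray-voxel dimension. Scaling each
#' block to unit row variance is the balancing step: it gives both
#' modalities an equal share of the reduced data regardless of the very
#' different raw variances of correlation and count matrices.
#'
#' @param fc,sc `group_reduction` objects for the FC and SC modality.
#' @return List with `joint` ((m_FC + m_SC) x V_gm matrix) and
#'   `concat_order` (data.frame: row, modality, component-within-block).
#' @export
concatenate_modalities <- function(fc, sc) {
  stopifnot(inherits(fc, "group_reduction"), inherits(sc, "group_reduction"))
  v <- nrow(fc$group_basis)
  if (nrow(sc$group_basis) != v) {
    stop("gray-matter voxel domains differ between modalities", call. = FALSE)
  }
  blocks <- list(FC = fc, SC = sc)
  rows <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    if (all(b$group_sing == 0)) {
      stop("modality ", nm, " has an all-zero reduction; cannot whiten",
           call. = FALSE)
    }
    sqrt(v) * t(b$group_basis)   # unit row variance: rows of U' have ssq 1
  })
  joint <- rbind(rows[[1]], rows[[2]])
  concat_order <- data.frame(
    row = seq_len(nrow(joint)),
    modality = rep(c("FC", "SC"), c(fc$m, sc$m)),
    component = c(seq_len(fc$m), seq_len(sc$m))
  )
  list(joint = joint, concat_order = concat_order)
}

# Whitening transform for the joint matrix (rows correlated across blocks).
joint_whitener <- function(joint) {
  m <- ncol(joint)
  e <- eigen(tcrossprod(joint) / m, symmetric = TRUE)
  if (min(e$values) < 1e-10 * max(e$values)) {
    stop("joint matrix is rank-deficient; reduce the per-modality order",
         call. = FALSE)
  }
  list(forward = (t(e$vectors) / sqrt(e$values)),
       backward = e$vectors %*% diag(sqrt(e$values), length(e$values)))
}

#' Fit the joint connectivity-matrix ICA model
#'
#' Full pipeline: temporal normalization and subject-level SVD per modality,
#' group-level PCA per modality, balanced concatenation along the gray-voxel
#' dimension, joint whitening, ICASSO-stabilized spatial ICA, and aggregation
#' of the best run's shared sources. Deterministic given `seed`.
#'
#' @param fmri list of `ts_subject` objects (or T x V matrices).
#' @param sc list of `structural_connectivity` objects (or count matrices),
#'   paired with `fmri` by position.
#' @param subject_r subject-level PCA rank per modality.
#' @param m_per_modality group PCA order per modality; the joint ICA order is
#'   `c = 2 * m_per_modality` (symmetric model).
#' @param icasso_runs number of ICA reruns for stability selection (>= 2).
#' @param seed master seed; ICA rerun seeds are derived from it.
#' @param sc_transform optional `log1p` transform of fiber counts.
#' @param algorithm ICA algorithm (see [run_ica()]).
#' @param max_iter,tol ICA optimizer controls.
#' @return Object of class `joint_cmica` with `reductions` (per modality
#'   `group_reduction`), `subject_reductions` (per modality list of
#'   `reduced_subject`), `demix_w` (c x c, acting on the balanced joint
#'   matrix), `aggregate_S` (c x V_gm, unit-variance rows), `stability`,
#'   `concat_order`, `c`, `config`, `seed`.
#' @export
fit_joint_cmica <- function(fmri, sc, subject_r = 40, m_per_modality = 30,
                            icasso_runs = 20, seed = 1,
                            sc_transform = c("none", "log1p"),
                            algorithm = c("infomax", "fastica"),
                            max_iter = 2000, tol = 1e-6) {
  sc_transform <- match.arg(sc_transform)
  algorithm <- match.arg(algorithm)
  if (length(fmri) != length(sc)) {
    stop("fmri and sc lists must be paired (equal length)", call. = FALSE)
  }
  n <- length(fmri)
  if (n < 2) stop("the group model needs at least 2 subjects", call. = FALSE)
  if (icasso_runs < 2) stop("icasso_runs must be >= 2", call. = FALSE)

  red_fc <- vector("list", n)
  red_sc <- vector("list", n)
  for (k in seq_len(n)) {
    x <- if (inherits(fmri[[k]], "ts_subject")) fmri[[k]]$data else fmri[[k]]
    sid <- if (inherits(fmri[[k]], "ts_subject")) fmri[[k]]$subject_id
           else sprintf("sub-%03d", k)
    xn <- suppressWarnings(temporal_normalize(x))
    red_fc[[k]] <- reduce_subject_fc(xn, r = subject_r, subject_id = sid)
    red_sc[[k]] <- reduce_subject_sc(sc[[k]], r = subject_r,
                                     transform = sc_transform,
                                     subject_id = sid)
  }

  grp_fc <- group_reduce(red_fc, m = m_per_modality)
  grp_sc <- group_reduce(red_sc, m = m_per_modality)
  cc <- concatenate_modalities(grp_fc, grp_sc)
  wh <- joint_whitener(cc$joint)
  zw <- wh$forward %*% cc$joint

  ic <- icasso(zw, n_runs = icasso_runs, base_seed = seed,
               algorithm = algorithm, max_iter = max_iter, tol = tol)
  w_joint <- ic$best_run$demix_w %*% wh$forward   # demixing on the joint matrix
  s_agg <- w_joint %*% cc$joint
  d <- apply(s_agg, 1, stats::sd)
  d[d == 0] <- 1
  s_agg <- s_agg / d
  w_joint <- w_joint / d

  structure(
    list(
      reductions = list(FC = grp_fc, SC = grp_sc),
      subject_reductions = list(FC = red_fc, SC = red_sc),
      demix_w = w_joint,
      aggregate_S = s_agg,
      stability = ic$stability,
      concat_order = cc$concat_order,
      c = nrow(s_agg),
      n_subjects = n,
      v_gm = ncol(s_agg),
      config = list(subject_r = subject_r, m_per_modality = m_per_modality,
                    icasso_runs = icasso_runs, sc_transform = sc_transform,
                    algorithm = algorithm, max_iter = max_iter, tol = tol),
      seed = seed
    ),
    class = "joint_cmica"
  )
}

#' @export
print.joint_cmica <- function(x, ...) {
  cat("<joint_cmica>", x$c, "components |", x$n_subjects, "subjects |",
      x$v_gm, "gray voxels | min stability:",
      sprintf("%.3f", min(x$stability$cluster_quality)), "\n")
  invisible(x)
}

#' Mixing (loading) matrix of a fitted joint model
#'
#' Columns are components; rows correspond to the balanced joint matrix's
#' rows and split into the FC and SC blocks recorded in `concat_order`.
#'
#' @param model a `joint_cmica`.
#' @return c x c mixing matrix `A = W^-1`.
#' @export
mixing_matrix <- function(model) {
  solve(model$demix_w)
}

#' Aggregate source maps restricted to one modality's contribution
#'
#' The aggregate sources decompose as `S = sum_m W_m J_m` over modality
#' blocks of the balanced joint matrix; this returns one term.
#'
#' @param model a `joint_cmica`.
#' @param modality `"FC"` or `"SC"`.
#' @return c x V_gm matrix.
#' @export
modality_aggregate <- function(model, modality = c("FC", "SC")) {
  modality <- match.arg(modality)
  idx <- model$concat_order$row[model$concat_order$modality == modality]
  grp <- model$reductions[[modality]]
  j_m <- sqrt(model$v_gm) * t(grp$group_basis)
  model$demix_w[, idx, drop = FALSE] %*% j_m
}

#' Back-reconstruct subject- and modality-specific maps
#'
#' GICA-style chain: the subject's reduced data `Y_k = Sigma_k U_k'` is
#' mapped through its partition of the group co-basis and the modality block
#' of the demixing matrix, `S_k = N sqrt(V) W_m Sigma_m^{-1} V_k' Y_k`, and
#' the connectivity maps are `R_k = P_k pinv(K_k)` with `P_k` the subject's
#' connectivity co-factor, so that `R_k S_k` reproduces the subject's
#' rank-limited connectivity matrix. The subject-mean of `S_k` equals the
#' modality-restricted aggregate sources exactly (SVD partition identity).
#'
#' @param model a `joint_cmica`.
#' @param modality `"FC"` or `"SC"`.
#' @param subject_index subject position used in the fit.
#' @param reduced optional `reduced_subject` (defaults to the one stored in
#'   the model).
#' @return Object of class `subject_maps`: `S_k` (c x V_gm), `R_k`
#'   (V_B x c), `modality`, `subject_id`.
#' @export
back_reconstruct <- function(model, modality = c("FC", "SC"), subject_index,
                             reduced = NULL) {
  stopifnot(inherits(model, "joint_cmica"))
  modality <- match.arg(modality)
  if (subject_index < 1 || subject_index > model$n_subjects) {
    stop("unknown subject index ", subject_index, call. = FALSE)
  }
  if (is.null(reduced)) {
    reduced <- model$subject_reductions[[modality]][[subject_index]]
  }
  grp <- model$reductions[[modality]]
  idx <- model$concat_order$row[model$concat_order$modality == modality]
  w_m <- model$demix_w[, idx, drop = FALSE]              # c x m
  vk <- grp$subject_partitions[[subject_index]]          # r x m
  n <- model$n_subjects
  v <- model$v_gm
  k_mat <- (n * sqrt(v)) * w_m %*% (t(vk) / grp$group_sing)   # c x r
  y_k <- reduced$sing_vals * t(reduced$basis_u)               # r x V_gm
  s_k <- k_mat %*% y_k
  p_k <- connectivity_cofactor(reduced)                       # V_B x r
  r_k <- p_k %*% pinv(k_mat)
  structure(
    list(S_k = s_k, R_k = r_k, modality = modality,
         subject_id = reduced$subject_id, subject_index = subject_index),
    class = "subject_maps"
  )
}

# Moore-Penrose pseudo-inverse via SVD.
pinv <- function(a, tol = NULL) {
  sv <- svd(a)
  if (is.null(tol)) tol <- max(dim(a)) * .Machine$double.eps * max(sv$d)
  keep <- sv$d > tol
  if (!any(keep)) return(matrix(0, ncol(a), nrow(a)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' @export
print.subject_maps <- function(x, ...) {
  cat("<subject_maps>", x$modality, "| subject:", x$subject_id, "|",
      nrow(x$S_k), "components\n")
  invisible(x)
}

#' Back-reconstruct all subjects for one modality
#'
#' @param model a `joint_cmica`.
#' @param modality `"FC"` or `"SC"`.
#' @return List of `subject_maps`, one per fitted subject.
#' @export
back_reconstruct_all <- function(model, modality = c("FC", "SC")) {
  modality <- match.arg(modality)
  lapply(seq_len(model$n_subjects), function(k)
    back_reconstruct(model, modality, k))
}

#' Group-average source and connectivity maps
#'
#' Voxel-wise mean of the back-reconstructed subject maps for one modality.
#'
#' @param model a `joint_cmica`.
#' @param maps list of `subject_maps` from [back_reconstruct_all()].
#' @param modality `"FC"` or `"SC"`.
#' @return List with `S_mean` (c x V_gm) and `R_mean` (V_B x c).
#' @export
group_average_maps <- function(model, maps, modality = c("FC", "SC")) {
  modality <- match.arg(modality)
  maps <- Filter(function(m) m$modality == modality, maps)
  if (length(maps) != model$n_subjects) {
    stop("need maps for all ", model$n_subjects, " fitted subjects, got ",
         length(maps), call. = FALSE)
  }
  s_mean <- Reduce(`+`, lapply(maps, `[[`, "S_k")) / length(maps)
  r_mean <- Reduce(`+`, lapply(maps, `[[`, "R_k")) / length(maps)
  list(S_mean = s_mean, R_mean = r_mean)
}
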