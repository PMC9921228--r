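#' Post-decomposition component analytics
#'
#' Variance sorting, the modality contribution ratio with the 20-80% shared
#' screen, cross-modality spatial similarity, one-sample t-maps, mean + k*sd
#' thresholding into regions of interest, and atlas-overlap labeling.
#'
#' @name component-analysis
NULL

#' Per-modality explained-variance shares of each component
#'
#' With orthogonal unit-variance sources, the variance of modality block m
#' explained by component j is the squared column norm of the mixing-matrix
#' block, normalized within modality.
#'
#' @param model a `joint_cmica`.
#' @return data.frame with `component`, `variance_fc`, `variance_sc`,
#'   `variance_mean` (shares summing to 1 within each modality).
#' @export
component_variances <- function(model) {
  a <- mixing_matrix(model)
  fc_rows <- model$concat_order$row[model$concat_order$modality == "FC"]
  sc_rows <- model$concat_order$row[model$concat_order$modality == "SC"]
  v_fc <- colSums(a[fc_rows, , drop = FALSE]^2)
  v_sc <- colSums(a[sc_rows, , drop = FALSE]^2)
  v_fc <- v_fc / sum(v_fc)
  v_sc <- v_sc / sum(v_sc)
  data.frame(component = seq_len(model$c), variance_fc = v_fc,
             variance_sc = v_sc, variance_mean = (v_fc + v_sc) / 2)
}

#' Sort components by mean explained variance
#'
#' Descending order of the across-modality mean variance share; ties break
#' stably by component index.
#'
#' @param model a `joint_cmica`, or a numeric vector of mean variances.
#' @return Integer ordering (component indices, most significant first).
#' @export
sort_by_variance <- function(model) {
  v <- if (inherits(model, "joint_cmica")) {
    component_variances(model)$variance_mean
  } else {
    as.numeric(model)
  }
  order(-v, seq_along(v))
}

#' Modality contribution ratio per component
#'
#' For component j, the mean absolute mixing loading is computed over each
#' modality's rows of `A = W^-1`; the FC contribution is
#' `a_FC / (a_FC + a_SC)`.
#'
#' @param model a `joint_cmica`.
#' @return data.frame with `component`, `contribution_fc`, `contribution_sc`
#'   (summing to 1 exactly).
#' @export
contribution_ratio <- function(model) {
  a <- mixing_matrix(model)
  fc_rows <- model$concat_order$row[model$concat_order$modality == "FC"]
  sc_rows <- model$concat_order$row[model$concat_order$modality == "SC"]
  a_fc <- colMeans(abs(a[fc_rows, , drop = FALSE]))
  a_sc <- colMeans(abs(a[sc_rows, , drop = FALSE]))
  tot <- a_fc + a_sc
  if (any(tot == 0)) {
    stop("undefined contribution ratio: component(s) ",
         paste(which(tot == 0), collapse = ", "),
         " have zero loadings in both modalities", call. = FALSE)
  }
  data.frame(component = seq_along(a_fc),
             contribution_fc = a_fc / tot,
             contribution_sc = a_sc / tot)
}

#' Select shared components by contribution ratio
#'
#' A component is "shared" when neither modality contributes more than
#' `high` nor less than `low` (inclusive bounds).
#'
#' @param ratios numeric vector of FC contribution ratios in `[0, 1]`, or
#'   the data.frame returned by [contribution_ratio()].
#' @param low,high inclusive bounds (defaults 0.2 and 0.8).
#' @return Integer vector of shared component indices.
#' @export
select_shared <- function(ratios, low = 0.2, high = 0.8) {
  if (is.data.frame(ratios)) ratios <- ratios$contribution_fc
  if (low >= high) stop("low must be < high", call. = FALSE)
  which(ratios >= low & ratios <= high)
}

#' Spatial similarity between two maps
#'
#' Pearson correlation over gray voxels, optionally with a seeded
#' voxel-shuffle permutation p-value.
#'
#' @param s_fc,s_sc numeric vectors of equal length.
#' @param n_perm number of voxel-shuffle permutations (0 = none).
#' @param seed seed for the permutation null.
#' @return The correlation, with attribute `p_value` when `n_perm > 0`.
#' @export
spatial_similarity <- function(s_fc, s_sc, n_perm = 0, seed = 1) {
  if (length(s_fc) != length(s_sc)) {
    stop("maps must have equal length", call. = FALSE)
  }
  if (stats::sd(s_fc) == 0 || stats::sd(s_sc) == 0) {
    stop("undefined similarity: zero-variance map", call. = FALSE)
  }
  r <- stats::cor(s_fc, s_sc)
  if (n_perm > 0) {
    null <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i)
        stats::cor(s_fc, sample(s_sc)), numeric(1))
    })
    attr(r, "p_value") <- (1 + sum(abs(null) >= abs(r))) / (n_perm + 1)
  }
  r
}

#' Voxel-wise one-sample t-statistic map across subjects
#'
#' `t = mean / (sd / sqrt(n))` per voxel; voxels with zero across-subject
#' standard deviation get `t = 0` and are flagged.
#'
#' @param subject_maps n_subj x V matrix (one subject map per row), or a
#'   list of equal-length vectors.
#' @return Numeric t map with attribute `zero_sd` (flagged voxel indices).
#' @export
tstat_map <- function(subject_maps) {
  if (is.list(subject_maps)) subject_maps <- do.call(rbind, subject_maps)
  n <- nrow(subject_maps)
  if (n < 2) stop("need at least 2 subjects for a t-map", call. = FALSE)
  mu <- colMeans(subject_maps)
  sd_v <- apply(subject_maps, 2, stats::sd)
  zero <- which(sd_v == 0)
  sd_safe <- sd_v
  sd_safe[zero] <- 1
  t_map <- mu / (sd_safe / sqrt(n))
  t_map[zero] <- 0
  attr(t_map, "zero_sd") <- zero
  t_map
}

#' Threshold a map at its own mean plus k standard deviations
#'
#' Retains voxels with `value > mean + k * sd` of the map itself. The
#' conventional defaults are `k = 3` for source (S) maps and `k = 2` for
#' connectivity (R) maps. A constant map yields an empty ROI with a warning.
#'
#' @param map numeric vector (or array) of finite values.
#' @param k_sigma threshold multiplier.
#' @return Logical ROI of the same shape, attribute `cutoff`.
#' @export
threshold_map <- function(map, k_sigma = 3) {
  vals <- as.numeric(map)
  if (any(!is.finite(vals))) stop("map must be finite", call. = FALSE)
  mu <- mean(vals)
  sg <- stats::sd(vals)
  if (sg == 0) {
    warning("constant map: sigma = 0, returning empty ROI", call. = FALSE)
    roi <- rep(FALSE, length(vals))
  } else {
    roi <- vals > mu + k_sigma * sg
  }
  if (!is.null(dim(map))) dim(roi) <- dim(map)
  attr(roi, "cutoff") <- mu + k_sigma * sg
  roi
}

#' Atlas overlap of a binary ROI
#'
#' Containment overlap: `overlap%(label) = 100 * |ROI intersect label| /
#' |ROI|`. The best label is the nonzero label with maximum overlap
#' (ties break to the lowest label id), assigned purely by maximum
#' correspondence. Background (label 0) counts toward the total so all
#' percentages sum to 100.
#'
#' @param roi logical 3-D array (or vector matching the atlas grid).
#' @param atlas an `atlas_volume`.
#' @return List with `overlap` (data.frame: label id, name, percent,
#'   including background as id 0) and `best` (list: id, name, percent).
#' @export
atlas_overlap <- function(roi, atlas) {
  stopifnot(inherits(atlas, "atlas_volume"))
  roi_v <- as.logical(roi)
  if (length(roi_v) != length(atlas$labels)) {
    stop("ROI and atlas grids differ in size", call. = FALSE)
  }
  n_roi <- sum(roi_v)
  if (n_roi == 0) stop("empty ROI", call. = FALSE)
  labs <- atlas$labels[roi_v]
  cnt <- table(factor(labs, levels = sort(unique(c(0L, atlas$names$id)))))
  pct <- 100 * as.numeric(cnt) / n_roi
  ids <- as.integer(names(cnt))
  name_of <- function(id) {
    if (id == 0L) return("background")
    atlas$names$name[match(id, atlas$names$id)]
  }
  overlap <- data.frame(
    id = ids,
    name = vapply(ids, name_of, character(1)),
    percent = pct
  )
  nz <- overlap[overlap$id != 0L, , drop = FALSE]
  nz <- nz[order(-nz$percent, nz$id), , drop = FALSE]
  best <- if (nrow(nz) && nz$percent[1] > 0) {
    list(id = nz$id[1], name = nz$name[1], percent = nz$percent[1])
  } else {
    list(id = NA_integer_, name = NA_character_, percent = 0)
  }
  list(overlap = overlap, best = best)
}

#' Per-component summary of a fitted joint model
#'
#' The machine twin of a component report table: explained-variance shares,
#' contribution ratio, shared flag, and cross-modality spatial similarity of
#' the group-averaged source maps.
#'
#' @param model a `joint_cmica`.
#' @param low,high shared-screen bounds (inclusive).
#' @param exclude integer indices of components to drop from the shared set
#'   (manual artifact exclusion list).
#' @return data.frame with one row per component, ordered by decreasing mean
#'   variance: `component`, `variance_fc`, `variance_sc`, `contribution_fc`,
#'   `shared`, `spatial_similarity`.
#' @export
component_summary <- function(model, low = 0.2, high = 0.8,
                              exclude = integer(0)) {
  vr <- component_variances(model)
  cr <- contribution_ratio(model)
  s_fc <- modality_aggregate(model, "FC")
  s_sc <- modality_aggregate(model, "SC")
  sim <- vapply(seq_len(model$c), function(j) {
    if (stats::sd(s_fc[j, ]) == 0 || stats::sd(s_sc[j, ]) == 0) {
      return(NA_real_)
    }
    stats::cor(s_fc[j, ], s_sc[j, ])
  }, numeric(1))
  shared <- seq_len(model$c) %in% select_shared(cr, low, high)
  shared[exclude] <- FALSE
  out <- data.frame(
    component = vr$component,
    variance_fc = vr$variance_fc,
    variance_sc = vr$variance_sc,
    contribution_fc = cr$contribution_fc,
    shared = shared,
    spatial_similarity = sim
  )
  out[sort_by_variance(model), , drop = FALSE]
}

#' Write a component summary as TSV
#'
#' @param summary data.frame from [component_summary()] (possibly with atlas
#'   columns appended).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_component_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
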