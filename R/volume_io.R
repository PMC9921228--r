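#' Brain masks, atlases and the canonical voxel vectorization
#'
#' All matrices in the pipeline index voxels in one fixed order: ascending
#' linear index over the 3-D grid with the first axis varying fastest
#' (column-major, R's native array order), 1-based inside R. Every spatial
#' map, connectivity matrix and exported volume uses this convention.
#'
#' @name volume-io
NULL

#' Construct a brain mask from a 3-D array
#'
#' Values are binarized at a threshold (default 0.5) so probabilistic masks
#' are handled; the voxel order of the mask defines the canonical
#' vectorization used throughout.
#'
#' @param grid 3-D numeric or logical array.
#' @param affine 4x4 voxel-to-world transform in mm; defaults to identity.
#' @param threshold binarization threshold for probabilistic inputs.
#' @return An object of class `brain_mask` with elements `grid` (logical
#'   array), `affine`, `n_voxels`, and `vox_idx` (linear indices of the
#'   in-mask voxels in canonical order).
#' @export
as_brain_mask <- function(grid, affine = diag(4), threshold = 0.5) {
  if (length(dim(grid)) != 3L) {
    stop("mask must be a 3-D volume, got ", length(dim(grid)), " dimensions",
         call. = FALSE)
  }
  g <- array(as.numeric(grid) > threshold, dim = dim(grid))
  idx <- which(g)
  if (length(idx) == 0L) {
    stop("empty mask: no voxels exceed the threshold of ", threshold,
         call. = FALSE)
  }
  structure(
    list(grid = g, affine = affine, n_voxels = length(idx), vox_idx = idx),
    class = "brain_mask"
  )
}

#' Load a brain mask from a NIfTI file
#'
#' @param path path to a 3-D NIfTI volume.
#' @param threshold binarization threshold (values > threshold are in-mask).
#' @return A [as_brain_mask()] object.
#' @export
load_mask <- function(path, threshold = 0.5) {
  vol <- RNifti::readNifti(path)
  arr <- as.array(vol)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- arr[, , , 1, drop = TRUE]
    dim(arr) <- dim(arr)[1:3]
  }
  if (length(dim(arr)) != 3L) {
    stop("mask file must contain a 3-D volume: ", path, call. = FALSE)
  }
  as_brain_mask(arr, affine = unclass(RNifti::xform(vol)),
                threshold = threshold)
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("<brain_mask> grid", paste(dim(x$grid), collapse = "x"),
      "| n_voxels:", x$n_voxels, "\n")
  invisible(x)
}

#' Extract masked voxel values in canonical order
#'
#' `devectorize()` is the exact inverse on masked voxels:
#' `devectorize(vectorize(v, m), m)` restores the in-mask values bit for bit.
#'
#' @param volume 3-D array with the same grid shape as the mask.
#' @param mask a `brain_mask`.
#' @return Numeric vector of length `mask$n_voxels`.
#' @export
vectorize <- function(volume, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  if (!identical(dim(volume), dim(mask$grid))) {
    stop("volume shape (", paste(dim(volume), collapse = "x"),
         ") does not match mask grid (",
         paste(dim(mask$grid), collapse = "x"), ")", call. = FALSE)
  }
  as.numeric(volume[mask$vox_idx])
}

#' Re-embed a masked vector into the 3-D grid
#'
#' @param values numeric vector over masked voxels (canonical order).
#' @param mask a `brain_mask`.
#' @param fill value for out-of-mask voxels.
#' @return 3-D array of the mask's grid shape.
#' @export
devectorize <- function(values, mask, fill = 0) {
  stopifnot(inherits(mask, "brain_mask"))
  if (length(values) != mask$n_voxels) {
    stop("expected ", mask$n_voxels, " values, got ", length(values),
         call. = FALSE)
  }
  out <- array(fill, dim = dim(mask$grid))
  out[mask$vox_idx] <- values
  out
}

#' Construct a labeled atlas volume
#'
#' @param labels 3-D integer array, 0 = background.
#' @param names data.frame with columns `id` and `name`, one row per nonzero
#'   label used in `labels`.
#' @return An object of class `atlas_volume`.
#' @export
as_atlas_volume <- function(labels, names) {
  if (length(dim(labels)) != 3L) {
    stop("atlas must be a 3-D label volume", call. = FALSE)
  }
  labels <- array(as.integer(round(labels)), dim = dim(labels))
  used <- sort(unique(labels[labels != 0L]))
  if (!all(used %in% names$id)) {
    stop("atlas labels without a name entry: ",
         paste(setdiff(used, names$id), collapse = ", "), call. = FALSE)
  }
  structure(list(labels = labels, names = names), class = "atlas_volume")
}

#' Load an atlas volume and its label names
#'
#' @param path NIfTI file of integer labels (0 = background).
#' @param names_path tab-separated file with columns `id` and `name`.
#' @return An `atlas_volume`.
#' @export
load_atlas <- function(path, names_path) {
  arr <- as.array(RNifti::readNifti(path))
  nm <- utils::read.table(names_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  as_atlas_volume(arr, nm)
}

#' Construct a structural connectivity matrix
#'
#' Gray-voxel (rows) by white-voxel (columns) nonnegative fiber counts, with
#' mask provenance. Stored sparse.
#'
#' @param mat matrix or `Matrix` of nonnegative counts, dimensions
#'   `row_mask$n_voxels` x `col_mask$n_voxels`.
#' @param row_mask,col_mask `brain_mask` objects for the two voxel domains.
#' @param subject_id optional identifier.
#' @return Object of class `structural_connectivity`.
#' @export
as_structural_connectivity <- function(mat, row_mask, col_mask,
                                       subject_id = NA_character_) {
  stopifnot(inherits(row_mask, "brain_mask"), inherits(col_mask, "brain_mask"))
  mat <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  if (nrow(mat) != row_mask$n_voxels || ncol(mat) != col_mask$n_voxels) {
    stop("connectivity matrix is ", nrow(mat), "x", ncol(mat),
         " but masks imply ", row_mask$n_voxels, "x", col_mask$n_voxels,
         call. = FALSE)
  }
  if (length(mat@x) && min(mat@x) < 0) {
    stop("connectivity matrix has negative entries; fiber counts must be >= 0",
         call. = FALSE)
  }
  structure(
    list(mat = mat, row_mask = row_mask, col_mask = col_mask,
         subject_id = subject_id),
    class = "structural_connectivity"
  )
}

#' @export
print.structural_connectivity <- function(x, ...) {
  cat("<structural_connectivity>", nrow(x$mat), "x", ncol(x$mat),
      "| nnz:", length(x$mat@x), "| subject:", x$subject_id, "\n")
  invisible(x)
}

#' Read a structural connectivity matrix from MatrixMarket format
#'
#' @param path `.mtx` file with the gray x white count matrix.
#' @param rows,cols `brain_mask` objects giving the expected voxel domains.
#' @param subject_id optional identifier.
#' @return A `structural_connectivity`.
#' @export
read_connectivity <- function(path, rows, cols, subject_id = NA_character_) {
  mat <- Matrix::readMM(path)
  as_structural_connectivity(mat, rows, cols, subject_id = subject_id)
}

#' Write a structural connectivity matrix to MatrixMarket format
#'
#' @param sc a `structural_connectivity`.
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(sc, path) {
  stopifnot(inherits(sc, "structural_connectivity"))
  Matrix::writeMM(sc$mat, path)
  invisible(path)
}

#' Export component maps as a 4-D NIfTI volume
#'
#' One volume per component (rows of `maps`), voxels re-embedded through the
#' mask; float32 on disk.
#'
#' @param maps components x voxels matrix in the mask's canonical order.
#' @param mask a `brain_mask` for the voxel domain.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_component_maps <- function(maps, mask, path) {
  stopifnot(inherits(mask, "brain_mask"))
  maps <- rbind(maps)
  arr <- array(0, dim = c(dim(mask$grid), nrow(maps)))
  for (j in seq_len(nrow(maps))) {
    arr[, , , j] <- devectorize(maps[j, ], mask)
  }
  img <- RNifti::asNifti(arr, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read component maps written by [write_component_maps()]
#'
#' @param path 4-D NIfTI file.
#' @param mask `brain_mask` used at export time.
#' @return components x voxels matrix.
#' @export
read_component_maps <- function(path, mask) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  k <- dim(arr)[4]
  out <- matrix(0, nrow = k, ncol = mask$n_voxels)
  for (j in seq_len(k)) {
    out[j, ] <- vectorize(arr[, , , j, drop = TRUE], mask)
  }
  out
}

#' Write a 3-D volume (e.g. a mask) as NIfTI
#'
#' @param arr 3-D array.
#' @param path output path.
#' @param datatype on-disk datatype passed to RNifti.
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, path, datatype = "float") {
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = datatype), path)
  invisible(path)
}
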