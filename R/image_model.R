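# ---------------------------------------------------------------------------
# Data model: subject volume maps, brain masks, atlas ROI sets.
# All subjects are assumed pre-registered to a common grid; functions refuse
# inputs whose extents or spacing differ. Voxel indices are 1-based (R arrays);
# no world coordinates are carried.
# ---------------------------------------------------------------------------

#' Construct a subject volume image
#'
#' A `voxel_image` is a 3D scalar lattice (e.g. a Jacobian-modulated
#' gray-matter map, in which voxel values reflect regional tissue volume)
#' together with its grid spacing in mm and a subject identifier.
#'
#' @param data 3D numeric array; tissue maps are nonnegative.
#' @param spacing numeric length-3, voxel edge length per axis in mm.
#' @param subject_id character scalar.
#' @param tissue `"gray"` or `"white"`.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(data, spacing = c(1, 1, 1), subject_id = "subject",
                        tissue = c("gray", "white")) {
  tissue <- match.arg(tissue)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three axis extents must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive edge lengths in mm")
  structure(
    list(data = data, spacing = spacing,
         subject_id = as.character(subject_id), tissue = tissue),
    class = "voxel_image"
  )
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("<voxel_image> %s (%s matter): %s voxels @ %s mm\n",
              x$subject_id, x$tissue,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Construct a brain mask
#'
#' @param data 3D logical (or coercible) array congruent with the images it
#'   will mask.
#' @param spacing voxel edge lengths in mm.
#' @return An object of class `brain_mask` with an `n_voxels` field.
#' @export
brain_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask `data` must be a 3D array")
  data <- array(as.logical(data), dim(data))
  if (anyNA(data)) stop("mask contains undefined values")
  n <- sum(data)
  if (n < 1L) stop("mask must contain at least one voxel")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(data = data, spacing = spacing, n_voxels = n),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s grid, %d voxels in mask\n",
              paste(dim(x$data), collapse = "x"), x$n_voxels))
  invisible(x)
}

#' Construct a named set of ROI masks
#'
#' @param labels named list of 3D logical arrays, one per region (e.g.
#'   `"L_SPL"`, `"R_OFC"`, `"L_amygdala"`). Names must be unique.
#' @param mask optional `brain_mask`; every ROI must lie within it.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(labels, mask = NULL) {
  if (!is.list(labels) || is.null(names(labels)) ||
      anyDuplicated(names(labels)) || any(names(labels) == ""))
    stop("`labels` must be a list with unique, non-empty names")
  labels <- lapply(labels, function(l) {
    if (!is.array(l) || length(dim(l)) != 3L) stop("each ROI must be a 3D array")
    array(as.logical(l), dim(l))
  })
  d <- dim(labels[[1L]])
  for (l in labels)
    if (!identical(dim(l), d)) stop("ROI grids differ in extent")
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "brain_mask"))
    if (!identical(dim(mask$data), d)) stop("ROI grid does not match mask grid")
    for (nm in names(labels))
      if (any(labels[[nm]] & !mask$data))
        stop(sprintf("ROI '%s' extends outside the brain mask", nm))
  }
  structure(list(labels = labels), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  sizes <- vapply(x$labels, sum, numeric(1))
  cat(sprintf("<roi_set> %d regions: %s\n", length(x$labels),
              paste(sprintf("%s(%d)", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

# congruence: identical extents, spacing equal to float tolerance
check_congruent <- function(a_dim, a_spacing, b_dim, b_spacing, what = "inputs") {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop(sprintf("%s have different grid extents (%s vs %s)", what,
                 paste(a_dim, collapse = "x"), paste(b_dim, collapse = "x")))
  if (max(abs(a_spacing - b_spacing)) > 1e-6)
    stop(sprintf("%s have different voxel spacing", what))
  invisible(TRUE)
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file into a [voxel_image]. Multi-frame (4D) inputs are
#' rejected: the pipeline operates on one 3D map per subject.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param subject_id,tissue stored on the returned image; `subject_id`
#'   defaults to the file name without extension.
#' @return A [voxel_image].
#' @export
read_volume <- function(path, subject_id = NULL, tissue = "gray") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("non-3D input: %s has %d dimensions", path, length(d)))
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  voxel_image(array(as.numeric(img), d), spacing = RNifti::pixdim(img),
              subject_id = subject_id, tissue = tissue)
}

#' Write a volume, mask, or 3D array as NIfTI
#'
#' @param x a [voxel_image], [brain_mask], or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing, used only when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing = c(1, 1, 1)) {
  if (inherits(x, "voxel_image")) {
    arr <- x$data; spacing <- x$spacing
  } else if (inherits(x, "brain_mask")) {
    arr <- array(as.integer(x$data), dim(x$data)); spacing <- x$spacing
  } else if (is.array(x) && length(dim(x)) == 3L) {
    arr <- x
  } else stop("cannot write object of this type as a NIfTI volume")
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- spacing
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read an ROI label volume plus its text legend
#'
#' The label image holds one integer per region; the legend is a two-column
#' whitespace- or comma-delimited text file mapping names to integers.
#'
#' @param path NIfTI label image.
#' @param legend_path text file with columns `name`, `value`.
#' @return A [roi_set].
#' @export
read_roi_labels <- function(path, legend_path) {
  img <- read_volume(path, tissue = "gray")
  if (!file.exists(legend_path)) stop(sprintf("legend not found: %s", legend_path))
  leg <- utils::read.table(legend_path, header = FALSE, sep = "",
                           col.names = c("name", "value"),
                           stringsAsFactors = FALSE)
  labels <- lapply(seq_len(nrow(leg)), function(i)
    img$data == leg$value[i])
  names(labels) <- leg$name
  roi_set(labels)
}

#' Down-sample a volume by block averaging
#'
#' Each output voxel is the mean of the input voxels it covers, which
#' preserves total tissue amount for modulated maps. The target edge must be
#' an integer multiple of the source spacing on each axis; partial blocks at
#' the far edge of an axis are averaged over the voxels they cover.
#'
#' @param img a [voxel_image].
#' @param target_edge output voxel edge length in mm (applied isotropically).
#' @return A [voxel_image] at the coarser grid.
#' @export
downsample <- function(img, target_edge) {
  stopifnot(inherits(img, "voxel_image"))
  if (target_edge < max(img$spacing) - 1e-9)
    stop("target_edge must be >= the source voxel spacing on every axis")
  f <- target_edge / img$spacing
  if (any(abs(f - round(f)) > 1e-6))
    stop("target_edge must be an integer multiple of the source spacing")
  f <- as.integer(round(f))
  arr <- img$data
  for (ax in 1:3) {
    arr <- block_mean_axis(arr, f[ax], ax)
  }
  voxel_image(arr, spacing = rep(target_edge, 3L),
              subject_id = img$subject_id, tissue = img$tissue)
}

# mean over consecutive groups of `f` planes along axis `ax`;
# the trailing partial group is averaged over its covered planes
block_mean_axis <- function(arr, f, ax) {
  if (f == 1L) return(arr)
  d <- dim(arr)
  n <- d[ax]
  g <- rep(seq_len(ceiling(n / f)), each = f)[seq_len(n)]
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  s <- rowsum(m, group = g, reorder = TRUE)
  cnt <- as.numeric(rowsum(rep(1, n), group = g, reorder = TRUE))
  s <- s / cnt
  out_d <- c(length(cnt), d[perm][-1L])
  aperm(array(s, out_d), order(perm))
}

#' Down-sample a mask or ROI set by coverage
#'
#' An output voxel is in the mask when at least `min_coverage` of the source
#' voxels it covers are.
#'
#' @param mask a [brain_mask].
#' @param target_edge output edge length in mm.
#' @param min_coverage fraction in (0, 1]; default 0.5.
#' @return A [brain_mask] on the coarser grid.
#' @export
downsample_mask <- function(mask, target_edge, min_coverage = 0.5) {
  stopifnot(inherits(mask, "brain_mask"))
  img <- voxel_image(array(as.numeric(mask$data), dim(mask$data)),
                     spacing = mask$spacing)
  cov <- downsample(img, target_edge)
  brain_mask(cov$data >= min_coverage, spacing = cov$spacing)
}

#' Vectorize images over a mask
#'
#' Builds the subjects-by-voxels matrix used by the multivariate stage.
#' Columns follow R's column-major raster order of the mask's true voxels,
#' and the recorded linear index maps any feature back to its lattice
#' coordinates.
#'
#' @param imgs a [voxel_image] or list of congruent [voxel_image]s.
#' @param mask a [brain_mask] congruent with the images.
#' @return list with `X` (subjects x voxels matrix, rownames = subject ids),
#'   `voxel_index` (linear indices into the lattice), `dim`, `spacing`.
#' @export
vectorize <- function(imgs, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  if (inherits(imgs, "voxel_image")) imgs <- list(imgs)
  idx <- which(mask$data)
  X <- matrix(NA_real_, nrow = length(imgs), ncol = length(idx))
  ids <- character(length(imgs))
  for (i in seq_along(imgs)) {
    im <- imgs[[i]]
    stopifnot(inherits(im, "voxel_image"))
    check_congruent(dim(im$data), im$spacing, dim(mask$data), mask$spacing,
                    sprintf("image '%s' and mask", im$subject_id))
    X[i, ] <- im$data[idx]
    ids[i] <- im$subject_id
  }
  if (anyNA(X)) stop("undefined values inside the analysis mask")
  rownames(X) <- ids
  list(X = X, voxel_index = idx, dim = dim(mask$data), spacing = mask$spacing)
}

#' Map a feature vector back onto the lattice
#'
#' Inverse of [vectorize] on masked voxels; unmasked voxels are `fill`.
#'
#' @param values numeric vector, one value per mask voxel.
#' @param vec the list returned by [vectorize] (or a [brain_mask]).
#' @param fill value outside the mask (default `NA`).
#' @return 3D array.
#' @export
devectorize <- function(values, vec, fill = NA_real_) {
  if (inherits(vec, "brain_mask"))
    vec <- list(voxel_index = which(vec$data), dim = dim(vec$data))
  if (length(values) != length(vec$voxel_index))
    stop("length of `values` does not match the number of mask voxels")
  out <- array(fill, vec$dim)
  out[vec$voxel_index] <- values
  out
}
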