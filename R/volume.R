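#' 3-D scalar image volume
#'
#' A `scalar_volume` holds a 3-D array of real intensities together with its
#' grid geometry: per-axis voxel spacing in mm and a 4x4 affine mapping
#' 0-based voxel indices (i, j, k) to world coordinates in mm (the NIfTI
#' convention). Anisotropic grids (e.g. 0.1 x 0.1 x 0.5 mm acquisitions) are
#' fully supported.
#'
#' @param data 3-D numeric array of intensities.
#' @param spacing Per-axis voxel size in mm (length 3, strictly positive).
#'   Ignored when `affine` is supplied (it is then derived from the affine).
#' @param affine 4x4 voxel-index-to-world matrix. Defaults to an axis-aligned
#'   mapping with the volume centred on the world origin.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as_volume_array(data)
  g <- make_grid(dim(data), spacing, affine)
  v <- structure(list(data = data, spacing = g$spacing, affine = g$affine),
                 class = c("scalar_volume", "volume"))
  validate_volume(v)
  v
}

#' 3-D integer label volume
#'
#' Shares the grid model of [scalar_volume()] but holds non-negative integer
#' region labels; 0 is background. Resampling a label volume always uses
#' nearest-neighbour interpolation so no new label ids can be created.
#'
#' @inheritParams scalar_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as_volume_array(data)
  if (max(abs(data - round(data))) > 1e-6)
    stop("label volume data must be integral", call. = FALSE)
  if (min(data) < 0)
    stop("label volume data must be non-negative", call. = FALSE)
  storage.mode(data) <- "integer"
  g <- make_grid(dim(data), spacing, affine)
  v <- structure(list(data = data, spacing = g$spacing, affine = g$affine),
                 class = c("label_volume", "volume"))
  validate_volume(v)
  v
}

as_volume_array <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("volume data must be a 3-D array", call. = FALSE)
  if (!is.numeric(data)) stop("volume data must be numeric", call. = FALSE)
  data
}

make_grid <- function(dim, spacing, affine) {
  dim <- as.integer(dim)
  if (is.null(affine)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- -(dim - 1) / 2 * spacing
  } else {
    affine <- as.matrix(affine)
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive", call. = FALSE)
  if (abs(det(affine)) < 1e-12) stop("grid affine must be invertible", call. = FALSE)
  list(dim = dim, spacing = spacing, affine = affine)
}

validate_volume <- function(v) {
  if (anyNA(v$data)) stop("volume data contains NA/NaN", call. = FALSE)
  invisible(v)
}

#' @export
print.volume <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label_volume" else "scalar_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  if (inherits(x, "label_volume"))
    cat("labels:", paste(labels_present(x), collapse = " "), "\n")
  invisible(x)
}

#' Grid specification
#'
#' Describes a target sampling grid (dimensions, spacing, affine) without
#' data, e.g. the 256x256x225 / 0.1 mm isotropic template grid.
#'
#' @param dim Integer voxel counts, length 3.
#' @inheritParams scalar_volume
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(dim, spacing = c(1, 1, 1), affine = NULL) {
  g <- make_grid(dim, spacing, affine)
  structure(g, class = "grid_spec")
}

#' @rdname grid_spec
#' @param x A volume or grid_spec.
#' @export
as_grid <- function(x) {
  if (inherits(x, "grid_spec")) return(x)
  if (inherits(x, "volume"))
    return(structure(list(dim = dim(x$data), spacing = x$spacing,
                          affine = x$affine), class = "grid_spec"))
  if (inherits(x, "deformation_field"))
    return(structure(list(dim = dim(x$displacement)[1:3], spacing = x$spacing,
                          affine = x$affine), class = "grid_spec"))
  stop("cannot interpret object as a grid", call. = FALSE)
}

#' Default template grid
#'
#' The high-resolution reference grid used for rat-brain template
#' construction: 256 x 256 x 225 voxels at 0.1 mm isotropic.
#' @return A [grid_spec()].
#' @export
default_template_grid <- function() grid_spec(c(256L, 256L, 225L), rep(0.1, 3))

grids_equal <- function(a, b, tol = 1e-6) {
  a <- as_grid(a); b <- as_grid(b)
  identical(a$dim, b$dim) && max(abs(a$affine - b$affine)) <= tol
}

#' Convert voxel indices to world coordinates (mm)
#'
#' @param grid A volume or [grid_spec()].
#' @param idx N x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @return N x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, idx) {
  g <- as_grid(grid)
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(idx %*% t(g$affine[1:3, 1:3]), 2, g$affine[1:3, 4], "+")
}

#' @rdname voxel_to_world
#' @param pts N x 3 matrix of world coordinates in mm.
#' @export
world_to_voxel <- function(grid, pts) {
  g <- as_grid(grid)
  inv <- solve(g$affine)
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")
}

# 0-based index coordinates of every voxel (optionally strided), as an N x 3
# matrix ordered like the flattened array.
grid_index_matrix <- function(dim, stride = 1L) {
  ix <- seq(0L, dim[1] - 1L, by = stride)
  iy <- seq(0L, dim[2] - 1L, by = stride)
  iz <- seq(0L, dim[3] - 1L, by = stride)
  cbind(rep(ix, times = length(iy) * length(iz)),
        rep(rep(iy, each = length(ix)), times = length(iz)),
        rep(iz, each = length(ix) * length(iy)))
}

#' Labels present in a label volume
#'
#' @param vol A [label_volume()].
#' @param include_background Keep 0 in the returned set?
#' @return Sorted integer vector of label ids.
#' @export
labels_present <- function(vol, include_background = FALSE) {
  stopifnot(inherits(vol, "label_volume"))
  l <- sort(unique(as.integer(vol$data)))
  if (!include_background) l <- l[l != 0L]
  l
}

#' Read a volume from a NIfTI-1 file
#'
#' Grid metadata (shape, spacing, affine) is taken from the header's sform.
#' With `kind = "label"` non-integral voxel values are rejected.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind `"scalar"` or `"label"`.
#' @return A [scalar_volume()] or [label_volume()].
#' @export
read_volume <- function(path, kind = c("scalar", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop("expected a 3-D volume in ", path, call. = FALSE)
  a <- array(as.numeric(a), dim(a))  # drop niftiImage attributes
  aff <- unclass(RNifti::xform(img))
  aff <- matrix(as.numeric(aff[1:4, 1:4]), 4, 4)
  if (kind == "label") {
    if (max(abs(a - round(a))) > 1e-6)
      stop("label file contains non-integral values: ", path, call. = FALSE)
    label_volume(round(a), affine = aff)
  } else {
    storage.mode(a) <- "double"
    scalar_volume(a, affine = aff)
  }
}

#' Write a volume to a NIfTI-1 file
#'
#' @param vol A [scalar_volume()] or [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume"))
  dt <- if (inherits(vol, "label_volume")) "int16" else "double"
  img <- RNifti::asNifti(vol$data, datatype = dt)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a region label lookup table
#'
#' The lookup table is a 2-column tab-separated file `label_id<TAB>region_name`
#' with a header line. Label ids must be unique positive integers.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `label_id` and `region_name`.
#' @export
read_label_lut <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lut <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(lut) <- c("label_id", "region_name")
  lut$label_id <- as.integer(lut$label_id)
  if (anyDuplicated(lut$label_id) || any(lut$label_id <= 0))
    stop("label ids must be unique positive integers", call. = FALSE)
  lut
}

#' @rdname read_label_lut
#' @param lut A lookup-table data.frame.
#' @export
write_label_lut <- function(lut, path) {
  utils::write.table(lut[, c("label_id", "region_name")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default 27-region rat-brain lookup table
#'
#' The standard 27-region nomenclature (Paxinos-style, bilateral cortical and
#' subcortical structures, ventricles and white matter) shipped with the
#' package.
#' @return A data.frame with columns `label_id` and `region_name`.
#' @export
default_label_lut <- function() {
  read_label_lut(system.file("extdata", "region_lut.tsv", package = "atlasseg",
                             mustWork = TRUE))
}

#' Resample a volume onto a target grid
#'
#' Pull-back resampling: `transform` maps world points of the target grid
#' into the source volume's world space; each output voxel is a single
#' interpolated read of the source. Voxels mapping outside the source field
#' of view are filled with 0 (background). Label volumes must use
#' nearest-neighbour interpolation so that no new label values appear.
#'
#' @param vol Source [scalar_volume()] or [label_volume()].
#' @param grid Target grid: a [grid_spec()] or a volume whose grid is used.
#' @param transform A transform (linear, deformation field, or chain) mapping
#'   target world points to source world points. Defaults to identity.
#' @param interp `"auto"` (trilinear for scalars, nearest for labels),
#'   `"trilinear"`, or `"nearest"`.
#' @return A volume of the same kind on the target grid.
#' @export
resample <- function(vol, grid, transform = identity_transform(),
                     interp = c("auto", "trilinear", "nearest")) {
  stopifnot(inherits(vol, "volume"))
  interp <- match.arg(interp)
  is_label <- inherits(vol, "label_volume")
  if (interp == "auto") interp <- if (is_label) "nearest" else "trilinear"
  if (is_label && interp != "nearest")
    stop("label volumes must be resampled with nearest-neighbour interpolation",
         call. = FALSE)
  g <- as_grid(grid)
  idx <- grid_index_matrix(g$dim)
  pts <- voxel_to_world(g, idx)
  pts <- apply_transform(transform, pts)
  src <- world_to_voxel(vol, pts)
  method <- if (interp == "nearest") 0L else 1L
  vals <- cpp_sample(as.numeric(vol$data), dim(vol$data), src, method, 0, 0L)
  arr <- array(vals, g$dim)
  if (is_label) label_volume(round(arr), affine = g$affine)
  else scalar_volume(arr, affine = g$affine)
}

#' Gaussian smoothing of a scalar volume
#'
#' Smooths with a separable Gaussian kernel specified by its full width at
#' half maximum in mm per axis (sigma = fwhm / (2 sqrt(2 ln 2)), converted to
#' voxels through the grid spacing). Boundaries are handled by reflective
#' padding, which conserves the mean intensity.
#'
#' @param vol A [scalar_volume()].
#' @param fwhm_mm Per-axis FWHM in mm (scalar or length 3, non-negative).
#' @return The smoothed [scalar_volume()].
#' @export
gaussian_blur <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "scalar_volume"))
  fwhm_mm <- as.numeric(fwhm_mm)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  if (any(fwhm_mm < 0)) stop("fwhm must be non-negative", call. = FALSE)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$spacing
  if (all(sigma_vox == 0)) return(vol)
  arr <- cpp_blur3(as.numeric(vol$data), dim(vol$data), sigma_vox)
  scalar_volume(array(arr, dim(vol$data)), affine = vol$affine)
}

# FWHM-to-sigma conversion constant (2 sqrt(2 ln 2))
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
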