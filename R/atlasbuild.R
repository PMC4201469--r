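#' Multi-atlas dataset
#'
#' A collection of individual atlases: paired anatomical MRI and label
#' volumes sharing one grid per entry, with a common label lookup table.
#'
#' @param entries List of `list(id =, mri =, labels =)` entries.
#' @param lut Label lookup table (data.frame `label_id`, `region_name`);
#'   defaults to the shipped 27-region table.
#' @return An `atlas_set`.
#' @export
atlas_set <- function(entries, lut = default_label_lut()) {
  stopifnot(length(entries) >= 1L)
  ids <- vapply(entries, function(e) as.character(e$id), character(1))
  if (anyDuplicated(ids)) stop("atlas ids must be unique", call. = FALSE)
  for (e in entries) {
    stopifnot(inherits(e$mri, "scalar_volume"), inherits(e$labels, "label_volume"))
    if (!grids_equal(e$mri, e$labels))
      stop("each entry's MRI and labels must share one grid", call. = FALSE)
    unknown <- setdiff(labels_present(e$labels), lut$label_id)
    if (length(unknown))
      stop("labels not in lookup table: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  names(entries) <- ids
  structure(list(entries = entries, lut = lut), class = "atlas_set")
}

#' @export
print.atlas_set <- function(x, ...) {
  cat(sprintf("<atlas_set> %d atlases: %s\n", length(x$entries),
              paste(names(x$entries), collapse = ", ")))
  invisible(x)
}

#' Construct a population MRI template
#'
#' Affinely registers every input MRI to the current target, resamples them
#' onto the output grid, normalizes each co-registered image by its
#' foreground mean intensity and averages voxelwise. The procedure is
#' repeated `iterations` times with the previous average as the new target
#' (the default of 2 corresponds to an initial pass plus one repeat, after
#' which further passes give no improvement).
#'
#' @param mris Named list of at least two [scalar_volume()]s.
#' @param initial_target The MRI (or its name in `mris`) used as target of
#'   the first pass, typically the highest-resolution individual.
#' @param grid Output [grid_spec()]; defaults to the 256x256x225 / 0.1 mm
#'   template grid.
#' @param iterations Number of register-and-average passes.
#' @param ... Passed to [register_linear()].
#' @return A `template_space`: `$template` ([scalar_volume()]) and
#'   `$transforms` (named list of pull-back template-to-individual
#'   transforms).
#' @export
build_template <- function(mris, initial_target = 1L,
                           grid = default_template_grid(), iterations = 2L,
                           ...) {
  if (length(mris) < 2L)
    stop("template construction needs at least two MRIs", call. = FALSE)
  if (is.null(names(mris)))
    names(mris) <- sprintf("mri%02d", seq_along(mris))
  target <- if (inherits(initial_target, "scalar_volume")) initial_target
            else mris[[initial_target]]
  target <- resample(target, grid)
  transforms <- NULL
  for (iter in seq_len(iterations)) {
    transforms <- lapply(mris, function(m)
      register_linear(m, target, kind = "affine", ...))
    resampled <- mapply(function(m, t) resample(m, grid, t),
                        mris, transforms, SIMPLIFY = FALSE)
    normed <- lapply(resampled, normalize_foreground_mean)
    avg <- Reduce(`+`, lapply(normed, function(v) v$data)) / length(normed)
    target <- scalar_volume(avg, affine = as_grid(grid)$affine)
  }
  structure(list(template = target, transforms = transforms),
            class = "template_space")
}

# Divide a volume by its mean over the foreground mask (voxels above 5% of
# the maximum), making co-registered individuals comparable before averaging.
normalize_foreground_mean <- function(vol) {
  m <- vol$data > 0.05 * max(vol$data)
  mu <- if (any(m)) mean(vol$data[m]) else mean(vol$data)
  if (mu == 0) return(vol)
  scalar_volume(vol$data / mu, affine = vol$affine)
}

#' @export
print.template_space <- function(x, ...) {
  g <- as_grid(x$template)
  cat(sprintf("<template_space> grid %s @ %s mm, %d transforms\n",
              paste(g$dim, collapse = "x"),
              paste(signif(g$spacing, 3), collapse = "x"),
              length(x$transforms)))
  invisible(x)
}

#' Majority-vote label fusion
#'
#' Per voxel, selects the most frequent label across the input volumes
#' (maximum-probability decision fusion of hard labels). Background (0)
#' competes as an ordinary label. Ties are resolved deterministically:
#' among the labels with maximal count, a nonzero label is preferred over
#' background, and among nonzero labels the smallest id wins.
#'
#' @param label_volumes List of [label_volume()]s on one common grid.
#' @return The fused [label_volume()].
#' @export
fuse_labels <- function(label_volumes) {
  stopifnot(length(label_volumes) >= 1L)
  ref <- label_volumes[[1L]]
  for (v in label_volumes) {
    stopifnot(inherits(v, "label_volume"))
    if (!grids_equal(v, ref))
      stop("all label volumes must share one grid", call. = FALSE)
  }
  m <- vapply(label_volumes, function(v) as.integer(v$data),
              integer(length(ref$data)))
  fused <- cpp_label_fuse(matrix(m, ncol = length(label_volumes)))
  label_volume(array(fused, dim(ref$data)), affine = ref$affine)
}

#' Create a maximum-probability atlas in template space
#'
#' Resamples each atlas's label volume onto the template grid through its
#' MRI's transform (nearest neighbour, so labels are preserved), then fuses
#' them with the majority-vote rule of [fuse_labels()].
#'
#' @param atlases An [atlas_set()].
#' @param space A `template_space` from [build_template()] whose
#'   `$transforms` contains every atlas id.
#' @return The maximum-probability [label_volume()] on the template grid.
#' @export
build_max_probability_atlas <- function(atlases, space) {
  stopifnot(inherits(atlases, "atlas_set"), inherits(space, "template_space"))
  ids <- names(atlases$entries)
  missing <- setdiff(ids, names(space$transforms))
  if (length(missing))
    stop("no template transform for atlas id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  grid <- as_grid(space$template)
  moved <- lapply(ids, function(id)
    resample(atlases$entries[[id]]$labels, grid,
             space$transforms[[id]], interp = "nearest"))
  fuse_labels(moved)
}
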