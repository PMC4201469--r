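#' Automated atlas-based segmentation
#'
#' The three automated strategies share one machinery:
#'
#' * **MP** (maximum probability): the subject MRI is registered to the MRI
#'   template (affine then non-linear); the inverse transformation (exact
#'   matrix inverse of the linear part, fixed-point inversion of the
#'   deformation field) carries the maximum-probability atlas back onto the
#'   subject grid with nearest-neighbour resampling.
#' * **SA** (single atlas): identical pathway, but propagating one
#'   individual's label volume instead of the fused atlas.
#' * **PF** (propagation-fusion): every atlas MRI is registered (affine then
#'   non-linear) directly onto the subject; the atlas label volumes are
#'   resampled (nearest neighbour) into subject space and fused by the
#'   majority-vote rule.
#'
#' All results live on the subject grid and carry provenance sufficient to
#' replay the label propagation.
#'
#' @param subject_mri The subject's [scalar_volume()].
#' @param space A `template_space` from [build_template()].
#' @param mp_atlas Maximum-probability [label_volume()] on the template grid.
#' @param schedule [nl_schedule()] for the non-linear stage.
#' @param chain Optional precomputed subject-to-template registration chain
#'   (as returned by the MP/SA pathway itself); when supplied the
#'   registration is skipped, which allows SA and MP to share one
#'   registration of the same subject.
#' @param seed Reproducibility seed.
#' @param ... Passed to [register_linear()].
#' @return A `segmentation_result`: `$labels` ([label_volume()] on the
#'   subject grid), `$method`, and `$provenance` (transforms and atlas ids).
#' @export
segment_mp <- function(subject_mri, space, mp_atlas, schedule = nl_schedule(),
                       chain = NULL, seed = 0L, ...) {
  segment_template_pathway(subject_mri, space, mp_atlas, method = "MP",
                           schedule = schedule, chain = chain, seed = seed, ...)
}

#' @rdname segment_mp
#' @param single_atlas One individual's [label_volume()] on the template
#'   grid.
#' @export
segment_sa <- function(subject_mri, space, single_atlas,
                       schedule = nl_schedule(), chain = NULL, seed = 0L, ...) {
  segment_template_pathway(subject_mri, space, single_atlas, method = "SA",
                           schedule = schedule, chain = chain, seed = seed, ...)
}

segment_template_pathway <- function(subject_mri, space, atlas_labels, method,
                                     schedule, chain, seed, ...) {
  stopifnot(inherits(subject_mri, "scalar_volume"),
            inherits(space, "template_space"),
            inherits(atlas_labels, "label_volume"))
  if (!grids_equal(atlas_labels, space$template))
    stop("atlas label volume must be on the template grid", call. = FALSE)
  if (is.null(chain)) {
    aff <- register_linear(subject_mri, space$template, kind = "affine",
                           seed = seed, ...)
    chain <- register_nonlinear(subject_mri, space$template,
                                schedule = schedule, init = aff, seed = seed)
  }
  inv_chain <- invert(chain)
  labels <- resample(atlas_labels, as_grid(subject_mri), inv_chain,
                     interp = "nearest")
  structure(list(labels = labels, method = method,
                 provenance = list(chain = chain, seed = seed,
                                   atlas = method)),
            class = "segmentation_result")
}

#' @rdname segment_mp
#' @param atlases An [atlas_set()] to propagate and fuse (PF method).
#' @param on_failure `"abort"` (default) or `"skip"`: policy when a single
#'   atlas registration fails. Aborting is the default so that silent atlas
#'   loss cannot bias the fusion.
#' @export
segment_pf <- function(subject_mri, atlases, schedule = nl_schedule(),
                       on_failure = c("abort", "skip"), seed = 0L, ...) {
  on_failure <- match.arg(on_failure)
  stopifnot(inherits(subject_mri, "scalar_volume"), inherits(atlases, "atlas_set"))
  grid <- as_grid(subject_mri)
  moved <- list()
  used <- character(0)
  for (id in names(atlases$entries)) {
    e <- atlases$entries[[id]]
    res <- tryCatch({
      aff <- register_linear(e$mri, subject_mri, kind = "affine",
                             seed = seed, ...)
      ch <- register_nonlinear(e$mri, subject_mri, schedule = schedule,
                               init = aff, seed = seed)
      resample(e$labels, grid, ch, interp = "nearest")
    }, error = function(err) err)
    if (inherits(res, "error")) {
      if (on_failure == "abort")
        stop("registration of atlas '", id, "' failed: ",
             conditionMessage(res), call. = FALSE)
      next
    }
    moved[[id]] <- res
    used <- c(used, id)
  }
  if (!length(moved))
    stop("no atlas could be propagated", call. = FALSE)
  labels <- fuse_labels(moved)
  structure(list(labels = labels, method = "PF",
                 provenance = list(atlas_ids = used, seed = seed)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> method %s, %d labels\n", x$method,
              length(labels_present(x$labels))))
  invisible(x)
}
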