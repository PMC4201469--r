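#' PET study container
#'
#' A PET activity image (kBq/mL) together with the injection metadata needed
#' for standardized-uptake-value conversion.
#'
#' @param pet [scalar_volume()] of activity concentration in kBq/mL.
#' @param injected_dose_mbq Injected dose in MBq (> 0).
#' @param body_weight_g Body weight in g (> 0).
#' @param subject_id Subject identifier.
#' @return A `pet_study`.
#' @export
pet_study <- function(pet, injected_dose_mbq, body_weight_g,
                      subject_id = "subject") {
  stopifnot(inherits(pet, "scalar_volume"))
  if (!is.numeric(injected_dose_mbq) || injected_dose_mbq <= 0)
    stop("injected dose must be positive", call. = FALSE)
  if (!is.numeric(body_weight_g) || body_weight_g <= 0)
    stop("body weight must be positive", call. = FALSE)
  structure(list(pet = pet, injected_dose_mbq = injected_dose_mbq,
                 body_weight_g = body_weight_g, subject_id = subject_id),
            class = "pet_study")
}

#' Convert a PET study to standardized uptake values
#'
#' `SUV = concentration [kBq/mL] * body_weight [g] / injected_dose [kBq]`,
#' assuming 1 g of tissue occupies 1 mL. A uniform concentration equal to
#' dose/weight therefore maps to SUV 1 everywhere.
#'
#' @param study A [pet_study()].
#' @return A unitless SUV [scalar_volume()] on the PET grid.
#' @export
suv_convert <- function(study) {
  stopifnot(inherits(study, "pet_study"))
  scalar_volume(study$pet$data * study$body_weight_g /
                  (study$injected_dose_mbq * 1000),
                affine = study$pet$affine)
}

#' Regional means of an SUV volume
#'
#' Unweighted arithmetic mean of the SUV voxels inside each label of an
#' atlas resliced into PET space. Labels are moved, never activity values,
#' so the extraction is exact. Regions listed in the lookup table but absent
#' from the atlas produce flagged zero-count rows.
#'
#' @param suv_vol SUV [scalar_volume()].
#' @param atlas_in_pet_space [label_volume()] on the same grid.
#' @param lut Optional lookup table naming the regions.
#' @return Data.frame with `label_id`, `region_name`, `mean_suv`,
#'   `n_voxels`.
#' @export
extract_regional <- function(suv_vol, atlas_in_pet_space, lut = NULL) {
  stopifnot(inherits(suv_vol, "scalar_volume"),
            inherits(atlas_in_pet_space, "label_volume"))
  if (!grids_equal(suv_vol, atlas_in_pet_space))
    stop("SUV volume and atlas must share one grid", call. = FALSE)
  present <- labels_present(atlas_in_pet_space)
  labs <- if (is.null(lut)) present else lut$label_id
  nm <- if (is.null(lut)) as.character(labs)
        else lut$region_name[match(labs, lut$label_id)]
  lv <- as.integer(atlas_in_pet_space$data)
  sv <- as.numeric(suv_vol$data)
  rows <- lapply(seq_along(labs), function(i) {
    sel <- lv == labs[i]
    n <- sum(sel)
    data.frame(label_id = labs[i], region_name = nm[i],
               mean_suv = if (n > 0) mean(sv[sel]) else NA_real_,
               n_voxels = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Atlas-driven regional PET extraction
#'
#' Extracts regional SUV means through one of four pathways:
#'
#' * `"sa"` / `"mp_with_mri"`: the PET is rigidly registered to the
#'   subject's MRI; this transform is concatenated with the subject's
#'   MRI-to-template (affine + non-linear) registration and the inverse path
#'   carries the single atlas (SA) or maximum-probability atlas (MP) into
#'   PET space.
#' * `"mp_without_mri"`: the PET is registered directly to the MRI template
#'   (affine + non-linear, mutual-information-driven since the pairing is
#'   cross-modality) and the maximum-probability atlas is resliced into PET
#'   space through the inverse.
#' * `"pf"`: propagation-fusion segmentation of the subject MRI, with the
#'   fused labels resliced rigidly into PET space.
#'
#' @param study A [pet_study()].
#' @param mode One of `"sa"`, `"mp_with_mri"`, `"mp_without_mri"`, `"pf"`.
#' @param assets List of pipeline assets: `space` (template space),
#'   `mp_atlas`, `single_atlas`, `atlases` ([atlas_set()]); optionally
#'   `subject_chain` (precomputed subject-MRI-to-template chain),
#'   `pf_labels` (precomputed PF segmentation on the subject grid) and
#'   `pet_to_mri` (precomputed rigid transform) to avoid re-registration.
#' @param subject_mri Subject [scalar_volume()]; required for every mode
#'   except `"mp_without_mri"`.
#' @param schedule [nl_schedule()] for non-linear stages.
#' @param lut Optional region lookup table for the output.
#' @param seed Reproducibility seed.
#' @param ... Passed to [register_linear()].
#' @return Data.frame as [extract_regional()] plus `subject` and `mode`
#'   columns.
#' @export
extract_mode <- function(study, mode = c("sa", "mp_with_mri", "mp_without_mri", "pf"),
                         assets, subject_mri = NULL, schedule = nl_schedule(),
                         lut = NULL, seed = 0L, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(study, "pet_study"))
  if (mode != "mp_without_mri" && is.null(subject_mri))
    stop("subject MRI is required for mode '", mode, "'", call. = FALSE)
  pet_grid <- as_grid(study$pet)
  if (mode == "mp_without_mri") {
    space <- assets$space
    aff <- register_linear(study$pet, space$template, kind = "affine",
                           seed = seed, ...)
    ch <- register_nonlinear(study$pet, space$template, schedule = schedule,
                             init = aff, metric = "mi", seed = seed)
    atlas_pet <- resample(assets$mp_atlas, pet_grid, invert(ch),
                          interp = "nearest")
  } else {
    rig <- assets$pet_to_mri
    if (is.null(rig))
      rig <- register_linear(study$pet, subject_mri, kind = "rigid",
                             seed = seed, ...)
    # rig maps MRI world -> PET world (pull-back of registering PET to MRI)
    if (mode == "pf") {
      labs <- assets$pf_labels
      if (is.null(labs))
        labs <- segment_pf(subject_mri, assets$atlases, schedule = schedule,
                           seed = seed, ...)$labels
      atlas_pet <- resample(labs, pet_grid, invert(rig), interp = "nearest")
    } else {
      chain <- assets$subject_chain
      if (is.null(chain)) {
        aff <- register_linear(subject_mri, assets$space$template,
                               kind = "affine", seed = seed, ...)
        chain <- register_nonlinear(subject_mri, assets$space$template,
                                    schedule = schedule, init = aff,
                                    seed = seed)
      }
      atlas <- if (mode == "sa") assets$single_atlas else assets$mp_atlas
      pet_to_template <- compose(invert(rig), invert(chain))
      atlas_pet <- resample(atlas, pet_grid, pet_to_template,
                            interp = "nearest")
    }
  }
  out <- extract_regional(suv_convert(study), atlas_pet, lut = lut)
  out$subject <- study$subject_id
  out$mode <- mode
  out
}

#' Agreement regression between automated and manual SUV tables
#'
#' Ordinary least squares of automated regional SUV means on the manual
#' (reference) means, matched by region (and subject when present).
#'
#' @param auto,manual Data.frames with columns `label_id`, `mean_suv` and
#'   optionally `subject`.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
agreement_regression <- function(auto, manual) {
  by <- intersect(c("subject", "label_id"), intersect(names(auto), names(manual)))
  m <- merge(auto, manual, by = by, suffixes = c("_auto", "_manual"))
  m <- m[is.finite(m$mean_suv_auto) & is.finite(m$mean_suv_manual), ]
  if (nrow(m) < 3L)
    stop("agreement regression needs at least three shared regions",
         call. = FALSE)
  fit <- lm(mean_suv_auto ~ mean_suv_manual, data = m)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n = nrow(m))
}
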