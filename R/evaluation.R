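#' Per-region overlap counts
#'
#' Exact voxel counts of the reference (manual) mask, the automated mask and
#' their intersection for one label, plus the voxel volume in mm^3. These
#' counts are the sufficient statistics for the morphometric metrics.
#'
#' @param reference,automated [label_volume()]s on identical grids.
#' @param label_id Region label to compare.
#' @return A `region_overlap` list: `label_id`, `n_manual`, `n_automated`,
#'   `n_intersection`, `voxel_volume`.
#' @export
overlap_counts <- function(reference, automated, label_id) {
  stopifnot(inherits(reference, "label_volume"), inherits(automated, "label_volume"))
  if (!grids_equal(reference, automated))
    stop("volumes must share one grid", call. = FALSE)
  rm_ <- reference$data == label_id
  am <- automated$data == label_id
  structure(list(label_id = as.integer(label_id),
                 n_manual = sum(rm_),
                 n_automated = sum(am),
                 n_intersection = sum(rm_ & am),
                 voxel_volume = abs(det(reference$affine[1:3, 1:3]))),
            class = "region_overlap")
}

#' Relative volume difference (signed, percent)
#'
#' `100 * (n_automated - n_manual) / n_manual`: the signed volume bias of the
#' automated delineation relative to the manual reference. Its magnitude
#' (absolute value) is the "volume bias" reported per region.
#'
#' @param counts A `region_overlap` from [overlap_counts()].
#' @return Signed percentage.
#' @export
rvd <- function(counts) {
  stopifnot(inherits(counts, "region_overlap"))
  if (counts$n_manual == 0)
    stop("relative volume difference undefined: empty reference region",
         call. = FALSE)
  100 * (counts$n_automated - counts$n_manual) / counts$n_manual
}

#' Dice similarity index
#'
#' `2 * n_intersection / (n_manual + n_automated)`; ranges from 0 (no
#' overlap) to 1 (complete overlap).
#'
#' @inheritParams rvd
#' @return Dice index in `[0, 1]`.
#' @export
dice <- function(counts) {
  stopifnot(inherits(counts, "region_overlap"))
  denom <- counts$n_manual + counts$n_automated
  if (denom == 0)
    stop("Dice undefined: both masks empty", call. = FALSE)
  2 * counts$n_intersection / denom
}

#' Per-region morphometric report
#'
#' Computes, for every nonzero label present in the reference or the lookup
#' table, the manual volume (mm^3), signed and absolute relative volume
#' difference and Dice index of an automated segmentation, plus a
#' whole-brain row (union of all nonzero labels). Regions absent from the
#' automated segmentation are kept with Dice 0 and rvd -100% and flagged.
#'
#' @param reference Manual [label_volume()].
#' @param automated Automated [label_volume()] on the same grid.
#' @param lut Optional lookup table restricting and naming the regions;
#'   defaults to the labels present in the reference.
#' @param subject,method Provenance columns copied into the report.
#' @return A data.frame with columns `subject`, `method`, `label_id`,
#'   `region_name`, `volume_mm3`, `rvd_pct`, `abs_rvd_pct`, `dice`,
#'   `missing`.
#' @export
morphometric_report <- function(reference, automated, lut = NULL,
                                subject = NA_character_,
                                method = NA_character_) {
  labs <- labels_present(reference)
  if (!is.null(lut)) {
    labs <- intersect(lut$label_id, labs)
    nm <- lut$region_name[match(labs, lut$label_id)]
  } else nm <- as.character(labs)
  rows <- lapply(seq_along(labs), function(i) {
    co <- overlap_counts(reference, automated, labs[i])
    data.frame(subject = subject, method = method, label_id = labs[i],
               region_name = nm[i],
               volume_mm3 = co$n_manual * co$voxel_volume,
               rvd_pct = rvd(co), abs_rvd_pct = abs(rvd(co)),
               dice = dice(co), missing = co$n_automated == 0,
               stringsAsFactors = FALSE)
  })
  wb_ref <- label_volume((reference$data > 0) * 1L, affine = reference$affine)
  wb_auto <- label_volume((automated$data > 0) * 1L, affine = automated$affine)
  co <- overlap_counts(wb_ref, wb_auto, 1L)
  rows <- c(rows, list(data.frame(
    subject = subject, method = method, label_id = NA_integer_,
    region_name = "whole brain",
    volume_mm3 = co$n_manual * co$voxel_volume,
    rvd_pct = rvd(co), abs_rvd_pct = abs(rvd(co)), dice = dice(co),
    missing = co$n_automated == 0, stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

#' Paired comparison of two segmentation methods
#'
#' Paired t-tests per region (and an overall test on per-subject means)
#' between two methods' morphometric reports, with Bonferroni adjustment
#' over regions, plus an F-test comparing the two methods' standard
#' deviations per region. Subjects are paired by the `subject` column.
#'
#' @param report_a,report_b Data.frames from [morphometric_report()] stacked
#'   over subjects, one method each.
#' @param metric Report column to compare (`"dice"` or `"abs_rvd_pct"`).
#' @return Data.frame with columns `region`, `n`, `mean_a`, `mean_b`, `t`,
#'   `p`, `p_bonferroni`, `f`, `f_p`, `degenerate`.
#' @export
compare_methods <- function(report_a, report_b, metric = "dice") {
  key <- function(r) paste(r$subject, r$label_id, r$region_name)
  b_idx <- match(key(report_a), key(report_b))
  if (anyNA(b_idx))
    stop("reports are not paired over identical subjects and regions",
         call. = FALSE)
  report_b <- report_b[b_idx, ]
  regions <- unique(report_a$region_name)
  rows <- lapply(regions, function(rg) {
    sel <- report_a$region_name == rg
    a <- report_a[[metric]][sel]
    b <- report_b[[metric]][sel]
    compare_paired(rg, a, b)
  })
  # overall: per-subject means across regions
  subj <- unique(report_a$subject)
  a_m <- vapply(subj, function(s) mean(report_a[[metric]][report_a$subject == s]),
                numeric(1))
  b_m <- vapply(subj, function(s) mean(report_b[[metric]][report_b$subject == s]),
                numeric(1))
  rows <- c(rows, list(compare_paired("overall", a_m, b_m)))
  out <- do.call(rbind, rows)
  m <- sum(out$region != "overall")
  out$p_bonferroni <- pmin(1, out$p * m)
  out
}

compare_paired <- function(region, a, b) {
  if (length(a) < 2L)
    stop("paired comparison needs at least two subjects", call. = FALSE)
  d <- a - b
  degen <- sd(d) == 0
  if (degen) {
    tt <- list(statistic = if (all(d == 0)) 0 else NA_real_,
               p.value = if (all(d == 0)) 1 else NA_real_)
  } else {
    tt <- t.test(a, b, paired = TRUE)
  }
  ft <- tryCatch(var.test(a, b),
                 error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  data.frame(region = region, n = length(a),
             mean_a = mean(a), mean_b = mean(b),
             t = as.numeric(tt$statistic), p = as.numeric(tt$p.value),
             p_bonferroni = NA_real_,
             f = as.numeric(ft$statistic), f_p = as.numeric(ft$p.value),
             degenerate = degen, stringsAsFactors = FALSE)
}
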