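#' Mutual information between two volumes on one grid
#'
#' Shannon mutual information (in bits) of the joint intensity histogram.
#' With `weighting = "hard"` every voxel contributes to exactly one joint
#' bin, so that `similarity_mi(a, a)` equals the marginal histogram entropy
#' of `a`. `weighting = "linear"` spreads each voxel over the four
#' neighbouring joint bins (partial-volume weighting), the smoother estimator
#' used internally by the linear registration.
#'
#' @param a,b [scalar_volume()]s on identical grids.
#' @param bins Number of histogram bins per axis.
#' @param weighting `"hard"` or `"linear"`.
#' @return Mutual information in bits (non-negative, symmetric in `a`, `b`).
#' @export
similarity_mi <- function(a, b, bins = 32L, weighting = c("hard", "linear")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(a, "scalar_volume"), inherits(b, "scalar_volume"))
  if (!grids_equal(a, b))
    stop("volumes must share one grid", call. = FALSE)
  mi_samples(as.numeric(a$data), as.numeric(b$data), bins = bins,
             arange = range(a$data), brange = range(b$data),
             pv = (weighting == "linear"))
}

# MI in bits from paired intensity samples over stated ranges.
mi_samples <- function(av, bv, bins, arange, brange, pv = TRUE) {
  if (diff(arange) <= 0) arange <- arange + c(-0.5, 0.5)
  if (diff(brange) <= 0) brange <- brange + c(-0.5, 0.5)
  h <- cpp_joint_hist(av, bv, as.integer(bins), arange[1], arange[2],
                      brange[1], brange[2], as.integer(pv))
  p <- h / sum(h)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Cross-correlation between two volumes on one grid
#'
#' Pearson correlation of voxel intensities, optionally restricted to a
#' logical mask. This is the similarity criterion of the non-linear
#' registration stage.
#'
#' @inheritParams similarity_mi
#' @param mask Optional logical array on the same grid.
#' @return Correlation in `[-1, 1]`.
#' @export
similarity_cc <- function(a, b, mask = NULL) {
  stopifnot(inherits(a, "scalar_volume"), inherits(b, "scalar_volume"))
  if (!grids_equal(a, b))
    stop("volumes must share one grid", call. = FALSE)
  av <- as.numeric(a$data); bv <- as.numeric(b$data)
  if (!is.null(mask)) {
    m <- as.logical(mask)
    av <- av[m]; bv <- bv[m]
  }
  if (sd(av) == 0 || sd(bv) == 0)
    stop("degenerate image: constant intensities on the evaluation mask",
         call. = FALSE)
  cor(av, bv)
}
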