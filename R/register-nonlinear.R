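#' Multi-resolution schedule for non-linear registration
#'
#' Pairs per-level image blur (FWHM, mm) with control-point spacing (mm),
#' gradient-ascent iteration counts and target-voxel subsampling strides.
#' The default is a hierarchical 4-level schedule: blur 1.0 / 0.5 / 0.4 /
#' 0.3 mm FWHM with control spacing 1.6 / 0.8 / 0.4 / 0.3 mm.
#'
#' @param fwhm Per-level blur FWHM in mm.
#' @param spacing Per-level control-point spacing in mm.
#' @param iters Per-level maximum iterations.
#' @param stride Per-level target-voxel subsampling stride.
#' @return An `nl_schedule` list.
#' @export
nl_schedule <- function(fwhm = c(1, 0.5, 0.4, 0.3),
                        spacing = c(1.6, 0.8, 0.4, 0.3),
                        iters = c(100L, 100L, 50L, 50L),
                        stride = c(2L, 2L, 1L, 1L)) {
  if (length(stride) == 1L) stride <- rep(stride, length(fwhm))
  if (length(iters) == 1L) iters <- rep(iters, length(fwhm))
  if (length(spacing) != length(fwhm) || length(iters) != length(fwhm) ||
      length(stride) != length(fwhm))
    stop("schedule lists must have equal lengths", call. = FALSE)
  structure(list(fwhm = fwhm, spacing = spacing,
                 iters = as.integer(iters), stride = as.integer(stride)),
            class = "nl_schedule")
}

#' Hierarchical non-linear registration
#'
#' Refines an affine initialization with a dense deformation, optimized over
#' a hierarchy of progressively finer control-point grids. At each level both
#' images are blurred to the level FWHM and the control-point displacements
#' (world mm, trilinearly interpolated between control points) are adjusted
#' by gradient ascent with backtracking line search on the similarity of the
#' target and the warped source, minus a first-order smoothness penalty
#' (squared differences of neighbouring control displacements, weight
#' `lambda`). The similarity is cross-correlation for same-modality pairs
#' (`metric = "cc"`) or partial-volume mutual information for cross-modality
#' pairs (`metric = "mi"`). The finest-level control grid is returned as the
#' deformation field; displacements at arbitrary points are its trilinear
#' interpolation.
#'
#' The result is the chain `[field, init]` in application (pull-back) order:
#' a target point `x` maps to `init(x + d(x))` in source space. The
#' deformation is listed first because points are pulled back through the
#' local refinement before the global linear pose.
#'
#' @param source,target Non-constant [scalar_volume()]s.
#' @param schedule An [nl_schedule()].
#' @param init A `linear_transform` (target-to-source pull-back), normally
#'   the affine stage output. Required.
#' @param lambda Smoothness penalty weight.
#' @param metric `"cc"` or `"mi"`.
#' @param bins Histogram bins for `metric = "mi"`.
#' @param seed Reproducibility seed (the optimizer is deterministic).
#' @return A `transform_chain` with attribute `objective` tracing per-level
#'   start/end values.
#' @export
register_nonlinear <- function(source, target, schedule = nl_schedule(),
                               init = NULL, lambda = 0.01,
                               metric = c("cc", "mi"), bins = 32L, seed = 0L) {
  metric <- match.arg(metric)
  stopifnot(inherits(source, "scalar_volume"), inherits(target, "scalar_volume"))
  if (is.null(init))
    stop("init (affine stage output) is required", call. = FALSE)
  if (inherits(init, "transform_chain")) {
    stopifnot(length(init$transforms) == 1L)
    init <- init$transforms[[1L]]
  }
  stopifnot(inherits(init, "linear_transform"))
  if (sd(source$data) == 0 || sd(target$data) == 0)
    stop("degenerate image: registration requires non-constant intensities",
         call. = FALSE)
  tg <- as_grid(target)
  L3 <- init$matrix[1:3, 1:3]
  Lt <- init$matrix[1:3, 4]
  ctrl <- NULL        # control displacement array (cdim x 3)
  ctrl_aff <- NULL
  trace <- list()
  for (lev in seq_along(schedule$fwhm)) {
    fw <- schedule$fwhm[lev]
    tb <- if (fw > 0) gaussian_blur(target, fw) else target
    sb <- if (fw > 0) gaussian_blur(source, fw) else source
    step_vox <- schedule$spacing[lev] / tg$spacing
    cdim <- pmax(as.integer(floor((tg$dim - 1) / step_vox)) + 2L, 2L)
    caff <- tg$affine
    caff[1:3, 1:3] <- caff[1:3, 1:3] %*% diag(step_vox)
    new_ctrl <- matrix(0, prod(cdim), 3)
    if (!is.null(ctrl)) {
      # carry the coarser solution over: sample old control field at new nodes
      cidx <- grid_index_matrix(cdim)
      w <- sweep(cidx %*% t(caff[1:3, 1:3]), 2, caff[1:3, 4], "+")
      oldinv <- solve(ctrl_aff)
      ov <- sweep(w %*% t(oldinv[1:3, 1:3]), 2, oldinv[1:3, 4], "+")
      odim <- attr(ctrl, "cdim")
      for (c in 1:3)
        new_ctrl[, c] <- cpp_sample(ctrl[, c], odim, ov, 1L, 0, 1L)
    }
    ctrl <- new_ctrl
    attr(ctrl, "cdim") <- cdim
    ctrl_aff <- caff
    st <- schedule$stride[lev]
    idx <- grid_index_matrix(tg$dim, stride = st)
    pts <- voxel_to_world(tg, idx)
    pts_ctrl <- sweep(idx, 2, step_vox, "/")
    tv <- as.numeric(tb$data)[1L + idx[, 1] +
                              tg$dim[1] * (idx[, 2] + tg$dim[2] * idx[, 3])]
    src_inv <- solve(sb$affine)
    BL <- src_inv[1:3, 1:3] %*% L3
    gx <- index_gradient(sb$data, 1L)
    gy <- index_gradient(sb$data, 2L)
    gz <- index_gradient(sb$data, 3L)
    arange <- as.numeric(quantile(tv, c(0.01, 0.99)))
    brange <- as.numeric(quantile(sb$data, c(0.01, 0.99)))
    ncp <- prod(cdim)
    sdim <- dim(sb$data)

    warp_values <- function(cmat, want_grad = FALSE) {
      d <- matrix(0, nrow(pts), 3)
      for (c in 1:3) d[, c] <- cpp_sample(cmat[, c], cdim, pts_ctrl, 1L, 0, 1L)
      y <- sweep((pts + d) %*% t(L3), 2, Lt, "+")
      vox <- sweep(y %*% t(src_inv[1:3, 1:3]), 2, src_inv[1:3, 4], "+")
      w <- cpp_sample(as.numeric(sb$data), sdim, vox, 1L, 0, 0L)
      if (!want_grad) return(list(w = w))
      gmat <- cbind(cpp_sample(gx, sdim, vox, 1L, 0, 0L),
                    cpp_sample(gy, sdim, vox, 1L, 0, 0L),
                    cpp_sample(gz, sdim, vox, 1L, 0, 0L)) %*% BL
      list(w = w, gmat = gmat)
    }
    data_term <- function(w) {
      if (metric == "cc") {
        wc <- w - mean(w); tc <- tv - mean(tv)
        Sw2 <- sum(wc^2); St2 <- sum(tc^2); Stw <- sum(tc * wc)
        if (Sw2 == 0) return(list(value = 0, dw = rep(0, length(w))))
        cc <- Stw / sqrt(St2 * Sw2)
        dw <- (tc - (Stw / Sw2) * wc) / sqrt(St2 * Sw2)
        list(value = cc, dw = dw)
      } else {
        g <- cpp_mi_grad(tv, w, as.integer(bins), arange[1], arange[2],
                         brange[1], brange[2])
        list(value = g$mi, dw = g$grad)
      }
    }
    penalty <- function(cmat) lambda * sum(neighbor_diff_sq(cmat, cdim)) / ncp
    objective <- function(cmat, wv = NULL) {
      if (is.null(wv)) wv <- warp_values(cmat)
      data_term(wv$w)$value - penalty(cmat)
    }

    obj <- objective(ctrl)
    obj0 <- obj
    stepsz <- 0.25 * schedule$spacing[lev]
    stalls <- 0L
    for (it in seq_len(schedule$iters[lev])) {
      wv <- warp_values(ctrl, want_grad = TRUE)
      dt <- data_term(wv$w)
      V <- wv$gmat * dt$dw
      g_ctrl <- cpp_scatter3(pts_ctrl, V, cdim)
      g_ctrl <- g_ctrl - (2 * lambda / ncp) * neighbor_laplacian(ctrl, cdim)
      gmax <- max(sqrt(rowSums(g_ctrl^2)))
      if (gmax < 1e-12) break
      dir <- g_ctrl / gmax
      improved <- FALSE
      for (bt in 1:5) {
        cand <- ctrl + stepsz * dir
        attr(cand, "cdim") <- cdim
        cand_obj <- objective(cand)
        if (cand_obj > obj) {
          ctrl <- cand
          obj <- cand_obj
          stepsz <- min(stepsz * 1.2, schedule$spacing[lev])
          improved <- TRUE
          break
        }
        stepsz <- stepsz / 2
      }
      if (!improved) {
        stalls <- stalls + 1L
        if (stalls >= 3L || stepsz < 1e-4) break
      } else stalls <- 0L
    }
    trace[[lev]] <- c(start = obj0, end = obj)
  }
  cdim <- attr(ctrl, "cdim")
  field <- deformation_field(array(ctrl, c(cdim, 3L)), affine = ctrl_aff)
  out <- transform_chain(field, init)
  attr(out, "objective") <- trace
  out
}

# Central-difference gradient of a 3-D array along one index axis
# (one-sided at the boundary).
index_gradient <- function(a, axis) {
  n <- dim(a)
  hi <- lo <- list(1:n[1], 1:n[2], 1:n[3])
  hi[[axis]] <- pmin(hi[[axis]] + 1L, n[axis])
  lo[[axis]] <- pmax(lo[[axis]] - 1L, 1L)
  g <- a[hi[[1]], hi[[2]], hi[[3]], drop = FALSE] -
       a[lo[[1]], lo[[2]], lo[[3]], drop = FALSE]
  denom <- hi[[axis]] - lo[[axis]]  # 1 at the boundary, 2 in the interior
  div <- switch(axis,
                denom,
                rep(denom, each = n[1]),
                rep(denom, each = n[1] * n[2]))
  out <- g / div  # recycling follows column-major order
  dim(out) <- n
  out
}

# Sum over axes of squared forward differences of the control displacements.
neighbor_diff_sq <- function(cmat, cdim) {
  a <- array(cmat, c(cdim, 3L))
  s <- 0
  n <- cdim
  if (n[1] > 1) s <- s + sum((a[2:n[1], , , ] - a[1:(n[1] - 1), , , ])^2)
  if (n[2] > 1) s <- s + sum((a[, 2:n[2], , ] - a[, 1:(n[2] - 1), , ])^2)
  if (n[3] > 1) s <- s + sum((a[, , 2:n[3], ] - a[, , 1:(n[3] - 1), ])^2)
  s
}

# Gradient of neighbor_diff_sq w.r.t. the control displacements, divided by 2.
neighbor_laplacian <- function(cmat, cdim) {
  a <- array(cmat, c(cdim, 3L))
  out <- array(0, dim(a))
  n <- cdim
  if (n[1] > 1) {
    d <- a[2:n[1], , , , drop = FALSE] - a[1:(n[1] - 1), , , , drop = FALSE]
    out[1:(n[1] - 1), , , ] <- out[1:(n[1] - 1), , , , drop = FALSE] - d
    out[2:n[1], , , ] <- out[2:n[1], , , , drop = FALSE] + d
  }
  if (n[2] > 1) {
    d <- a[, 2:n[2], , , drop = FALSE] - a[, 1:(n[2] - 1), , , drop = FALSE]
    out[, 1:(n[2] - 1), , ] <- out[, 1:(n[2] - 1), , , drop = FALSE] - d
    out[, 2:n[2], , ] <- out[, 2:n[2], , , drop = FALSE] + d
  }
  if (n[3] > 1) {
    d <- a[, , 2:n[3], , drop = FALSE] - a[, , 1:(n[3] - 1), , drop = FALSE]
    out[, , 1:(n[3] - 1), ] <- out[, , 1:(n[3] - 1), , drop = FALSE] - d
    out[, , 2:n[3], ] <- out[, , 2:n[3], , drop = FALSE] + d
  }
  matrix(out, prod(cdim), 3)
}
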