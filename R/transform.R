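#' Rigid or affine spatial transform
#'
#' Parameterized linear world-to-world mapping. A rigid transform has 6
#' degrees of freedom (3 translations in mm, 3 rotations in rad); an affine
#' transform adds 3 per-axis scale factors (9 DOF, no shear). Rotation and
#' scaling are applied about `center` (world mm), which conditions the
#' optimization; the derived 4x4 matrix is
#' `T(t) C R S C^-1` with `R = Rz Ry Rx`.
#'
#' Throughout the package transforms follow the pull-back convention: the
#' transform returned by registering `source` to `target` maps target-space
#' world points into source space, so that resampling the source onto the
#' target grid is a single gather.
#'
#' @param kind `"rigid"` or `"affine"`.
#' @param params Named or positional numeric vector:
#'   `tx, ty, tz` (mm), `rx, ry, rz` (rad) and, for affine, `sx, sy, sz`.
#' @param center Rotation/scaling center in world mm.
#' @return A `linear_transform` with a derived `$matrix`.
#' @export
linear_transform <- function(kind = c("rigid", "affine"),
                             params = NULL, center = c(0, 0, 0)) {
  kind <- match.arg(kind)
  np <- if (kind == "rigid") 6L else 9L
  if (is.null(params)) params <- c(rep(0, 6), rep(1, 3))[seq_len(np)]
  params <- as.numeric(params)
  if (length(params) != np)
    stop(sprintf("%s transform needs %d parameters", kind, np), call. = FALSE)
  nm <- c("tx", "ty", "tz", "rx", "ry", "rz", "sx", "sy", "sz")[seq_len(np)]
  names(params) <- nm
  m <- params_to_matrix(params, kind, center)
  structure(list(kind = kind, params = params, center = as.numeric(center),
                 matrix = m),
            class = c("linear_transform", "spatial_transform"))
}

params_to_matrix <- function(p, kind, center) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  R <- Rz %*% Ry %*% Rx
  S <- if (kind == "affine") diag(p[7:9]) else diag(3)
  A <- R %*% S
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- p[1:3] + center - A %*% center
  unname(m)
}

#' Wrap an explicit 4x4 matrix as a linear transform
#'
#' Used for matrix inverses and products where the rigid/affine
#' parameterization is no longer available.
#' @param matrix A 4x4 world-to-world matrix.
#' @param kind Transform kind recorded for provenance.
#' @return A `linear_transform` with `params = NULL`.
#' @export
linear_from_matrix <- function(matrix, kind = "affine") {
  matrix <- unname(as.matrix(matrix))
  stopifnot(all(dim(matrix) == c(4, 4)))
  structure(list(kind = kind, params = NULL, center = c(0, 0, 0),
                 matrix = matrix),
            class = c("linear_transform", "spatial_transform"))
}

#' Identity transform
#' @return A rigid `linear_transform` with zero parameters.
#' @export
identity_transform <- function() linear_transform("rigid")

#' Dense deformation field
#'
#' Per-voxel world-space displacement vectors (mm) defined on their own grid.
#' Applying the field to a world point adds the trilinearly interpolated
#' displacement; points outside the field grid are displaced by the value at
#' the clamped boundary.
#'
#' @param displacement 4-D array `(nx, ny, nz, 3)` of mm displacements.
#' @param spacing,affine Grid geometry of the field (see [scalar_volume()]).
#' @return A `deformation_field`.
#' @export
deformation_field <- function(displacement, spacing = c(1, 1, 1), affine = NULL) {
  d <- dim(displacement)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement must be an (nx, ny, nz, 3) array", call. = FALSE)
  if (anyNA(displacement)) stop("displacement contains NA/NaN", call. = FALSE)
  g <- make_grid(d[1:3], spacing, affine)
  structure(list(displacement = displacement, spacing = g$spacing,
                 affine = g$affine),
            class = c("deformation_field", "spatial_transform"))
}

#' Ordered chain of spatial transforms
#'
#' Transforms are applied to points in list order (left to right); nested
#' chains are flattened. An empty chain is the identity.
#'
#' @param ... `linear_transform`, `deformation_field` or `transform_chain`
#'   objects.
#' @return A `transform_chain`.
#' @export
transform_chain <- function(...) {
  els <- list(...)
  flat <- list()
  for (e in els) {
    if (inherits(e, "transform_chain")) flat <- c(flat, e$transforms)
    else if (inherits(e, "spatial_transform")) flat <- c(flat, list(e))
    else stop("not a spatial transform", call. = FALSE)
  }
  structure(list(transforms = flat),
            class = c("transform_chain", "spatial_transform"))
}

#' Apply a transform to world points
#'
#' @param transform A transform or chain.
#' @param pts N x 3 matrix of world coordinates (mm).
#' @return N x 3 matrix of mapped world coordinates.
#' @export
apply_transform <- function(transform, pts) UseMethod("apply_transform")

#' @export
apply_transform.linear_transform <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  m <- transform$matrix
  sweep(pts %*% t(m[1:3, 1:3]), 2, m[1:3, 4], "+")
}

#' @export
apply_transform.deformation_field <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  pts + sample_field(transform, pts)
}

#' @export
apply_transform.transform_chain <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  for (t in transform$transforms) pts <- apply_transform(t, pts)
  pts
}

# Trilinearly sample a deformation field's displacement (mm) at world points.
sample_field <- function(field, pts) {
  vox <- world_to_voxel(field, pts)
  d <- dim(field$displacement)[1:3]
  out <- matrix(0, nrow(pts), 3)
  for (c in 1:3) {
    comp <- field$displacement[, , , c, drop = TRUE]
    out[, c] <- cpp_sample(as.numeric(comp), d, vox, 1L, 0, 1L)
  }
  out
}

#' Invert a spatial transform
#'
#' Linear transforms are inverted exactly (matrix inverse). Deformation
#' fields are inverted numerically by fixed-point iteration on the field
#' grid; the iteration fails if the field folds (non-positive Jacobian
#' determinant) or if the compose-with-inverse residual does not fall below
#' `tol` mm. Chains are inverted by reversing and inverting each element.
#'
#' @param transform A transform or chain.
#' @param tol Maximum residual displacement (mm) of `t o invert(t)` on the
#'   field grid.
#' @param maxit Maximum fixed-point iterations.
#' @return A transform of the same kind.
#' @export
invert <- function(transform, tol = 0.05, maxit = 50L) UseMethod("invert")

#' @export
invert.linear_transform <- function(transform, tol = 0.05, maxit = 50L) {
  linear_from_matrix(solve(transform$matrix), kind = transform$kind)
}

#' @export
invert.deformation_field <- function(transform, tol = 0.05, maxit = 50L) {
  jmin <- min_jacobian(transform)
  if (jmin <= 0)
    stop(sprintf("deformation field folds (min Jacobian determinant %.3g); cannot invert",
                 jmin), call. = FALSE)
  dims <- dim(transform$displacement)[1:3]
  idx <- grid_index_matrix(dims)
  pts <- voxel_to_world(transform, idx)
  e <- matrix(0, nrow(pts), 3)
  resid <- Inf
  for (it in seq_len(maxit)) {
    d_at <- sample_field(transform, pts + e)
    resid <- max(sqrt(rowSums((e + d_at)^2)))
    if (resid < tol) break
    e <- -d_at
  }
  if (resid >= tol)
    stop(sprintf("deformation inversion did not converge (residual %.3g mm > %.3g mm)",
                 resid, tol), call. = FALSE)
  inv <- array(e, c(dims, 3L))
  deformation_field(inv, affine = transform$affine)
}

#' @export
invert.transform_chain <- function(transform, tol = 0.05, maxit = 50L) {
  inv <- lapply(rev(transform$transforms), invert, tol = tol, maxit = maxit)
  do.call(transform_chain, inv)
}

# Minimum Jacobian determinant of (identity + displacement), by central
# differences on the field grid interior.
min_jacobian <- function(field) {
  disp <- field$displacement
  dims <- dim(disp)[1:3]
  if (any(dims < 3)) return(1)
  A <- field$affine[1:3, 1:3]
  nint <- prod(dims - 2L)
  J <- array(0, c(nint, 3, 3))  # J[, i, k] = d disp_i / d index_k (interior)
  n <- dims
  for (ci in 1:3) {
    comp <- disp[, , , ci, drop = TRUE]
    J[, ci, 1] <- as.vector(comp[3:n[1], 2:(n[2] - 1), 2:(n[3] - 1)] -
                            comp[1:(n[1] - 2), 2:(n[2] - 1), 2:(n[3] - 1)]) / 2
    J[, ci, 2] <- as.vector(comp[2:(n[1] - 1), 3:n[2], 2:(n[3] - 1)] -
                            comp[2:(n[1] - 1), 1:(n[2] - 2), 2:(n[3] - 1)]) / 2
    J[, ci, 3] <- as.vector(comp[2:(n[1] - 1), 2:(n[2] - 1), 3:n[3]] -
                            comp[2:(n[1] - 1), 2:(n[2] - 1), 1:(n[3] - 2)]) / 2
  }
  Ainv <- solve(A)
  # world-space Jacobian of the map id + d: M = I + (dd/didx) %*% (didx/dworld)
  M <- array(0, c(nint, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    M[, i, j] <- J[, i, 1] * Ainv[1, j] + J[, i, 2] * Ainv[2, j] +
                 J[, i, 3] * Ainv[3, j] + as.numeric(i == j)
  }
  jd <- M[, 1, 1] * (M[, 2, 2] * M[, 3, 3] - M[, 2, 3] * M[, 3, 2]) -
        M[, 1, 2] * (M[, 2, 1] * M[, 3, 3] - M[, 2, 3] * M[, 3, 1]) +
        M[, 1, 3] * (M[, 2, 1] * M[, 3, 2] - M[, 2, 2] * M[, 3, 1])
  min(jd)
}

#' Compose (flatten) a transform chain
#'
#' Flattens nested chains and multiplies runs of adjacent linear transforms
#' into single matrices; applying the result to any point equals sequential
#' application of the original elements.
#'
#' @param ... Transforms or chains, applied in argument order.
#' @return A `transform_chain` (possibly with a single element).
#' @export
compose <- function(...) {
  chain <- transform_chain(...)
  out <- list()
  for (t in chain$transforms) {
    n <- length(out)
    if (n > 0 && inherits(t, "linear_transform") &&
        inherits(out[[n]], "linear_transform")) {
      kind <- if (out[[n]]$kind == "rigid" && t$kind == "rigid") "rigid" else "affine"
      out[[n]] <- linear_from_matrix(t$matrix %*% out[[n]]$matrix, kind = kind)
    } else {
      out <- c(out, list(t))
    }
  }
  do.call(transform_chain, out)
}

#' @export
print.linear_transform <- function(x, ...) {
  cat(sprintf("<linear_transform: %s>\n", x$kind))
  print(signif(x$matrix, 6))
  invisible(x)
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(apply(x$displacement^2, 1:3, sum))
  cat(sprintf("<deformation_field> %s control grid, max |d| = %.3g mm\n",
              paste(dim(x$displacement)[1:3], collapse = "x"), max(mag)))
  invisible(x)
}

#' @export
print.transform_chain <- function(x, ...) {
  cat(sprintf("<transform_chain> %d element(s)\n", length(x$transforms)))
  invisible(x)
}

#' Read and write spatial transforms
#'
#' Linear transforms are stored as plain text: a one-line header
#' (`# atlasseg linear <kind> pull-back`) followed by the 4x4 matrix,
#' row-major. Deformation fields are stored as 4-D NIfTI volumes with the
#' displacement components (mm) in the fourth dimension. Chains are stored
#' as a JSON manifest referencing element files alongside it.
#'
#' @param transform A transform or chain.
#' @param path Output path; chains use `path` for the manifest and
#'   `path_00.*` for the elements.
#' @return `path`, invisibly (reading returns the transform).
#' @export
write_transform <- function(transform, path) UseMethod("write_transform")

#' @export
write_transform.linear_transform <- function(transform, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# atlasseg linear %s pull-back", transform$kind), con)
  utils::write.table(format(transform$matrix, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_transform.deformation_field <- function(transform, path) {
  img <- RNifti::asNifti(transform$displacement, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(transform$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @export
write_transform.transform_chain <- function(transform, path) {
  base <- sub("\\.json$", "", path)
  entries <- list()
  for (i in seq_along(transform$transforms)) {
    t <- transform$transforms[[i]]
    if (inherits(t, "linear_transform")) {
      f <- sprintf("%s_%02d.txt", base, i)
      write_transform(t, f)
      entries[[i]] <- list(type = "linear", file = basename(f))
    } else {
      f <- sprintf("%s_%02d.nii.gz", base, i)
      write_transform(t, f)
      entries[[i]] <- list(type = "field", file = basename(f))
    }
  }
  jsonlite::write_json(list(format = "atlasseg transform chain",
                            order = "points are mapped by elements in list order",
                            elements = entries),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (grepl("\\.json$", path)) {
    man <- jsonlite::read_json(path)
    base_dir <- dirname(path)
    els <- lapply(man$elements, function(e) read_transform(file.path(base_dir, e$file)))
    return(do.call(transform_chain, els))
  }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    a <- array(as.numeric(a), dim(a))
    aff <- unclass(RNifti::xform(img))
    aff <- matrix(as.numeric(aff[1:4, 1:4]), 4, 4)
    return(deformation_field(a, affine = aff))
  }
  lines <- readLines(path)
  kind <- if (grepl("rigid", lines[1])) "rigid" else "affine"
  m <- matrix(scan(text = lines[-1], quiet = TRUE), 4, 4, byrow = TRUE)
  linear_from_matrix(m, kind = kind)
}
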