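#' Structured three-component velocity field
#'
#' The central gridded container of the package: a regular, axis-aligned
#' voxel grid carrying a 3-component velocity vector per voxel plus a lumen
#' validity mask.  All quantities are SI (metres, metres per second).
#' Voxel `(i, j, k)` (1-based) has its centre at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param u numeric array of dimension `c(dims, 3)`; `u[,,,1]` is the x
#'   velocity component, `[,,,2]` y and `[,,,3]` z, in m/s.
#' @param spacing length-3 positive numeric, voxel pitch in m.
#' @param origin length-3 numeric, centre of voxel `(1,1,1)` in m.
#' @param mask logical array matching `dim(u)[1:3]`; `TRUE` marks lumen
#'   (valid fluid) voxels.  Defaults to all-`TRUE`.
#' @return an object of class `"velocity_field"`, a list with elements
#'   `u`, `mask`, `spacing`, `origin`, `dims`.
#' @export
velocity_field <- function(u, spacing, origin = c(0, 0, 0), mask = NULL) {
  du <- dim(u)
  if (length(du) != 4L || du[4] != 3L)
    stop("`u` must be a 4-d array with dim (nx, ny, nz, 3)")
  dims <- du[1:3]
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!is.logical(mask) || !identical(as.integer(dim(mask)), as.integer(dims)))
    stop("`mask` must be a logical array with the same grid dims as `u`")
  fin <- array(is.finite(u[, , , 1, drop = FALSE]) &
                 is.finite(u[, , , 2, drop = FALSE]) &
                 is.finite(u[, , , 3, drop = FALSE]), dims)
  if (any(mask & !fin))
    stop("masked-true voxels must carry finite velocities")
  structure(
    list(u = u, mask = mask, spacing = spacing, origin = origin, dims = dims),
    class = "velocity_field"
  )
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("velocity_field:", paste(x$dims, collapse = " x "), "voxels\n")
  cat("  spacing [m]:", paste(signif(x$spacing, 4), collapse = ", "), "\n")
  cat("  origin  [m]:", paste(signif(x$origin, 4), collapse = ", "), "\n")
  cat("  lumen voxels:", sum(x$mask), "/", length(x$mask), "\n")
  sp <- field_speed(x)
  cat("  max speed [m/s]:", signif(max(sp[x$mask], -Inf), 5), "\n")
  invisible(x)
}

#' Voxel-centre coordinates of a velocity field
#'
#' @param field a [velocity_field].
#' @param which optional logical array selecting voxels; default all.
#' @return an n x 3 matrix of voxel-centre coordinates (m).
#' @export
voxel_centers <- function(field, which = NULL) {
  d <- field$dims
  idx <- arrayInd(if (is.null(which)) seq_len(prod(d)) else which(which), d)
  sweep(sweep(idx - 1, 2, field$spacing, "*"), 2, field$origin, "+")
}

#' Per-voxel speed (velocity magnitude)
#'
#' @param field a [velocity_field].
#' @return numeric array of `field$dims` with the Euclidean norm of the
#'   velocity vector at each voxel.
#' @export
field_speed <- function(field) {
  array(sqrt(field$u[, , , 1]^2 + field$u[, , , 2]^2 + field$u[, , , 3]^2),
        field$dims)
}

# Continuous (fractional, 1-based) grid coordinates of physical points.
grid_coords <- function(field, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, field$origin, "-"), 2, field$spacing, "/") + 1
}

#' Trilinear interpolation on a masked structured grid
#'
#' Samples one or more scalar voxel arrays at arbitrary physical points by
#' trilinear interpolation between the 8 enclosing voxel centres.  A sample
#' is valid only when all 8 enclosing corners lie inside the grid and are
#' lumen voxels; invalid samples come back `NA`.  Exact on affine data.
#'
#' @param field a [velocity_field] supplying geometry and mask.
#' @param values a numeric array of `field$dims`, or a list of such arrays.
#' @param pts n x 3 matrix of physical coordinates (m).
#' @return if `values` is one array, a length-n numeric vector; if a list,
#'   an n x length(values) matrix (one column per array).
#' @export
trilinear_sample <- function(field, values, pts) {
  single <- !is.list(values)
  if (single) values <- list(values)
  pts <- rbind(pts)
  g <- grid_coords(field, pts)
  d <- field$dims
  i0 <- floor(g)
  frac <- g - i0
  # points exactly on the upper grid face: pull the base cell inward
  for (ax in 1:3) {
    hi <- i0[, ax] == d[ax] & frac[, ax] < 1e-9
    i0[hi, ax] <- i0[hi, ax] - 1
    frac[hi, ax] <- 1
  }
  inside <- i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
    i0[, 1] <= d[1] - 1 & i0[, 2] <= d[2] - 1 & i0[, 3] <= d[3] - 1
  n <- nrow(pts)
  out <- matrix(NA_real_, n, length(values))
  if (!any(inside)) {
    if (single) return(out[, 1]) else return(out)
  }
  ii <- which(inside)
  b <- i0[ii, , drop = FALSE]
  f <- frac[ii, , drop = FALSE]
  acc <- matrix(0, length(ii), length(values))
  ok <- rep(TRUE, length(ii))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    lin <- (b[, 1] + dx) + d[1] * ((b[, 2] + dy - 1) + d[2] * (b[, 3] + dz - 1))
    ok <- ok & field$mask[lin]
    for (v in seq_along(values)) acc[, v] <- acc[, v] + w * values[[v]][lin]
  }
  acc[!ok, ] <- NA_real_
  out[ii, ] <- acc
  if (single) out[, 1] else out
}
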