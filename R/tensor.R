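#' Velocity-gradient tensor on a masked structured grid
#'
#' Finite-difference velocity gradients \eqn{g_{ab} = \partial u_a / \partial
#' x_b} per voxel: second-order central differences where both axis
#' neighbours are lumen voxels, first-order one-sided differences where only
#' one is (so near-wall gradients — the ones that drive wall shear stress —
#' are kept rather than discarded), and invalid where neither is.  A voxel
#' is `valid` only if it is lumen and a stencil existed along all three
#' axes.
#'
#' @param field a [velocity_field].
#' @return an object of class `"gradient_field"`: list with `g` (array of
#'   dim `c(dims, 3, 3)`, units 1/s, `NA` outside `valid`), `valid`
#'   (logical array), and the grid geometry (`spacing`, `origin`, `dims`,
#'   `mask`).
#' @export
gradient_tensor <- function(field) {
  d <- field$dims
  if (any(d < 2)) stop("grid must have at least 2 voxels along every axis")
  mask <- field$mask
  shift <- function(a, axis, by) {
    # a[idx] -> a[idx + by] along `axis`, padding with NA / FALSE
    out <- array(if (is.logical(a)) FALSE else NA_real_, d)
    n <- d[axis]
    src <- if (by > 0) 2:n else 1:(n - 1)
    dst <- if (by > 0) 1:(n - 1) else 2:n
    ix <- list(1:d[1], 1:d[2], 1:d[3])
    ixs <- ix; ixs[[axis]] <- src
    ixd <- ix; ixd[[axis]] <- dst
    out[ixd[[1]], ixd[[2]], ixd[[3]]] <- a[ixs[[1]], ixs[[2]], ixs[[3]]]
    out
  }
  g <- array(NA_real_, c(d, 3, 3))
  valid <- mask
  for (b in 1:3) {
    h <- field$spacing[b]
    mp <- shift(mask, b, +1)
    mm <- shift(mask, b, -1)
    has <- mask & (mp | mm)
    valid <- valid & has
    for (a in 1:3) {
      ua <- array(field$u[, , , a], d)
      up <- shift(ua, b, +1)
      um <- shift(ua, b, -1)
      der <- array(NA_real_, d)
      ctr <- mask & mp & mm
      fwd <- mask & mp & !mm
      bwd <- mask & !mp & mm
      der[ctr] <- (up[ctr] - um[ctr]) / (2 * h)
      der[fwd] <- (up[fwd] - ua[fwd]) / h
      der[bwd] <- (ua[bwd] - um[bwd]) / h
      g[, , , a, b] <- der
    }
  }
  # blank out voxels that lost any axis
  for (a in 1:3) for (b in 1:3) {
    slice <- g[, , , a, b]
    slice[!valid] <- NA_real_
    g[, , , a, b] <- slice
  }
  structure(
    list(g = g, valid = valid, spacing = field$spacing,
         origin = field$origin, dims = d, mask = mask),
    class = "gradient_field"
  )
}

#' @export
print.gradient_field <- function(x, ...) {
  cat("gradient_field:", paste(x$dims, collapse = " x "),
      "voxels,", sum(x$valid), "valid\n")
  invisible(x)
}

#' Symmetric/antisymmetric split of the velocity gradient
#'
#' Splits \eqn{g} into the rate-of-deformation tensor
#' \eqn{S = (g + g^T)/2} (the \eqn{\dot\varepsilon} driving viscous stress
#' in a Newtonian fluid) and the rotation tensor \eqn{W = (g - g^T)/2}.
#'
#' @param G a `gradient_field`.
#' @return list with arrays `S` and `W` of dim `c(dims, 3, 3)` (1/s), plus
#'   `valid`.
#' @export
deformation_split <- function(G) {
  S <- G$g
  W <- G$g
  for (a in 1:3) for (b in 1:3) {
    S[, , , a, b] <- (G$g[, , , a, b] + G$g[, , , b, a]) / 2
    W[, , , a, b] <- (G$g[, , , a, b] - G$g[, , , b, a]) / 2
  }
  list(S = S, W = W, valid = G$valid)
}

#' Vorticity vector field
#'
#' \eqn{\omega = \nabla \times u} from the gradient tensor.
#'
#' @param G a `gradient_field`.
#' @return array of dim `c(dims, 3)`, 1/s; `NA` outside `valid`.
#' @export
vorticity <- function(G) {
  d <- G$dims
  w <- array(NA_real_, c(d, 3))
  w[, , , 1] <- G$g[, , , 3, 2] - G$g[, , , 2, 3]
  w[, , , 2] <- G$g[, , , 1, 3] - G$g[, , , 3, 1]
  w[, , , 3] <- G$g[, , , 2, 1] - G$g[, , , 1, 2]
  w
}

#' Similarity-scaled out-of-plane vorticity
#'
#' The z vorticity component multiplied by the velocity and length ratios
#' of the dynamic-similarity bundle, making in-vitro vorticity levels
#' comparable with in-vivo ones.
#'
#' @param G a `gradient_field`.
#' @param sim a [similarity_spec].
#' @return numeric array of `G$dims` (1/s, in-vivo equivalent).
#' @export
vorticity_z_scaled <- function(G, sim) {
  stopifnot(inherits(sim, "similarity_spec"))
  wz <- G$g[, , , 2, 1] - G$g[, , , 1, 2]
  array(wz * sim$u_ratio * sim$d_ratio, G$dims)
}

#' Q-criterion vortex indicator
#'
#' Second invariant of the velocity-gradient tensor in the Hunt et al.
#' form \eqn{Q = (\|W\|_F^2 - \|S\|_F^2)/2}; positive where rotation
#' dominates strain, so iso-surfaces of Q > 0 delineate vortex cores.
#'
#' @param G a `gradient_field`.
#' @return numeric array of `G$dims`, 1/s^2; `NA` outside `valid`.
#' @export
q_criterion <- function(G) {
  sw <- deformation_split(G)
  s2 <- array(0, G$dims)
  w2 <- array(0, G$dims)
  for (a in 1:3) for (b in 1:3) {
    s2 <- s2 + sw$S[, , , a, b]^2
    w2 <- w2 + sw$W[, , , a, b]^2
  }
  (w2 - s2) / 2
}

#' Discrete divergence from the gradient tensor
#'
#' `trace(g)` per voxel; a cheap solenoidality check for synthetic fields.
#'
#' @param G a `gradient_field`.
#' @return numeric array of `G$dims`, 1/s.
#' @export
divergence <- function(G) {
  G$g[, , , 1, 1] + G$g[, , , 2, 2] + G$g[, , , 3, 3]
}
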