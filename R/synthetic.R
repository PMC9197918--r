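#' Imaging-modality degradation settings
#'
#' Presets reflect the acquisition resolutions of the study conditions this
#' package emulates, expressed in the scaled (in-vitro phantom) frame where
#' the geometry is enlarged 3.77x relative to the vessel:
#' \describe{
#'   \item{`tomo_piv`}{isotropic 0.63 mm vector pitch (0.25 mm^3
#'     interrogation volume), no depth averaging, noise-free.}
#'   \item{`stereo_piv`}{0.38 mm in-plane (0.144 mm^2 window), 1 mm plane
#'     spacing and 1 mm laser-sheet depth averaging, noise-free.}
#'   \item{`mri`}{0.47 x 0.47 x 0.5 mm voxels at vessel scale, i.e.
#'     1.772 x 1.772 x 1.885 mm in the scaled frame; additive Gaussian
#'     noise with SD 5% of a 150 cm/s VENC translated to the scaled frame.}
#'   \item{`cfd`}{pass-through reference (no degradation).}
#' }
#' All presets remain overridable — the vector pitch of a PIV processing
#' chain depends on window overlap and is a configuration value, not a
#' physical constant.
#'
#' @param name one of `"mri"`, `"stereo_piv"`, `"tomo_piv"`, `"cfd"`.
#' @param spacing target voxel pitch, length-3 numeric, m; `NULL` takes the
#'   preset.
#' @param noise_sd additive Gaussian noise SD per velocity component, m/s.
#' @param depth_averaging slab thickness averaged along z, m (laser-sheet /
#'   slice-profile emulation).
#' @param scale_factor geometric scale-up of the phantom; used to convert
#'   the MRI voxel preset into the scaled frame.
#' @return object of class `"modality_spec"`.
#' @export
modality_spec <- function(name = c("mri", "stereo_piv", "tomo_piv", "cfd"),
                          spacing = NULL, noise_sd = NULL,
                          depth_averaging = NULL, scale_factor = 3.77) {
  name <- match.arg(name)
  preset <- switch(name,
    mri = list(spacing = c(0.47e-3, 0.47e-3, 0.5e-3) * scale_factor,
               # 5% of VENC (1.5 m/s) mapped to the scaled frame by the
               # Reynolds-matched velocity ratio ~1.76
               noise_sd = 0.05 * 1.5 / 1.76, depth_averaging = 0),
    stereo_piv = list(spacing = c(0.38e-3, 0.38e-3, 1.0e-3),
                      noise_sd = 0, depth_averaging = 1.0e-3),
    tomo_piv = list(spacing = c(0.63e-3, 0.63e-3, 0.63e-3),
                    noise_sd = 0, depth_averaging = 0),
    cfd = list(spacing = NULL, noise_sd = 0, depth_averaging = 0)
  )
  if (!is.null(spacing)) preset$spacing <- rep(as.numeric(spacing), length.out = 3)
  if (!is.null(noise_sd)) preset$noise_sd <- noise_sd
  if (!is.null(depth_averaging)) preset$depth_averaging <- depth_averaging
  if (!is.null(preset$spacing) && any(preset$spacing <= 0))
    stop("modality spacing must be strictly positive")
  if (preset$noise_sd < 0) stop("noise_sd must be >= 0")
  structure(c(list(name = name), preset), class = "modality_spec")
}

#' Aneurysm-like phantom geometry and flow settings
#'
#' A straight parent tube (axis z, `z` in `[0, tube_length]`) with a
#' spherical side sac.  `sac_center_offset` positions the sac centre
#' (absolute coordinates, tube axis through the origin); the default hangs
#' a sac off the side wall at mid-length.
#'
#' @param tube_radius,tube_length parent-vessel radius and length, m.
#' @param sac_radius aneurysm sac radius, m (0 degenerates to a plain tube).
#' @param sac_center_offset length-3 numeric, m.
#' @param v_max centreline velocity of the parent tube, m/s.
#' @param scale_factor geometric scale-up relative to the vessel, recorded
#'   for similarity bookkeeping.
#' @return object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(tube_radius, tube_length,
                         sac_radius = 0.8 * tube_radius,
                         sac_center_offset = c(tube_radius + 0.6 * sac_radius,
                                               0, tube_length / 2),
                         v_max = 1, scale_factor = 3.77) {
  if (tube_radius <= 0 || tube_length <= 0) stop("tube dimensions must be > 0")
  if (sac_radius < 0) stop("sac_radius must be >= 0")
  if (scale_factor <= 0) stop("scale_factor must be > 0")
  structure(list(tube_radius = tube_radius, tube_length = tube_length,
                 sac_radius = sac_radius,
                 sac_center_offset = as.numeric(sac_center_offset),
                 v_max = v_max, scale_factor = scale_factor),
            class = "phantom_spec")
}

#' Analytic wall shear stress of fully developed pipe flow
#'
#' For a parabolic profile \eqn{u_z(r) = v_{max}(1 - r^2/R^2)} the wall
#' shear stress is \eqn{\tau_w = 2 \mu v_{max} / R}.
#'
#' @param mu dynamic viscosity, Pa s.
#' @param v_max centreline velocity, m/s.
#' @param tube_radius pipe radius, m.
#' @return wall shear stress in Pa.
#' @export
analytic_wss_poiseuille <- function(mu, v_max, tube_radius) {
  if (any(!is.finite(c(mu, v_max, tube_radius))) ||
      any(c(mu, v_max, tube_radius) <= 0))
    stop("mu, v_max and tube_radius must all be > 0")
  2 * mu * v_max / tube_radius
}

#' Poiseuille pipe-flow phantom
#'
#' Samples the parabolic profile on a regular grid (axis z, lumen
#' `r <= R`, no-slip at the wall, one dry voxel layer of margin) and
#' triangulates the cylindrical wall.
#'
#' @param tube_radius,tube_length pipe radius and length, m.
#' @param v_max centreline velocity, m/s.
#' @param spacing voxel pitch, scalar or length-3, m; must be smaller than
#'   the radius or no lumen voxel ring can resolve the profile.
#' @param n_theta circumferential surface resolution.
#' @return list with elements `field` ([velocity_field]) and `surface`
#'   ([tri_surface], normals not yet computed).
#' @export
make_poiseuille <- function(tube_radius, tube_length, v_max, spacing,
                            n_theta = NULL) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing >= tube_radius))
    stop("spacing must be < tube_radius to resolve the profile")
  R <- tube_radius
  nxy <- 2 * ceiling(R / spacing[1:2]) + 3  # one dry voxel margin each side
  nz <- max(2, floor(tube_length / spacing[3]) + 1)
  dims <- c(nxy, nz)
  origin <- c(-(nxy - 1) / 2 * spacing[1:2], 0)
  x <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  y <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  r2 <- outer(x^2, y^2, "+")
  inside <- r2 <= R^2
  uz_xy <- ifelse(inside, v_max * (1 - r2 / R^2), 0)
  u <- array(0, c(dims, 3))
  u[, , , 3] <- array(rep(uz_xy, dims[3]), dims)
  mask <- array(rep(inside, dims[3]), dims)
  if (is.null(n_theta))
    n_theta <- max(32, ceiling(2 * pi * R / min(spacing[1:2])))
  surface <- cylinder_surface(R, tube_length, n_theta = n_theta,
                              n_z = max(2, nz))
  list(field = velocity_field(u, spacing, origin, mask), surface = surface)
}

# Hill's spherical vortex velocity, blended to zero at the sphere boundary
# through the Stokes stream function so the result stays exactly
# divergence-free: psi_blend = w(s) * psi_hill with
# u_rho = -(1/rho) d(psi)/dz, u_z = (1/rho) d(psi)/drho.
# w is a QUINTIC (C2) smoothstep over the outer `blend_frac` of the radius:
# the velocity contains w', so w'' must be continuous or the velocity
# gradient jumps at the shell edges and discrete divergence stops
# converging there.
hill_vortex_velocity <- function(x, y, z, center, a, U, blend_frac = 0.1) {
  dx <- x - center[1]; dy <- y - center[2]; zl <- z - center[3]
  rho2 <- dx^2 + dy^2
  rho <- sqrt(rho2)
  s <- sqrt(rho2 + zl^2)
  C <- 3 * U / (2 * a^2)
  psi <- -(C / 2) * rho2 * (a^2 - rho2 - zl^2)
  dpsi_drho <- -C * rho * (a^2 - 2 * rho2 - zl^2)
  dpsi_dz <- C * rho2 * zl
  s0 <- (1 - blend_frac) * a
  t <- pmin(pmax((s - s0) / (a - s0), 0), 1)
  w <- 1 - (6 * t^5 - 15 * t^4 + 10 * t^3)
  wp <- ifelse(s > s0 & s < a, -30 * t^2 * (1 - t)^2 / (a - s0), 0)
  s_safe <- pmax(s, 1e-300)
  rho_safe <- pmax(rho, 1e-300)
  u_rho <- -(w * dpsi_dz + psi * wp * zl / s_safe) / rho_safe
  u_zl <- (w * dpsi_drho + psi * wp * rho / s_safe) / rho_safe
  on_axis <- rho < 1e-12 * a
  u_rho[on_axis] <- 0
  u_zl[on_axis] <- (w * (-C) * (a^2 - zl^2))[on_axis]
  out_sphere <- s >= a
  u_rho[out_sphere] <- 0
  u_zl[out_sphere] <- 0
  cx <- ifelse(rho > 0, dx / rho_safe, 0)
  cy <- ifelse(rho > 0, dy / rho_safe, 0)
  list(ux = u_rho * cx, uy = u_rho * cy, uz = u_zl)
}

#' Aneurysm-like tube-plus-sac phantom
#'
#' A divergence-free composite flow: parabolic Poiseuille flow in the
#' parent tube plus a Hill's-spherical-vortex recirculation inside the sac,
#' blended continuously over the outer quarter of the sac radius through
#' the vortex stream function (so the blend itself cannot create
#' divergence).  The lumen is
#' the union of the tube and sphere interiors; the wall surface is a
#' marching-tetrahedra iso-surface of the union signed-distance field.
#' The vortex strength defaults to 5% of the tube centreline velocity:
#' sidewall-aneurysm sacs carry a slow jet-driven recirculation whose
#' velocities are a small fraction of the parent jet, which is what puts
#' the sac wall far below the neck in the resulting WSS map.
#'
#' @param spec a [phantom_spec]; the sac must intersect the tube.
#' @param spacing voxel pitch, scalar or length-3, m.
#' @param vortex_strength Hill-vortex propagation speed as a fraction of
#'   `spec$v_max`.
#' @param blend_frac fraction of the sac radius over which the vortex is
#'   smoothly faded out at the sac boundary.  The default 0.25 keeps the
#'   blend shell resolvable by realistic grid spacings; a thinner shell
#'   concentrates velocity curvature below the voxel scale and the
#'   discrete-divergence check loses its asymptotic decay.
#' @param with_surface triangulate the wall?  Skipping it
#'   (`with_surface = FALSE`) saves most of the runtime when only the
#'   volumetric field is needed, e.g. for solenoidality checks.
#' @return list with `field` ([velocity_field]) and `surface`
#'   ([tri_surface], `NULL` when `with_surface = FALSE`).
#' @export
make_sac_phantom <- function(spec, spacing, vortex_strength = 0.05,
                             blend_frac = 0.25, with_surface = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$sac_radius == 0)
    return(make_poiseuille(spec$tube_radius, spec$tube_length, spec$v_max,
                           spacing))
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing >= spec$tube_radius))
    stop("spacing must be < tube_radius to resolve the profile")
  Rt <- spec$tube_radius; Rs <- spec$sac_radius
  ctr <- spec$sac_center_offset
  d_axis <- sqrt(ctr[1]^2 + ctr[2]^2)
  if (d_axis - Rs >= Rt)
    stop("sac does not intersect the tube (disjoint geometry)")
  # grid bounds: tube cross-section and sac bounding box plus one dry voxel
  lo <- pmin(c(-Rt, -Rt, 0), ctr - Rs) - spacing
  hi <- pmax(c(Rt, Rt, spec$tube_length), ctr + Rs) + spacing
  lo[3] <- 0; hi[3] <- spec$tube_length  # tube stays open at the grid ends
  dims <- pmax(2, ceiling((hi - lo) / spacing) + 1)
  origin <- lo
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)
  r2_tube <- X^2 + Y^2
  in_tube <- r2_tube <= Rt^2
  d_sac2 <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2
  in_sac <- d_sac2 <= Rs^2
  uz_tube <- ifelse(in_tube, spec$v_max * (1 - r2_tube / Rt^2), 0)
  hv <- hill_vortex_velocity(X, Y, Z, ctr, Rs, vortex_strength * spec$v_max,
                             blend_frac = blend_frac)
  u <- array(0, c(dims, 3))
  u[, , , 1] <- hv$ux
  u[, , , 2] <- hv$uy
  u[, , , 3] <- uz_tube + hv$uz
  mask <- in_tube | in_sac
  field <- velocity_field(u, spacing, origin, mask)
  surface <- NULL
  if (with_surface) {
    # union signed distance on the same node lattice; iso-surface at 0
    phi <- pmin(sqrt(r2_tube) - Rt, sqrt(d_sac2) - Rs)
    surface <- iso_surface(phi, spacing, origin)
  }
  list(field = field, surface = surface)
}

# --- marching tetrahedra -----------------------------------------------

# Kuhn decomposition of the cube into 6 tetrahedra sharing the main
# diagonal; face diagonals are translation-consistent across cells.
kuhn_tets <- rbind(
  c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
  c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))

#' Triangulate the zero iso-surface of a scalar node field
#'
#' Marching tetrahedra on the Kuhn 6-tet cube decomposition.  Nodes with
#' negative values are "inside"; each tetrahedron crossed by the surface
#' contributes one or two triangles whose vertices are linear
#' interpolations along crossing edges.  Shared edges are interpolated in a
#' canonical node order, so coincident vertices are bit-identical and
#' collapse in the final dedup, yielding a watertight (up to open grid
#' boundaries) manifold mesh.
#'
#' @param phi numeric array of node values (e.g. a signed distance).
#' @param spacing node pitch, length-3, m.
#' @param origin position of node `(1,1,1)`, m.
#' @return a [tri_surface] (no normals).
#' @export
iso_surface <- function(phi, spacing, origin = c(0, 0, 0)) {
  d <- dim(phi)
  stopifnot(length(d) == 3, all(d >= 2))
  spacing <- rep(as.numeric(spacing), length.out = 3)
  # nudge node values away from zero: an intersection point exactly on a
  # grid node collapses triangles from every tetrahedron around that node
  # into slivers sharing it, which breaks manifoldness downstream.  Moving
  # the surface by <= delta (far below the discretisation error) avoids
  # the whole degenerate family.
  delta <- 1e-4 * min(spacing)
  small <- abs(phi) < delta
  phi[small] <- ifelse(phi[small] >= 0, delta, -delta)
  nc <- d - 1L
  ncell <- prod(nc)
  ci <- arrayInd(seq_len(ncell), nc)  # base corner (i,j,k) of each cell
  base <- ci[, 1] + d[1] * ((ci[, 2] - 1) + d[2] * (ci[, 3] - 1))
  # linear-index offsets of the 8 cube corners c0..c7 (bit order x,y,z)
  off <- integer(8)
  for (b in 0:7)
    off[b + 1] <- (b %% 2) + d[1] * (((b %/% 2) %% 2) + d[2] * (b %/% 4))
  node_pos <- function(id) {
    ijk <- arrayInd(id, d)
    sweep(sweep(ijk - 1, 2, spacing, "*"), 2, origin, "+")
  }
  nn <- prod(d)
  edge_point <- function(n1, n2) {
    lo <- pmin(n1, n2); hi <- pmax(n1, n2)
    t <- phi[lo] / (phi[lo] - phi[hi])
    p <- node_pos(lo) + t * (node_pos(hi) - node_pos(lo))
    list(key = (lo - 1) * nn + hi, p = p)
  }
  emit <- function(e1, e2, e3) {
    # one triangle per row across the vectorised cell set
    list(keys = cbind(e1$key, e2$key, e3$key),
         pts = rbind(e1$p, e2$p, e3$p))
  }
  acc <- list()
  for (tt in seq_len(nrow(kuhn_tets))) {
    corners <- kuhn_tets[tt, ]
    n <- cbind(base + off[corners[1] + 1], base + off[corners[2] + 1],
               base + off[corners[3] + 1], base + off[corners[4] + 1])
    f <- matrix(phi[n], ncol = 4)
    inside <- f < 0
    code <- inside[, 1] + 2L * inside[, 2] + 4L * inside[, 3] + 8L * inside[, 4]
    for (cd in 1:14) {
      sel <- which(code == cd)
      if (!length(sel)) next
      ins <- which(bitwAnd(cd, c(1L, 2L, 4L, 8L)) > 0)
      outs <- setdiff(1:4, ins)
      ns <- n[sel, , drop = FALSE]
      if (length(ins) == 1 || length(ins) == 3) {
        v <- if (length(ins) == 1) ins else outs
        o <- setdiff(1:4, v)
        e1 <- edge_point(ns[, v], ns[, o[1]])
        e2 <- edge_point(ns[, v], ns[, o[2]])
        e3 <- edge_point(ns[, v], ns[, o[3]])
        acc[[length(acc) + 1]] <- emit(e1, e2, e3)
      } else {
        v1 <- ins[1]; v2 <- ins[2]; o1 <- outs[1]; o2 <- outs[2]
        e11 <- edge_point(ns[, v1], ns[, o1])
        e12 <- edge_point(ns[, v1], ns[, o2])
        e21 <- edge_point(ns[, v2], ns[, o1])
        e22 <- edge_point(ns[, v2], ns[, o2])
        acc[[length(acc) + 1]] <- emit(e11, e21, e22)
        acc[[length(acc) + 1]] <- emit(e11, e22, e12)
      }
    }
  }
  if (!length(acc)) stop("iso-surface is empty: field does not change sign")
  keys <- do.call(rbind, lapply(acc, `[[`, "keys"))
  allkeys <- c(t(keys))  # corner order e1,e2,e3 per triangle
  # pts blocks are stacked [all e1; all e2; all e3]; interleave to match
  allpts <- do.call(rbind, lapply(acc, function(blk) {
    m <- nrow(blk$keys)
    blk$pts[as.vector(t(matrix(seq_len(3 * m), ncol = 3))), , drop = FALSE]
  }))
  uk <- !duplicated(allkeys)
  vid <- match(allkeys, allkeys[uk])
  verts <- allpts[uk, , drop = FALSE]
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  tri_surface(verts, faces)
}

#' Degrade a velocity field to an imaging modality's resolution
#'
#' Box-averages the source field over each target voxel (and over a
#' `depth_averaging` slab along z when that exceeds the target pitch), then
#' adds i.i.d. Gaussian noise per component.  The average runs over *all*
#' source voxels in the box — wall-adjacent boxes therefore mix lumen flow
#' with the zero-velocity exterior, reproducing the partial-volume
#' underestimation that coarse modalities exhibit near walls.  A target
#' voxel is lumen if at least half its contributing source voxels are.
#'
#' @param field a [velocity_field] (the "true" fine-resolution flow).
#' @param modality a [modality_spec]; its spacing must be >= the source
#'   spacing componentwise (`NULL` spacing means pass-through).
#' @param seed integer seed for the noise; the global RNG state is left
#'   untouched.
#' @return a [velocity_field] at the modality resolution.
#' @export
emulate_modality <- function(field, modality, seed = 1L) {
  stopifnot(inherits(modality, "modality_spec"))
  sp_t <- modality$spacing
  if (is.null(sp_t)) sp_t <- field$spacing
  sp_t <- rep(as.numeric(sp_t), length.out = 3)
  if (any(sp_t < field$spacing - 1e-15))
    stop("modality spacing must be >= source spacing componentwise")
  d <- field$dims
  sp_s <- field$spacing
  dom_lo <- field$origin - sp_s / 2
  extent <- d * sp_s
  nt <- pmax(1, floor(extent / sp_t + 1e-9))
  origin_t <- dom_lo + sp_t / 2
  # per-axis target bin of every source voxel (x and y; z handled below)
  src_x <- field$origin[1] + (seq_len(d[1]) - 1) * sp_s[1]
  src_y <- field$origin[2] + (seq_len(d[2]) - 1) * sp_s[2]
  src_z <- field$origin[3] + (seq_len(d[3]) - 1) * sp_s[3]
  bin <- function(coord, ax) {
    b <- floor((coord - dom_lo[ax]) / sp_t[ax]) + 1L
    b[b > nt[ax]] <- NA_integer_  # leftover sliver beyond the last full box
    b
  }
  bx <- bin(src_x, 1); by <- bin(src_y, 2)
  ix <- rep(bx, times = d[2])
  iy <- rep(by, each = d[1])
  plane_bin <- ix + nt[1] * (iy - 1L)  # NA where out of any box
  nplane <- nt[1] * nt[2]
  win_z <- max(sp_t[3], modality$depth_averaging)
  u_t <- array(0, c(nt, 3))
  mask_t <- array(FALSE, nt)
  mask_num <- array(as.numeric(field$mask), d)
  for (k in seq_len(nt[3])) {
    z_k <- origin_t[3] + (k - 1) * sp_t[3]
    zsel <- which(src_z >= z_k - win_z / 2 - 1e-12 &
                  src_z < z_k + win_z / 2 - 1e-12)
    if (!length(zsel)) next
    pb <- rep(plane_bin, times = length(zsel))
    keep <- !is.na(pb)
    pb <- pb[keep]
    cnt <- tabulate(pb, nbins = nplane)
    acc <- matrix(0, nplane, 3)
    msub <- as.vector(mask_num[, , zsel])[keep]
    rs <- rowsum(msub, pb, reorder = FALSE)
    lum_full <- numeric(nplane); lum_full[as.integer(rownames(rs))] <- rs
    for (c3 in 1:3) {
      us <- as.vector(field$u[, , zsel, c3])[keep]
      s <- rowsum(us, pb, reorder = FALSE)
      acc_full <- numeric(nplane); acc_full[as.integer(rownames(s))] <- s
      acc[, c3] <- acc_full
    }
    nonzero <- cnt > 0
    for (c3 in 1:3) {
      slab <- matrix(0, nt[1], nt[2])
      slab[nonzero] <- acc[nonzero, c3] / cnt[nonzero]
      u_t[, , k, c3] <- slab
    }
    mslab <- matrix(FALSE, nt[1], nt[2])
    mslab[nonzero] <- (lum_full[nonzero] / cnt[nonzero]) >= 0.5
    mask_t[, , k] <- mslab
  }
  if (modality$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(as.integer(seed))
    u_t <- u_t + array(stats::rnorm(length(u_t), 0, modality$noise_sd),
                       dim(u_t))
  }
  velocity_field(u_t, sp_t, origin_t, mask_t)
}
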