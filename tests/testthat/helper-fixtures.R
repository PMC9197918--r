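# Lazily built, cached fixtures shared across test files.  Everything is
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fixture_cache)) {
    val <- switch(name,
      # Poiseuille pipe at the tomographic-PIV preset pitch, in-vitro fluid
      pois_tomo = {
        p <- make_poiseuille(5.655e-3, 24e-3, 0.4376, 0.63e-3)
        p$surface <- compute_vertex_normals(p$surface, c(0, 0, 12e-3))
        p
      },
      # finer Poiseuille for convergence / degradation experiments
      pois_fine = {
        p <- make_poiseuille(5.655e-3, 24e-3, 0.4376, 0.4e-3)
        p$surface <- compute_vertex_normals(p$surface, c(0, 0, 12e-3))
        p
      },
      # aneurysm-like sac phantom with surface, normals and fine WSS
      sac = {
        ps <- phantom_spec(2e-3, 16e-3, sac_radius = 1.6e-3, v_max = 0.4)
        s <- make_sac_phantom(ps, 0.2e-3)
        s$spec <- ps
        s$surface <- compute_vertex_normals(s$surface, c(0, 0, 8e-3))
        s$wss <- wss_pipeline(s$field, s$surface, mu = 0.008113)
        s
      },
      stop("unknown fixture: ", name))
    assign(name, val, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# full gradient -> surface -> traction chain used throughout
wss_pipeline <- function(field, surface, mu, power = 2, n_neighbors = 8) {
  G <- gradient_tensor(field)
  sg <- map_gradients_to_surface(G, surface, power = power,
                                 n_neighbors = n_neighbors)
  wss_vectors(sg, surface, mu)
}

# unit cube surface: 8 vertices, 12 faces, outward winding
cube_surface <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  faces <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = 1
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = 1
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6)   # x = 1
  )
  tri_surface(v, faces)
}

# velocity field from an analytic function u(x, y, z) -> list(ux, uy, uz)
field_from_function <- function(f, dims, spacing, origin = c(0, 0, 0),
                                mask = NULL) {
  dims <- rep(dims, length.out = 3)
  spacing <- rep(spacing, length.out = 3)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  x <- origin[1] + (idx[, 1] - 1) * spacing[1]
  y <- origin[2] + (idx[, 2] - 1) * spacing[2]
  z <- origin[3] + (idx[, 3] - 1) * spacing[3]
  uv <- f(x, y, z)
  u <- array(0, c(dims, 3))
  u[, , , 1] <- array(uv[[1]], dims)
  u[, , , 2] <- array(uv[[2]], dims)
  u[, , , 3] <- array(uv[[3]], dims)
  velocity_field(u, spacing, origin, mask)
}

# interior voxels whose full central stencil stays in the mask
interior_mask <- function(field) {
  m <- field$mask
  d <- field$dims
  sh <- function(a, ax, by) {
    out <- array(FALSE, d)
    n <- d[ax]
    src <- if (by > 0) 2:n else 1:(n - 1)
    dst <- if (by > 0) 1:(n - 1) else 2:n
    ix <- list(1:d[1], 1:d[2], 1:d[3])
    ixs <- ix; ixs[[ax]] <- src
    ixd <- ix; ixd[[ax]] <- dst
    out[ixd[[1]], ixd[[2]], ixd[[3]]] <- a[ixs[[1]], ixs[[2]], ixs[[3]]]
    out
  }
  im <- m
  for (ax in 1:3) im <- im & sh(m, ax, 1) & sh(m, ax, -1)
  im
}
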