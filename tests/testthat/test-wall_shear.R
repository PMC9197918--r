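test_that("vertex normals point inward on sphere and cylinder", {
  # sphere of radius 0.5 via the iso-surfacer, interior point at the centre
  sphere_at <- function(h) {
    n <- ceiling(1.4 / h)
    ax <- seq(-0.7, 0.7, length.out = n)
    phi <- array(0, c(n, n, n))
    for (k in seq_len(n)) phi[, , k] <-
      sqrt(outer(ax^2, ax^2, "+") + ax[k]^2) - 0.5
    compute_vertex_normals(
      iso_surface(phi, rep(ax[2] - ax[1], 3), rep(ax[1], 3)), c(0, 0, 0))
  }
  ang_err <- vapply(c(0.1, 0.05), function(h) {
    s <- sphere_at(h)
    rad <- s$vertices / sqrt(rowSums(s$vertices^2))
    max(acos(pmin(1, rowSums(s$normals * (-rad)))))
  }, numeric(1))
  expect_lt(ang_err[1], 0.2)       # radians
  expect_lt(ang_err[2], ang_err[1])

  cyl <- compute_vertex_normals(cylinder_surface(1e-3, 4e-3, 32, 8),
                                c(0, 0, 2e-3))
  rad <- cbind(cyl$vertices[, 1], cyl$vertices[, 2], 0) / 1e-3
  expect_lt(max(abs(rowSums(cyl$normals * rad) + 1)), 1e-2)
  expect_lt(max(abs(cyl$normals[, 3])), 1e-6)
  expect_identical(cyl$orientation, "inward")
})

test_that("final normals are independent of the input face winding", {
  cyl <- cylinder_surface(1e-3, 4e-3, 24, 6)
  flipped <- tri_surface(cyl$vertices, cyl$faces[, c(1, 3, 2)])
  n1 <- compute_vertex_normals(cyl, c(0, 0, 2e-3))$normals
  n2 <- compute_vertex_normals(flipped, c(0, 0, 2e-3))$normals
  expect_equal(n1, n2)
})

test_that("degenerate and non-manifold surfaces are rejected with diagnostics", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0))  # zero-area triangle
  expect_error(compute_vertex_normals(tri_surface(v, rbind(1:3)), c(0, 0, 1)),
               "vertex ids")
  # three faces sharing one edge
  v4 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))
  f4 <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_error(compute_vertex_normals(tri_surface(v4, f4), c(0, 0, 0)),
               "manifold")
})

test_that("IDW mapping reproduces hand-computed weights", {
  # synthetic gradient field: two valid voxels on the x axis
  d <- c(2, 2, 2)
  g <- array(NA_real_, c(d, 3, 3))
  valid <- array(FALSE, d)
  valid[1, 1, 1] <- TRUE   # centre (0, 0, 0), tensor value 0
  valid[2, 1, 1] <- TRUE   # centre (1, 0, 0), tensor value 3
  g[1, 1, 1, , ] <- 0
  g[2, 1, 1, , ] <- 3
  G <- structure(list(g = g, valid = valid, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0), dims = d,
                      mask = valid), class = "gradient_field")
  surf <- tri_surface(rbind(c(-1, 0, 0)), rbind(c(1, 1, 1)))
  # distances 1 and 2, power 2: (0/1 + 3/4) / (1 + 1/4) = 0.6
  m <- map_gradients_to_surface(G, surf, power = 2, n_neighbors = 8,
                                radius = 3)
  expect_equal(m$tensors[1, 1, 1], 0.6)
  # n_neighbors = 1 short-circuits to the nearest voxel
  m1 <- map_gradients_to_surface(G, surf, n_neighbors = 1, radius = 3)
  expect_equal(m1$tensors[1, 2, 2], 0)
  # coincident vertex takes that voxel exactly
  surf2 <- tri_surface(rbind(c(1, 0, 0)), rbind(c(1, 1, 1)))
  m2 <- map_gradients_to_surface(G, surf2, radius = 3)
  expect_equal(m2$tensors[1, 3, 3], 3)
  # out-of-reach vertex is flagged, not fabricated
  far <- tri_surface(rbind(c(50, 0, 0)), rbind(c(1, 1, 1)))
  mf <- map_gradients_to_surface(G, far, radius = 3)
  expect_false(mf$mapped[1])
  expect_equal(mf$n_unmapped, 1)
  expect_true(all(is.na(mf$tensors[1, , ])))
})

test_that("IDW of a spatially constant tensor returns that constant", {
  ph <- fixture("pois_tomo")
  G <- gradient_tensor(ph$field)
  G$g[] <- 1.7
  m <- map_gradients_to_surface(G, ph$surface)
  expect_equal(unique(round(as.vector(m$tensors[m$mapped, , ]), 10)), 1.7)
})

test_that("wss_vectors evaluates the Newtonian traction componentwise", {
  # single-vertex surface with normal (1, 0, 0); shear u_z = gamma x
  gam <- 120; mu <- 0.004
  n <- rbind(c(1, 0, 0))
  surf <- tri_surface(rbind(c(0, 0, 0)), rbind(c(1, 1, 1)), normals = n)
  tens <- array(0, c(1, 3, 3))
  tens[1, 3, 1] <- gam           # d u_z / d x
  sg <- list(tensors = tens, mapped = TRUE, n_unmapped = 0)
  wss <- wss_vectors(sg, surf, mu)
  expect_equal(wss$tau[1, ], c(0, 0, mu * gam))
  expect_equal(wss$magnitude[1], mu * gam)
  # zero gradient -> zero traction
  sg0 <- list(tensors = array(0, c(1, 3, 3)), mapped = TRUE, n_unmapped = 0)
  expect_equal(wss_vectors(sg0, surf, mu)$magnitude[1], 0)
  # tangential component of a purely tangential traction is itself
  wt <- wss_vectors(sg, surf, mu, tangential = TRUE)
  expect_equal(wt$tangential[1], wt$magnitude[1])
  expect_error(wss_vectors(sg, tri_surface(rbind(c(0, 0, 0)), rbind(c(1, 1, 1))), mu),
               "normals")
})

test_that("pipeline WSS on the Poiseuille cylinder approaches the analytic wall value", {
  mu <- 0.008113; vmax <- 0.4376; R <- 5.655e-3
  ana <- analytic_wss_poiseuille(mu, vmax, R)
  med <- vapply(list(fixture("pois_tomo"), fixture("pois_fine")), function(ph) {
    w <- wss_pipeline(ph$field, ph$surface, mu)
    stats::median(w$magnitude[w$mapped])
  }, numeric(1))
  err <- abs(med - ana) / ana
  expect_lt(err[1], 0.20)   # validation bound at PIV-like resolution
  expect_lt(err[2], err[1]) # refinement moves the estimate toward analytic
})

test_that("WSS magnitude is invariant under a rigid rotation of the scene", {
  ph <- fixture("pois_tomo")
  w0 <- wss_pipeline(ph$field, ph$surface, 0.008113)
  # rotate everything 90 degrees about z: (x, y) -> (-y, x)
  f <- ph$field
  d <- f$dims
  rot_u <- array(0, c(d[2], d[1], d[3], 3))
  rot_m <- array(FALSE, c(d[2], d[1], d[3]))
  # new index (i', j') = (d2 + 1 - j, i)
  perm <- function(a) aperm(a, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  rot_u[, , , 1] <- -perm(array(f$u[, , , 2], d))
  rot_u[, , , 2] <- perm(array(f$u[, , , 1], d))
  rot_u[, , , 3] <- perm(array(f$u[, , , 3], d))
  rot_m[] <- perm(f$mask)
  # the grid is centred on the axis, so the rotated origin mirrors y
  forigin <- c(-(f$origin[2] + (d[2] - 1) * f$spacing[2]), f$origin[1],
               f$origin[3])
  frot <- velocity_field(rot_u, f$spacing[c(2, 1, 3)], forigin, rot_m)
  vr <- ph$surface$vertices %*% t(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3,
                                         byrow = TRUE))
  srot <- compute_vertex_normals(tri_surface(vr, ph$surface$faces),
                                 c(0, 0, 12e-3))
  wr <- wss_pipeline(frot, srot, 0.008113)
  ok <- w0$mapped & wr$mapped
  expect_gt(mean(ok), 0.99)
  expect_equal(wr$magnitude[ok], w0$magnitude[ok], tolerance = 1e-6)
})

test_that("normalization by the parent vessel behaves as specified", {
  mags <- c(2, 2, 2, 5)
  fld <- structure(list(magnitude = mags, mapped = rep(TRUE, 4),
                        surface = NULL), class = "surface_vector_field")
  nw <- normalize_wss(fld, parent_patch = 1:3)
  expect_equal(nw$values, mags / 2)
  # patch = all vertices of a field with mean 2 -> vertex at 5 maps to 2.5
  fld2 <- structure(list(magnitude = c(1, 2, 3, 5, 2, 2, 2, 2, 2, 2),
                         mapped = rep(TRUE, 10), surface = NULL),
                    class = "surface_vector_field")
  # mean is (1+2+3+5+2*6)/10 = 2.3
  fldu <- structure(list(magnitude = rep(1, 6), mapped = rep(TRUE, 6),
                         surface = NULL), class = "surface_vector_field")
  expect_equal(unique(normalize_wss(fldu, 1:6)$values), 1)
  expect_error(normalize_wss(fldu, integer(0)), "nonempty")
  z <- structure(list(magnitude = rep(0, 3), mapped = rep(TRUE, 3),
                      surface = NULL), class = "surface_vector_field")
  expect_error(normalize_wss(z, 1:3), "degenerate")
  expect_equal(normalize_wss(fld2, 1:10)$values[4], 5 / 2.3)
})

test_that("neck WSS on the sac phantom exceeds twice the sac mean", {
  sac <- fixture("sac")
  v <- sac$surface$vertices
  ctr <- sac$spec$sac_center_offset
  dsac <- sqrt(rowSums(sweep(v, 2, ctr, "-")^2))
  rtube <- sqrt(v[, 1]^2 + v[, 2]^2)
  on_sphere <- abs(dsac - sac$spec$sac_radius) < 0.15 * sac$spec$sac_radius
  neck <- on_sphere & rtube < sac$spec$tube_radius
  sacwall <- on_sphere & rtube > sac$spec$tube_radius * 1.05
  parent <- rtube < sac$spec$tube_radius * 1.02 &
    abs(v[, 3] - ctr[3]) > sac$spec$sac_radius + 1e-3
  nw <- normalize_wss(sac$wss, which(parent))
  expect_gt(mean(nw$values[neck], na.rm = TRUE),
            2 * mean(nw$values[sacwall], na.rm = TRUE))
})

test_that("similarity scaling of WSS multiplies by the three ratios", {
  expect_equal(scale_wss(1, similarity_spec(1, 1, 1)), 1)
  expect_equal(scale_wss(1, similarity_spec(0.5, 2, 3)), 3)
  sim <- build_similarity(fluid_spec(1060, 0.0035), fluid_spec(1147, 0.008113),
                          d_ratio = 3.77)
  # algebra oracle: with Reynolds matching the overall factor collapses to
  # (mu_vivo/mu_vitro)^2 * (rho_vitro/rho_vivo) * d_ratio^2
  fac_oracle <- (0.0035 / 0.008113)^2 * (1147 / 1060) * 3.77^2
  expect_equal(scale_wss(1, sim), fac_oracle)
  expect_equal(scale_wss(scale_wss(2.2, sim), invert_similarity(sim)), 2.2)
  # surface_vector_field route scales tau and magnitude together
  sac <- fixture("sac")
  sw <- scale_wss(sac$wss, sim)
  expect_equal(sw$magnitude, sac$wss$magnitude * fac_oracle)
  expect_equal(sw$tau, sac$wss$tau * fac_oracle)
})

test_that("summaries honour mapping flags and the mean <= peak invariant", {
  fld <- structure(list(magnitude = c(1, 2, 3), mapped = rep(TRUE, 3),
                        surface = NULL), class = "surface_vector_field")
  s <- summarize_wss(fld)
  expect_equal(s$mean, 2)
  expect_equal(s$peak, 3)
  one <- structure(list(magnitude = 4.2, mapped = TRUE, surface = NULL),
                   class = "surface_vector_field")
  s1 <- summarize_wss(one)
  expect_equal(s1$mean, s1$peak)
  unm <- structure(list(magnitude = c(1, NA), mapped = c(TRUE, FALSE),
                        surface = NULL), class = "surface_vector_field")
  expect_equal(summarize_wss(unm)$n_vertices, 1)
  none <- structure(list(magnitude = NA_real_, mapped = FALSE, surface = NULL),
                    class = "surface_vector_field")
  expect_error(summarize_wss(none), "no mapped")
  sac <- fixture("sac")
  sfull <- summarize_wss(sac$wss)
  expect_lte(sfull$mean, sfull$peak)
  saw <- summarize_wss(sac$wss, area_weighted = TRUE)
  expect_lte(saw$mean, sfull$peak)
})
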