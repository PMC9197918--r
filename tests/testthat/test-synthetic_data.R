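test_that("Poiseuille phantom samples the exact parabolic profile", {
  R <- 2e-3; L <- 8e-3; vmax <- 0.7
  ph <- make_poiseuille(R, L, vmax, 0.2e-3)
  f <- ph$field
  # axis voxel carries v_max exactly, and is the field maximum
  ctr <- which(abs(voxel_centers(f)[, 1]) < 1e-12 &
               abs(voxel_centers(f)[, 2]) < 1e-12)
  expect_true(length(ctr) > 0)
  expect_equal(unique(f$u[, , , 3][ctr]), vmax)
  expect_equal(max(f$u[, , , 3]), vmax)
  # every lumen voxel matches the analytic profile; wall limit is no-slip
  xyz <- voxel_centers(f, f$mask)
  r2 <- xyz[, 1]^2 + xyz[, 2]^2
  expect_equal(f$u[, , , 3][f$mask], vmax * (1 - r2 / R^2))
  expect_true(all(r2 <= R^2))
  expect_error(make_poiseuille(R, L, vmax, spacing = R), "spacing")
})

test_that("lumen-average axial velocity converges to v_max / 2", {
  # analytic oracle: mean of v_max (1 - r^2/R^2) over the disc = v_max/2
  R <- 2e-3; vmax <- 0.7
  errs <- vapply(c(0.25e-3, 0.125e-3), function(h) {
    f <- make_poiseuille(R, 4e-3, vmax, h)$field
    abs(mean(f$u[, , , 3][f$mask]) - vmax / 2)
  }, numeric(1))
  expect_lt(errs[1] / (vmax / 2), 0.05)
  expect_lt(errs[2], errs[1])
})

test_that("analytic pipe-flow WSS follows 2 mu v_max / R", {
  expect_equal(analytic_wss_poiseuille(1, 1, 1), 2)
  # oracle: 2 * 0.0035 * 0.5 / 0.0015 by hand
  expect_equal(analytic_wss_poiseuille(0.0035, 0.5, 0.0015), 7 / 3,
               tolerance = 1e-12)
  w <- analytic_wss_poiseuille(0.004, 0.3, 1e-3)
  expect_equal(analytic_wss_poiseuille(0.004, 0.3, 2e-3), w / 2)
  expect_error(analytic_wss_poiseuille(0, 1, 1), "> 0")
})

test_that("sac phantom degenerates to the plain tube when sac_radius is 0", {
  ps <- phantom_spec(2e-3, 8e-3, sac_radius = 0, v_max = 0.5)
  a <- make_sac_phantom(ps, 0.4e-3)
  b <- make_poiseuille(2e-3, 8e-3, 0.5, 0.4e-3)
  expect_identical(a$field$u, b$field$u)
  expect_identical(a$field$mask, b$field$mask)
  expect_identical(a$surface$vertices, b$surface$vertices)
  expect_error(
    make_sac_phantom(phantom_spec(1e-3, 8e-3, sac_radius = 0.5e-3,
                                  sac_center_offset = c(5e-3, 0, 4e-3)),
                     0.2e-3),
    "disjoint")
})

test_that("sac phantom discrete divergence decays first-order under refinement", {
  ps <- phantom_spec(1.0e-3, 4e-3, sac_radius = 0.8e-3, v_max = 0.4)
  maxdiv <- vapply(c(5e-5, 2.5e-5), function(h) {
    s <- make_sac_phantom(ps, h, with_surface = FALSE)
    dv <- divergence(gradient_tensor(s$field))
    max(abs(dv[interior_mask(s$field)]))
  }, numeric(1))
  expect_lt(maxdiv[2], 0.6 * maxdiv[1])  # first-order would give 0.5
})

test_that("sac interior contains a vortex core (Q > 0)", {
  sac <- fixture("sac")
  G <- gradient_tensor(sac$field)
  q <- q_criterion(G)
  ctr <- sac$spec$sac_center_offset
  vc <- voxel_centers(sac$field)
  core <- (vc[, 1] - ctr[1])^2 + (vc[, 2] - ctr[2])^2 +
    (vc[, 3] - ctr[3])^2 < (0.7 * sac$spec$sac_radius)^2
  expect_gt(max(q[core & G$valid], na.rm = TRUE), 0)
})

test_that("modality emulation is the identity at matched resolution", {
  ph <- fixture("pois_tomo")
  same <- emulate_modality(ph$field,
                           modality_spec("cfd"))
  expect_identical(same$u, ph$field$u)
  expect_identical(same$mask, ph$field$mask)
  expect_error(
    emulate_modality(ph$field, modality_spec("tomo_piv", spacing = 0.1e-3)),
    ">=")
})

test_that("box-averaging preserves constants and contracts the maximum", {
  const <- field_from_function(function(x, y, z)
    list(rep(1, length(x)), rep(0, length(x)), rep(0, length(x))),
    dims = c(12, 12, 12), spacing = 1e-3)
  for (sp in c(1.5e-3, 2e-3, 3.7e-3)) {
    dg <- emulate_modality(const, modality_spec("tomo_piv", spacing = sp))
    expect_equal(unique(as.vector(dg$u[, , , 1])), 1)
    expect_equal(unique(as.vector(dg$u[, , , 2:3])), 0)
  }
  # contraction in max-norm on a non-trivial field
  ph <- fixture("pois_fine")
  for (sp in c(0.63e-3, 1.1e-3, 1.9e-3)) {
    dg <- emulate_modality(ph$field, modality_spec("tomo_piv", spacing = sp))
    expect_lte(max(abs(dg$u)), max(abs(ph$field$u)))
  }
})

test_that("degrading a concave profile pulls the peak below v_max", {
  ph <- fixture("pois_tomo")
  dg <- emulate_modality(ph$field,
                         modality_spec("tomo_piv", spacing = 1.26e-3))
  expect_lt(max(dg$u[, , , 3]), 0.4376)
  # oracle: brute-force box average over one centre voxel
  f <- ph$field
  xyz <- voxel_centers(f)
  ctr_t <- voxel_centers(dg)[which.max(dg$u[, , , 3]), ]
  inbox <- abs(xyz[, 1] - ctr_t[1]) <= 0.63e-3 &
           abs(xyz[, 2] - ctr_t[2]) <= 0.63e-3 &
           abs(xyz[, 3] - ctr_t[3]) <= 0.63e-3
  # tolerant half-open handling: compare against the emulator within the
  # discretisation of box membership at the box faces
  expect_equal(max(dg$u[, , , 3]), mean(f$u[, , , 3][inbox]),
               tolerance = 0.05)
})

test_that("noise is seed-deterministic and seed-sensitive", {
  ph <- fixture("pois_tomo")
  ms <- modality_spec("mri")
  a <- emulate_modality(ph$field, ms, seed = 7)
  b <- emulate_modality(ph$field, ms, seed = 7)
  c <- emulate_modality(ph$field, ms, seed = 8)
  expect_identical(a$u, b$u)
  expect_false(identical(a$u, c$u))
  # the global RNG stream is left untouched
  set.seed(123); x1 <- rnorm(3)
  set.seed(123); invisible(emulate_modality(ph$field, ms, seed = 9))
  expect_identical(rnorm(3), x1)
})

test_that("stereo-PIV depth averaging flattens axial structure", {
  # field varying along z only; a 1 mm slab average must smooth it
  f <- field_from_function(function(x, y, z)
    list(sin(2 * pi * z / 2e-3), rep(0, length(x)), rep(0, length(x))),
    dims = c(6, 6, 40), spacing = 0.25e-3)
  dg <- emulate_modality(f, modality_spec("stereo_piv",
                                          spacing = c(0.25e-3, 0.25e-3, 0.25e-3),
                                          depth_averaging = 1e-3))
  expect_lt(max(abs(dg$u[, , , 1])), max(abs(f$u[, , , 1])))
  # oracle: averaging a unit sine over half its period attenuates the
  # peak to 2/pi = 0.637 (discrete window, hence the loose tolerance)
  expect_equal(max(abs(dg$u[3, 3, 10:30, 1])), 2 / pi, tolerance = 0.12)
})
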