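test_that("phantom constructor enforces its invariants", {
  expect_error(heart_phantom(c(15, 15, 30), c(14, 16, 36)),
               "epicardial semi-axes must strictly exceed")
  expect_error(heart_phantom(c(15, 15, 30), c(18, 18, 36),
                             lv_truncation_fraction = 1.2),
               "truncation_fraction")
  expect_error(heart_phantom(c(15, 15, 30), c(18, 18, 36), es_scale = 1),
               "es_scale")
  expect_error(heart_phantom(c(15, -1, 30), c(18, 18, 36)),
               "lv_endo_semiaxes")
  expect_error(heart_phantom(c(15, 15, 30), c(18, 18, 36),
                             la_appendage = list(amplitude = 3)),
               "la_appendage")
})

test_that("analytic volumes match solid-geometry closed forms", {
  el <- heart_phantom(c(15, 15, 45), c(18, 18, 48), lv_truncation_fraction = 1)
  expect_equal(analytic_volume(el, "LV", "endo", "ED") * 1000,
               4 / 3 * pi * 15 * 15 * 45, tolerance = 1e-12)
  sph <- sphere_phantom(10)
  expect_equal(analytic_volume(sph) * 1000, 4 / 3 * pi * 1000,
               tolerance = 1e-12)
  # truncated: V = pi*a*b*c * (f - f^3/3 + 2/3)
  tr <- heart_phantom(c(12, 14, 30), c(16, 18, 34),
                      lv_truncation_fraction = 0.8)
  expect_equal(analytic_volume(tr) * 1000,
               pi * 12 * 14 * 30 * (0.8 - 0.8^3 / 3 + 2 / 3),
               tolerance = 1e-12)
})

test_that("analytic mass is wall volume times density, zero for zero density", {
  ph <- heart_phantom(c(14, 14, 30), c(20, 20, 36), myocardial_density = 1.05)
  wall <- analytic_volume(ph, "LV", "epi", "ES") -
    analytic_volume(ph, "LV", "endo", "ES")
  expect_equal(analytic_mass(ph, "ES"), wall * 1.05, tolerance = 1e-12)
  ph0 <- heart_phantom(c(14, 14, 30), c(20, 20, 36), myocardial_density = 0)
  expect_identical(analytic_mass(ph0), 0)
})

test_that("presets hit their scale targets and are seed-deterministic", {
  for (s in 1:8) {
    ph <- make_phantom("canine", seed = s)
    expect_gt(analytic_volume(ph), 18)
    expect_lt(analytic_volume(ph), 29)
    m <- analytic_mass(ph, "ED")
    expect_gt(m, 94.1)
    expect_lt(m, 105.1)
  }
  for (s in 1:4) {
    ph <- make_phantom("human", seed = s)
    expect_gt(analytic_volume(ph), 78)
    expect_lt(analytic_volume(ph), 276)
  }
  expect_equal(make_phantom("canine", seed = 7),
               make_phantom("canine", seed = 7))
})

test_that("end-systole strictly decreases the endocardial volume", {
  for (s in 1:5) {
    ph <- make_phantom("canine", seed = s)
    expect_lt(analytic_volume(ph, "LV", "endo", "ES"),
              analytic_volume(ph, "LV", "endo", "ED"))
  }
})

test_that("voxel oracle reproduces the sphere closed form and converges", {
  sph <- sphere_phantom(10)
  v_true <- 4 / 3 * pi * 1000 / 1000
  expect_equal(voxel_volume(sph, resolution = 0.1), v_true, tolerance = 0.002)
  # lattice-alignment luck makes single halvings fluctuate by a few percent;
  # require near-monotone decrease and a large overall gain
  errs <- sapply(c(1.6, 0.8, 0.4, 0.2, 0.1), function(res)
    abs(voxel_volume(sph, resolution = res) - v_true))
  expect_true(all(errs[-1] <= errs[-length(errs)] * 1.1))
  expect_lt(errs[5], errs[1] / 100)
})

test_that("analytic and voxel volumes agree for appendage-free phantoms", {
  for (s in c(1, 11)) {
    ph <- make_phantom(if (s <= 10) "canine" else "human", seed = s)
    for (layer in c("endo", "epi")) {
      expect_equal(analytic_volume(ph, "LV", layer),
                   voxel_volume(ph, "LV", layer, resolution = 0.2),
                   tolerance = 0.003)
    }
    expect_equal(analytic_volume(ph, "LA"),
                 voxel_volume(ph, "LA", resolution = 0.2), tolerance = 0.003)
  }
})

test_that("appendage quadrature matches the voxel oracle closely", {
  ph <- make_phantom("canine", seed = 3,
                     la_appendage = between_planes_appendage())
  expect_equal(analytic_volume(ph, "LA"),
               voxel_volume(ph, "LA", resolution = 0.2), tolerance = 0.001)
})

test_that("tilted mitral plane keeps analytic and voxel volumes in agreement", {
  ph <- make_phantom("canine", seed = 4, mitral_tilt = 15)
  expect_equal(analytic_volume(ph, "LV", "endo"),
               voxel_volume(ph, "LV", "endo", resolution = 0.2),
               tolerance = 0.003)
})

test_that("voxel oracle handles degenerate chambers", {
  ph <- heart_phantom(c(10, 10, 10), c(12, 12, 12))  # no LA
  expect_warning(v <- voxel_volume(ph, "LA", resolution = 0.5), "unreliable")
  expect_identical(v, 0)
  expect_warning(voxel_volume(sphere_phantom(1), resolution = 0.9),
                 "unreliable")
})
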