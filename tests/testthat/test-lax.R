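test_that("split_contour recovers radii of centred and offset circles", {
  phi <- 2 * pi * (0:359) / 360
  circ <- cbind(10 * cos(phi), 10 * sin(phi))
  prof <- split_contour(manual_lax_contour(circ), long_axis = z_axis)
  mid <- abs(prof$level) < 8
  expect_equal(prof$radius[mid], sqrt(100 - prof$level[mid]^2),
               tolerance = 1e-3)
  # offset 2 mm perpendicular to the axis: max radii 12 and 8
  off <- cbind(10 * cos(phi) + 2, 10 * sin(phi))
  prof2 <- suppressMessages(
    split_contour(manual_lax_contour(off), long_axis = z_axis))
  expect_equal(max(prof2$radius[prof2$angle == 0]), 12, tolerance = 1e-3)
  expect_equal(max(prof2$radius[prof2$angle == 180]), 8, tolerance = 1e-3)
})

test_that("split_contour matches the truncated-ellipsoid closed form", {
  ax <- axisym_phantom(a = 14, c = 30, f = 0.9)
  lx <- slice_lax(ax, 6, chambers = "LV", layers = "endo")
  prof <- split_contour(lx[1, ], long_axis = attr(lx, "long_axis"))
  inside <- prof$level > -28 & prof$level < 25
  expect_equal(prof$radius[inside],
               14 * sqrt(1 - prof$level[inside]^2 / 900),
               tolerance = 2e-3)
})

test_that("split_contour rejects planes not containing the axis", {
  ph <- make_phantom("canine", seed = 1)
  st <- slice_sax(ph, 8, 2)
  expect_error(split_contour(st[1, ], long_axis = attr(st, "long_axis")),
               "long-axis direction")
})

test_that("triangle-fan cylinder volumes match the closed-form fan/sector areas", {
  R <- 10; H <- 30
  cyl <- cylinder_lax_set(R, H, 6)
  # uncorrected inscribed fan: H * 2N * r^2/2 * sin(pi/N) = 3 R^2 H at N = 6
  expect_equal(rotational_volume(cyl, 64, chord_correction = FALSE),
               3 * R^2 * H / 1000, tolerance = 1e-12)
  # chord correction recovers pi R^2 H exactly for the axisymmetric case
  expect_equal(rotational_volume(cyl, 64, chord_correction = TRUE),
               pi * R^2 * H / 1000, tolerance = 1e-12)
  # N -> large: uncorrected converges to the true cylinder volume
  expect_equal(rotational_volume(cylinder_lax_set(R, H, 96), 64,
                                 chord_correction = FALSE),
               pi * R^2 * H / 1000, tolerance = 1e-3)
})

test_that("rotational volume of solids of revolution is N- and azimuth-invariant", {
  ax <- axisym_phantom()
  va <- analytic_volume(ax)
  vols <- sapply(c(2, 3, 6, 12), function(N)
    rotational_volume(slice_lax(ax, N), 256))
  expect_equal(vols, rep(va, 4), tolerance = 1e-3)
  expect_lt(max(vols) - min(vols), 1e-6 * va)
  offs <- sapply(c(0, 7.3, 15, 28.6), function(o)
    rotational_volume(slice_lax(ax, 6, angle_offset = o), 256))
  expect_lt((max(offs) - min(offs)) / mean(offs), 1e-4)
})

test_that("level-grid refinement is converged at the default resolution", {
  ph <- make_phantom("canine", seed = 2)
  lx <- slice_lax(ph, 6)
  v256 <- rotational_volume(lx, 256)
  v512 <- rotational_volume(lx, 512)
  expect_lt(abs(v512 - v256) / v256, 0.001)
})

test_that("narrow between-plane LA appendage is undersampled from below", {
  ph <- make_phantom("canine", seed = 3,
                     la_appendage = between_planes_appendage())
  vox <- voxel_volume(ph, "LA", resolution = 0.2)
  errs <- sapply(c(3, 12, 48), function(N)
    rotational_volume(slice_lax(ph, N), 256, chamber = "LA") - vox)
  expect_true(all(errs < 0))          # star-shaped: converges from below
  expect_true(all(diff(abs(errs)) < 0))  # and monotonically over this ladder
})

test_that("mass_lax matches wall-volume arithmetic and validates inputs", {
  ph <- make_phantom("canine", seed = 1)
  es <- slice_lax(ph, 6, "ES")
  m <- mass_lax(es, es)
  wall <- rotational_volume(es, chamber = "LV", layer = "epi") -
    rotational_volume(es, chamber = "LV", layer = "endo")
  expect_equal(m, wall * 1.05, tolerance = 1e-12)
  ed <- slice_lax(ph, 6, "ED")
  expect_error(mass_lax(ed, es), "phase")
  expect_error(mass_lax(es, slice_lax(ph, 4, "ES")), "plane angles")
})
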