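test_that("polygon_area: unit square, orientation independence, circle limit", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_identical(polygon_area(sq), 1)
  expect_identical(polygon_area(sq[4:1, ]), 1)
  phi <- 2 * pi * (0:359) / 360
  circ <- cbind(20 * cos(phi), 20 * sin(phi))
  expect_equal(polygon_area(circ), pi * 400, tolerance = 1e-4)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 0))), "3")
})

test_that("clip_basal: no-crossing identity, fully atrial empty, centre-line halving", {
  sq <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  contour <- tibble::tibble(
    chamber = "LV", layer = "endo", phase = "ED", slice = 1L,
    angle = NA_real_, vertices = list(sq),
    plane = list(new_plane(c(0, 0, 0), c(0, 0, 1),
                           cbind(c(1, 0, 0), c(0, 1, 0)))))
  above <- list(normal = c(0, 0, 1), d = 5)      # mitral plane above slice
  below <- list(normal = c(0, 0, 1), d = -5)     # mitral plane below slice
  expect_equal(clip_basal(contour, above)$vertices[[1]], sq)
  expect_message(out <- clip_basal(contour, below), "atrial")
  expect_equal(nrow(out), 0L)
  # oblique plane whose trace is the line y = 0: area exactly halved
  halfing <- list(normal = c(0, 1, 1) / sqrt(2), d = 0)
  clipped <- clip_basal(contour, halfing)
  expect_equal(polygon_area(clipped), 2, tolerance = 1e-12)
})

test_that("stack volumes follow the effective-spacing summation", {
  sph <- sphere_phantom(10)
  # sphere, fine slices: within 1% of 4.189 ml
  expect_equal(stack_volume(slice_sax(sph, 1, 0)), 4 / 3 * pi,
               tolerance = 0.01)
  # gap attribution: 8 + 2 behaves as 10 mm spacing on identical areas
  st80 <- slice_sax(sph, 10, 0)
  st82 <- slice_sax(sph, 8, 2)
  z80 <- sapply(st80$plane, function(p) p$origin[3])
  z82 <- sapply(st82$plane, function(p) p$origin[3])
  expect_equal(z80, z82)
  expect_equal(stack_volume(st82), stack_volume(st80), tolerance = 1e-12)
})

test_that("stack_volume rejects mixed chamber/layer selections", {
  ph <- make_phantom("canine", seed = 1)
  st <- slice_sax(ph, 8, 2)
  expect_error(stack_volume(st, chamber = c("LV", "LA"), layer = "endo"),
               "single chamber")
  expect_error(stack_volume(st, chamber = "LV", layer = c("endo", "epi")),
               "single chamber")
})

test_that("stack_volume is invariant under in-plane rigid motion of contours", {
  ph <- make_phantom("canine", seed = 2)
  st <- slice_sax(ph, 8, 2)
  v0 <- stack_volume(st, clip = FALSE)
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  st$vertices <- lapply(st$vertices, function(v)
    sweep(v %*% t(Rm), 2, c(-3, 8), "+"))
  expect_equal(stack_volume(st, clip = FALSE), v0, tolerance = 1e-12)
})

test_that("dropping the basal slice removes exactly area x spacing", {
  ph <- make_phantom("canine", seed = 7)
  st <- slice_sax(ph, 5, 0, chambers = "LV", layers = "endo")
  v0 <- stack_volume(st, clip = FALSE)
  basal <- st[st$slice == min(st$slice), ]
  dropped <- st[st$slice != min(st$slice), ]
  # preserve attributes through manual subset
  for (a in c("thickness", "gap", "mitral_plane", "long_axis"))
    attr(dropped, a) <- attr(st, a)
  class(dropped) <- class(st)
  expect_equal(v0 - stack_volume(dropped, clip = FALSE),
               polygon_area(basal) * 5 / 1000, tolerance = 1e-12)
})

test_that("basal clipping moves a tilted-base stack toward the oracle", {
  errs <- sapply(1:5, function(s) {
    ph <- make_phantom("canine", seed = s, mitral_tilt = 15)
    vox <- voxel_volume(ph, "LV", "endo", "ED", resolution = 0.3)
    st <- slice_sax(ph, 5, 0)
    c(clip = abs(stack_volume(st, TRUE) - vox),
      noclip = abs(stack_volume(st, FALSE) - vox))
  })
  expect_lt(mean(errs["clip", ]), mean(errs["noclip", ]))
})

test_that("mass_sax composes wall volume and density with consistency checks", {
  ph <- make_phantom("canine", seed = 1)
  es <- slice_sax(ph, 8, 2, "ES")
  m <- mass_sax(es, es, density = 1.05)
  wall <- stack_volume(es, chamber = "LV", layer = "epi") -
    stack_volume(es, chamber = "LV", layer = "endo")
  expect_equal(m, wall * 1.05, tolerance = 1e-12)
  ed <- slice_sax(ph, 8, 2, "ED")
  expect_error(mass_sax(ed, es), "phase")
  expect_error(mass_sax(es, slice_sax(ph, 5, 0, "ES")), "spacing")
})

test_that("function_params computes SV and EF with the documented contracts", {
  fp <- function_params(120, 48)
  expect_equal(fp$sv, 72)
  expect_equal(fp$ef, 60)
  expect_equal(function_params(100, 100)$ef, 0)
  expect_equal(function_params(100, 0)$ef, 100)
  expect_error(function_params(0, 0), "undefined")
  expect_warning(fp2 <- function_params(100, 110), "negative")
  expect_equal(fp2$ef, -10)
})
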