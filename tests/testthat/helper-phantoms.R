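# Fixture builders shared across test files. All geometry is generated in
# code; no stored fixtures.

sphere_phantom <- function(r = 10, wall = 2) {
  heart_phantom(c(r, r, r), c(r + wall, r + wall, r + wall),
                lv_truncation_fraction = 1)
}

# axisymmetric truncated-ellipsoid phantom (solid of revolution)
axisym_phantom <- function(a = 14, c = 30, wall = 6, f = 0.9) {
  heart_phantom(c(a, a, c), c(a + wall, a + wall, c + wall),
                lv_truncation_fraction = f)
}

# narrow LA appendage placed between the default 6 LAX planes (centred 15 deg,
# Gaussian SD 6 deg => negligible at the sampled azimuths 0/30/.../330)
between_planes_appendage <- function(amplitude = 8, center = 15) {
  list(amplitude = amplitude, angular_center = center, angular_width = 6,
       axial_center = NA, axial_width = 8)
}

# one-row LAX-style contour tibble in the x-z plane (angle 0), for testing
# split_contour / rotational primitives on hand-built shapes
manual_lax_contour <- function(vertices, angle = 0) {
  pl <- lax_plane_for_test(angle)
  tibble::tibble(chamber = "LV", layer = "endo", phase = "ED",
                 slice = NA_integer_, angle = angle,
                 vertices = list(vertices), plane = list(pl))
}

lax_plane_for_test <- function(angle_deg) {
  t <- angle_deg * pi / 180
  new_plane(c(0, 0, 0), c(-sin(t), cos(t), 0),
            cbind(c(cos(t), sin(t), 0), c(0, 0, 1)))
}

z_axis <- list(point = c(0, 0, 0), direction = c(0, 0, 1))

# hand-built lax_set of 2N rectangle half-profiles: a cylinder of radius R and
# height H sampled by n_planes radial planes
cylinder_lax_set <- function(R = 10, H = 30, n_planes = 6) {
  angles <- (0:(n_planes - 1)) * 180 / n_planes
  rows <- lapply(angles, function(a) {
    manual_lax_contour(rbind(c(-R, 0), c(R, 0), c(R, H), c(-R, H)), angle = a)
  })
  x <- dplyr::bind_rows(rows)
  class(x) <- c("lax_set", "contour_set", class(tibble::tibble()))
  attr(x, "long_axis") <- z_axis
  attr(x, "plane_angles") <- angles
  x
}
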