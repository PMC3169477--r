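# Brute-force voxel-counting volume oracle. The volume is the number of voxel
# centres inside the surface times resolution^3 -- the independent check for
# every other volume computation in the package. Counting is exact on a fixed
# cubic lattice with centres at (k + 0.5) * resolution; for ellipsoidal
# chambers the per-column count is evaluated arithmetically (same number as
# enumerating every voxel, without materialising the grid), for the
# appendage-bearing LA each axial level is tested point-by-point in polar form.

# number of lattice centres (k + 0.5) * res lying in [lo, hi] (vectorised)
count_centers_in <- function(lo, hi, res) {
  n <- floor(hi / res - 0.5) - ceiling(lo / res - 0.5) + 1
  pmax(n, 0)
}

lattice_axis <- function(lo, hi, res) {
  ks <- (ceiling(lo / res - 0.5) - 1L):(floor(hi / res - 0.5) + 1L)
  (ks + 0.5) * res
}

# voxel count inside ellipsoid (semi-axes sem, centre ctr) intersected with
# half-space normal . p <= d (optional)
count_ellipsoid_halfspace <- function(sem, ctr, res, normal = NULL, d = NULL) {
  a <- sem[1]; b <- sem[2]; c <- sem[3]
  if (any(sem <= 0)) return(0)
  xs <- lattice_axis(ctr[1] - a, ctr[1] + a, res)
  zs <- lattice_axis(ctr[3] - c, ctr[3] + c, res)
  X <- matrix(xs, nrow = length(xs), ncol = length(zs))
  Z <- matrix(zs, nrow = length(xs), ncol = length(zs), byrow = TRUE)
  rad2 <- 1 - ((X - ctr[1]) / a)^2 - ((Z - ctr[3]) / c)^2
  inside <- rad2 > 0
  yw <- sqrt(pmax(rad2, 0)) * b
  lo <- ctr[2] - yw
  hi <- ctr[2] + yw
  if (!is.null(normal)) {
    q <- d - normal[1] * X - normal[3] * Z
    if (abs(normal[2]) < 1e-12) {
      inside <- inside & (q >= 0)
    } else if (normal[2] > 0) {
      hi <- pmin(hi, q / normal[2])
    } else {
      lo <- pmax(lo, q / normal[2])
    }
  }
  cnt <- count_centers_in(lo, hi, res)
  sum(cnt[inside])
}

# voxel count of the LA with appendage: per-level polar membership test
count_la_appendage <- function(phantom, res) {
  s <- phantom$la_semiaxes
  zc <- la_center_z(phantom)
  rmax <- max(s[1], s[2]) + phantom$la_appendage$amplitude
  xs <- lattice_axis(-rmax, rmax, res)
  ys <- xs
  X <- matrix(xs, nrow = length(xs), ncol = length(ys))
  Y <- matrix(ys, nrow = length(xs), ncol = length(ys), byrow = TRUE)
  RHO <- sqrt(X^2 + Y^2)
  TH <- atan2(Y, X)
  zs <- lattice_axis(zc - s[3], zc + s[3], res)
  total <- 0
  for (z in zs) {
    if (abs(z - zc) >= s[3]) next
    r <- la_radius(phantom, TH, z)
    total <- total + sum(RHO <= r)
  }
  total
}

#' Voxel-counting volume oracle
#'
#' Counts voxel centres of a cubic lattice (spacing `resolution`) inside the
#' requested chamber surface and multiplies by `resolution^3`. This is the
#' independent brute-force oracle against which the analytic, slice-summation
#' and rotational volumes are validated.
#'
#' @inheritParams analytic_volume
#' @param resolution Voxel edge length in mm (default 0.1).
#' @return Volume in ml. A warning is issued when fewer than 100 voxels fall
#'   inside. A phantom without an atrium yields 0 ml for `chamber = "LA"`.
#' @export
voxel_volume <- function(phantom, chamber = c("LV", "LA"),
                         layer = c("endo", "epi"), phase = c("ED", "ES"),
                         resolution = 0.1) {
  stopifnot(inherits(phantom, "heart_phantom"))
  chamber <- match.arg(chamber)
  layer <- match.arg(layer)
  phase <- match.arg(phase)
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    abort("resolution must be a positive number (mm)")
  }
  cnt <- if (chamber == "LV") {
    sem <- lv_semiaxes(phantom, layer, phase)
    mp <- mitral_plane_anatomical(phantom)
    count_ellipsoid_halfspace(sem, c(0, 0, 0), resolution, mp$normal, mp$d)
  } else if (is.null(phantom$la_semiaxes)) {
    0
  } else if (!is.null(phantom$la_appendage) &&
             phantom$la_appendage$amplitude > 0) {
    count_la_appendage(phantom, resolution)
  } else {
    count_ellipsoid_halfspace(phantom$la_semiaxes,
                              c(0, 0, la_center_z(phantom)), resolution)
  }
  if (cnt < 100) {
    warn(sprintf(
      "voxel_volume: only %d voxels inside at resolution %g mm; result is unreliable",
      cnt, resolution))
  }
  cnt * resolution^3 / 1000
}
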