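# Rotational long-axis volumetry: each radial contour is split at the long
# axis into two radius profiles; the 2N angular half-planes are integrated as
# sector areas over a common axial level grid.

# project a contour's vertices into (s, t) coordinates where t runs along the
# long axis and s is the signed perpendicular offset; returns matrix cbind(s, t)
contour_axis_coords <- function(contour_row, long_axis) {
  plane <- contour_row$plane[[1L]]
  v <- contour_row$vertices[[1L]]
  d3 <- long_axis$direction / sqrt(sum(long_axis$direction^2))
  if (abs(sum(plane$normal * d3)) > 1e-8) {
    abort("contour plane does not contain the long-axis direction")
  }
  off <- long_axis$point - plane$origin
  if (abs(sum(plane$normal * off)) > 1e-6) {
    abort("long axis does not lie in the contour plane")
  }
  t_dir <- c(sum(plane$basis[, 1] * d3), sum(plane$basis[, 2] * d3))
  s_dir <- c(t_dir[2], -t_dir[1])
  uv0 <- c(sum(plane$basis[, 1] * off), sum(plane$basis[, 2] * off))
  rel_u <- v[, 1] - uv0[1]
  rel_v <- v[, 2] - uv0[2]
  cbind(s = rel_u * s_dir[1] + rel_v * s_dir[2],
        t = rel_u * t_dir[1] + rel_v * t_dir[2])
}

# distance from the axis to the outermost polygon-boundary crossing on each
# side of the axis, at each level; 0 where the polygon is absent
radius_at_levels <- function(st, levels) {
  n <- nrow(st)
  i2 <- c(2:n, 1L)
  s1 <- st[, 1]; t1 <- st[, 2]
  s2 <- st[i2, 1]; t2 <- st[i2, 2]
  right <- numeric(length(levels))
  left <- numeric(length(levels))
  multi <- 0L
  for (j in seq_along(levels)) {
    z <- levels[j]
    hit <- (t1 <= z & t2 > z) | (t2 <= z & t1 > z)
    if (!any(hit)) next
    tt <- (z - t1[hit]) / (t2[hit] - t1[hit])
    s_cross <- s1[hit] + tt * (s2[hit] - s1[hit])
    pos <- s_cross[s_cross > 0]
    neg <- s_cross[s_cross < 0]
    if (length(pos) > 1L || length(neg) > 1L) multi <- multi + 1L
    if (length(pos)) right[j] <- max(pos)
    if (length(neg)) left[j] <- -min(neg)
  }
  list(right = right, left = left, multi = multi)
}

#' Split a long-axis contour into two radius profiles
#'
#' Decomposes a radial contour (plane containing the long axis) into the
#' boundary radius as a function of axial position, on each side of the axis:
#' one profile at the plane azimuth and one at azimuth + 180 degrees. Where a
#' level line crosses the boundary more than once on a side (overhanging
#' shapes), the outermost crossing is used.
#'
#' @param contour A one-row subset of a `lax_set`.
#' @param long_axis The axis as `list(point, direction)`; defaults to the
#'   set's own axis when `contour` carries one.
#' @param levels Axial positions (mm) at which to sample the radius; default
#'   256 uniformly spaced levels spanning the contour.
#' @return A tibble with columns `angle` (deg, in `[0, 360)`), `level` (mm)
#'   and `radius` (mm, 0 where the half-contour is absent).
#' @export
split_contour <- function(contour, long_axis = NULL, levels = NULL) {
  if (!is.data.frame(contour) || nrow(contour) != 1L) {
    abort("split_contour expects a one-row contour")
  }
  long_axis <- long_axis %||% attr(contour, "long_axis")
  if (is.null(long_axis)) abort("no long axis supplied")
  st <- contour_axis_coords(contour, long_axis)
  if (is.null(levels)) {
    rng <- range(st[, 2])
    levels <- rng[1] + (seq_len(256L) - 0.5) * diff(rng) / 256L
  }
  r <- radius_at_levels(st, levels)
  ang <- contour$angle[[1L]]
  if (is.na(ang)) ang <- 0
  out <- dplyr::bind_rows(
    tibble(angle = ang %% 360, level = levels, radius = r$right),
    tibble(angle = (ang + 180) %% 360, level = levels, radius = r$left))
  if (r$multi > 0L) {
    inform(sprintf(
      "split_contour: %d level(s) crossed the boundary more than once per side; outermost crossing used",
      r$multi))
  }
  out
}

#' Rotational long-axis volume
#'
#' With 2N half-plane radius profiles sorted by azimuth, the cross-sectional
#' area at each axial level is the triangle-fan sum
#' `sum_k 1/2 * r_k * r_{k+1} * sin(dtheta_k)` (cyclic). With
#' `chord_correction = TRUE` (default) each sector is rescaled by
#' `dtheta / sin(dtheta)`, i.e. sector areas become
#' `1/2 * r_k * r_{k+1} * dtheta`, so axisymmetric cross-sections are
#' recovered exactly at any N. Levels are a uniform grid of `n_levels`
#' midpoint cells spanning the union of the contours' axial extents (the
#' basal truncation edge bounds the grid).
#'
#' @param lax A `lax_set`.
#' @param n_levels Number of axial integration levels (>= 8; default 256).
#' @param chord_correction Apply the chord-to-arc sector correction
#'   (default `TRUE`).
#' @param chamber,layer,phase Select the contours to integrate.
#' @return Volume in ml.
#' @examples
#' ph <- make_phantom("canine", seed = 1)
#' rotational_volume(slice_lax(ph, 6), chamber = "LV", layer = "endo")
#' @export
rotational_volume <- function(lax, n_levels = 256L, chord_correction = TRUE,
                              chamber = "LV", layer = "endo", phase = NULL) {
  if (!inherits(lax, "lax_set")) abort("lax must be a lax_set")
  if (!is.numeric(n_levels) || n_levels < 8) abort("n_levels must be >= 8")
  n_levels <- as.integer(n_levels)
  x <- cs_filter(lax, chamber = chamber, layer = layer, phase = phase)
  if (nrow(x) == 0L) abort("no contours match the requested chamber/layer/phase")
  if (length(unique(x$phase)) > 1L) {
    abort("rotational_volume requires contours of a single phase")
  }
  if (nrow(x) < 2L) abort("rotational volumetry needs at least 2 planes")
  long_axis <- attr(x, "long_axis")
  sts <- lapply(seq_len(nrow(x)), function(i) {
    contour_axis_coords(cs_subset(x, seq_len(nrow(x)) == i), long_axis)
  })
  rng <- range(unlist(lapply(sts, function(st) range(st[, 2]))))
  dz <- diff(rng) / n_levels
  levels <- rng[1] + (seq_len(n_levels) - 0.5) * dz
  azimuths <- numeric(0)
  radii <- NULL
  for (i in seq_along(sts)) {
    r <- radius_at_levels(sts[[i]], levels)
    azimuths <- c(azimuths, x$angle[i] %% 360, (x$angle[i] + 180) %% 360)
    radii <- cbind(radii, r$right, r$left)
  }
  ord <- order(azimuths)
  azimuths <- azimuths[ord]
  radii <- radii[, ord, drop = FALSE]
  K <- length(azimuths)
  dth <- diff(c(azimuths, azimuths[1] + 360)) * pi / 180
  nxt <- c(2:K, 1L)
  w <- if (chord_correction) dth / 2 else sin(dth) / 2
  areas <- rowSums(radii * radii[, nxt, drop = FALSE] *
                     matrix(w, nrow = n_levels, ncol = K, byrow = TRUE))
  sum(areas) * dz / 1000
}

#' LV mass from rotational long-axis sets
#'
#' `(rotational_volume(epi) - rotational_volume(endo)) * density`.
#'
#' @param endo_lax,epi_lax `lax_set`s of LV endocardial and epicardial
#'   contours sharing plane angles and phase.
#' @param density Myocardial density g/ml (default 1.05).
#' @param n_levels Axial integration levels (default 256).
#' @param chord_correction Apply the sector chord correction (default `TRUE`).
#' @return Mass in g.
#' @export
mass_lax <- function(endo_lax, epi_lax, density = 1.05, n_levels = 256L,
                     chord_correction = TRUE) {
  if (!inherits(endo_lax, "lax_set") || !inherits(epi_lax, "lax_set")) {
    abort("mass_lax expects two lax_sets")
  }
  en <- cs_filter(endo_lax, chamber = "LV", layer = "endo")
  ep <- cs_filter(epi_lax, chamber = "LV", layer = "epi")
  if (nrow(en) == 0L || nrow(ep) == 0L) {
    abort("mass_lax: sets must contain LV endo and LV epi contours")
  }
  if (!identical(unique(en$phase), unique(ep$phase))) {
    abort("mass_lax: endo and epi sets must share the cardiac phase")
  }
  if (!isTRUE(all.equal(sort(unique(en$angle)), sort(unique(ep$angle))))) {
    abort("mass_lax: endo and epi sets must share plane angles")
  }
  wall <- rotational_volume(ep, n_levels, chord_correction, "LV", "epi") -
    rotational_volume(en, n_levels, chord_correction, "LV", "endo")
  if (wall < 0) abort("mass_lax: epicardial volume smaller than endocardial volume")
  wall * density
}
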