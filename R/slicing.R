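# Slice a phantom into SAX stacks and rotational LAX sets. Contours are exact
# conic-section (or radius-function) intersections of the analytic surfaces
# with each slice's central plane, discretised at a configurable vertex count.

#' Slice a phantom into a short-axis stack
#'
#' Slice planes are perpendicular to the anatomical long axis at spacing
#' `thickness + gap`. The stack is anchored so the basal-most ventricular
#' plane centre lies half a spacing below the mitral plane's long-axis
#' crossing (plus `anchor_offset`), mimicking a technologist planning full
#' coverage; the lattice extends over the atrium so the LA is fully covered.
#' An LV contour is emitted for a slice iff its central plane lies apical to
#' the mitral plane at the long-axis crossing; any residual atrial sub-area of
#' an oblique basal slice is removed later by [clip_basal()]/[stack_volume()].
#'
#' The blood cross-section of the first atrial-side plane (slice index 0) is
#' kept aside in the `basal_extra` attribute; [perturb()] with
#' `basal_shift = +1` appends it to emulate erroneous inclusion of an extra
#' basal slice.
#'
#' @param phantom A [heart_phantom()].
#' @param thickness Slice thickness mm (> 0).
#' @param gap Inter-slice gap mm (>= 0).
#' @param phase `"ED"` or `"ES"`.
#' @param chambers Chambers to contour, subset of `c("LV", "LA")`.
#' @param layers Wall layers for the LV, subset of `c("endo", "epi")`.
#' @param n_vertices Vertices per contour polygon (default 360).
#' @param anchor_offset Extra apical shift of the whole lattice, mm in
#'   `[0, thickness + gap)`; exposes placement sensitivity.
#' @return A `sax_stack` tibble of contours.
#' @examples
#' ph <- make_phantom("canine", seed = 1)
#' slice_sax(ph, thickness = 8, gap = 2)
#' @export
slice_sax <- function(phantom, thickness, gap = 0, phase = c("ED", "ES"),
                      chambers = c("LV", "LA"), layers = c("endo", "epi"),
                      n_vertices = 360L, anchor_offset = 0) {
  stopifnot(inherits(phantom, "heart_phantom"))
  phase <- match.arg(phase)
  if (!is.numeric(thickness) || length(thickness) != 1L || thickness <= 0) {
    abort("thickness must be > 0")
  }
  if (!is.numeric(gap) || length(gap) != 1L || gap < 0) {
    abort("gap must be >= 0")
  }
  chambers <- match.arg(chambers, c("LV", "LA"), several.ok = TRUE)
  layers <- match.arg(layers, c("endo", "epi"), several.ok = TRUE)
  spacing <- thickness + gap
  if (anchor_offset < 0 || anchor_offset >= spacing) {
    abort("anchor_offset must lie in [0, thickness + gap)")
  }
  z_b <- phantom$lv_truncation_fraction * phantom$lv_endo_semiaxes[3]
  zk <- function(k) z_b - anchor_offset - (k - 0.5) * spacing

  has_la <- !is.null(phantom$la_semiaxes)
  c_epi <- phantom$lv_epi_semiaxes[3]
  k_max <- ceiling((z_b + c_epi) / spacing + 1)
  k_min <- if (has_la) -ceiling((2 * phantom$la_semiaxes[3]) / spacing + 1) else 1L

  rows <- list()
  add <- function(chamber, layer, k, verts) {
    rows[[length(rows) + 1L]] <<- list(
      chamber = chamber, layer = layer, phase = phase, slice = as.integer(k),
      angle = NA_real_, vertices = list(verts), plane = list(sax_plane(zk(k))))
  }

  lv_section <- function(sem, z) {
    w2 <- 1 - (z / sem[3])^2
    if (w2 <= 0) return(NULL)
    ellipse_poly(sem[1] * sqrt(w2), sem[2] * sqrt(w2), n_vertices)
  }
  la_section <- function(z) {
    s <- phantom$la_semiaxes
    zc <- la_center_z(phantom)
    if (abs(z - zc) >= s[3]) return(NULL)
    if (!is.null(phantom$la_appendage) && phantom$la_appendage$amplitude > 0) {
      th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
      r <- la_radius(phantom, th, z)
      cbind(r * cos(th), r * sin(th))
    } else {
      w <- sqrt(1 - ((z - zc) / s[3])^2)
      ellipse_poly(s[1] * w, s[2] * w, n_vertices)
    }
  }

  for (k in k_min:k_max) {
    z <- zk(k)
    if ("LV" %in% chambers && k >= 1L) {
      for (layer in layers) {
        v <- lv_section(lv_semiaxes(phantom, layer, phase), z)
        if (!is.null(v)) add("LV", layer, k, v)
      }
    }
    if ("LA" %in% chambers && has_la) {
      v <- la_section(z)
      if (!is.null(v)) add("LA", "endo", k, v)
    }
  }
  if (!length(rows)) abort("no slice plane intersects the requested chambers")

  basal_extra <- NULL
  if (has_la && "LV" %in% chambers && "endo" %in% layers) {
    v0 <- la_section(zk(0L))
    if (!is.null(v0)) {
      basal_extra <- tibble(
        chamber = "LV", layer = "endo", phase = phase, slice = 0L,
        angle = NA_real_, vertices = list(v0), plane = list(sax_plane(zk(0L))))
    }
  }

  out <- purrr::map_dfr(rows, as_tibble)
  mp <- mitral_plane_anatomical(phantom)
  pose <- phantom$pose
  out$plane <- lapply(out$plane, pose_plane, pose = pose)
  if (!is.null(basal_extra)) {
    basal_extra$plane <- lapply(basal_extra$plane, pose_plane, pose = pose)
  }
  mp_n <- pose_dir(pose, mp$normal)
  mp_p <- pose_point(pose, mp$point)
  new_contour_set(out, "sax_stack", list(
    thickness = thickness, gap = gap,
    mitral_plane = list(normal = mp_n, d = sum(mp_n * mp_p), point = mp_p),
    long_axis = list(point = pose_point(pose, c(0, 0, 0)),
                     direction = pose_dir(pose, c(0, 0, 1))),
    n_vertices = as.integer(n_vertices),
    basal_extra = basal_extra))
}

#' Slice a phantom into a rotational long-axis set
#'
#' `n_planes` planes containing the long axis at azimuths
#' `angle_offset + k * 180 / n_planes` degrees. Each LV contour is the full
#' ellipse section clipped at the mitral plane (the basal truncation edge is
#' part of the polygon); LA contours are assembled from the boundary radius on
#' both sides of the axis.
#'
#' @inheritParams slice_sax
#' @param n_planes Number of radial planes (>= 2; default 6, i.e. 30-degree
#'   increments).
#' @param angle_offset Azimuth of the first plane, degrees.
#' @return A `lax_set` tibble of contours.
#' @examples
#' ph <- make_phantom("canine", seed = 1)
#' slice_lax(ph, n_planes = 6)
#' @export
slice_lax <- function(phantom, n_planes = 6L, phase = c("ED", "ES"),
                      chambers = c("LV", "LA"), layers = c("endo", "epi"),
                      n_vertices = 360L, angle_offset = 0) {
  stopifnot(inherits(phantom, "heart_phantom"))
  phase <- match.arg(phase)
  if (!is.numeric(n_planes) || length(n_planes) != 1L || n_planes < 2) {
    abort("n_planes must be >= 2")
  }
  n_planes <- as.integer(n_planes)
  chambers <- match.arg(chambers, c("LV", "LA"), several.ok = TRUE)
  layers <- match.arg(layers, c("endo", "epi"), several.ok = TRUE)
  angles <- angle_offset + (0:(n_planes - 1L)) * 180 / n_planes
  mp <- mitral_plane_anatomical(phantom)
  has_la <- !is.null(phantom$la_semiaxes)

  rows <- list()
  add <- function(chamber, layer, ang, verts) {
    rows[[length(rows) + 1L]] <<- list(
      chamber = chamber, layer = layer, phase = phase, slice = NA_integer_,
      angle = ang, vertices = list(verts), plane = list(lax_plane(ang)))
  }

  for (ang in angles) {
    th <- ang * pi / 180
    e1 <- c(cos(th), sin(th), 0)
    e2 <- c(0, 0, 1)
    alpha <- sum(mp$normal * e1)
    beta <- sum(mp$normal * e2)
    if ("LV" %in% chambers) {
      for (layer in layers) {
        sem <- lv_semiaxes(phantom, layer, phase)
        full <- ellipse_poly(ellipse_radius(sem[1], sem[2], th), sem[3],
                             n_vertices)
        v <- clip_poly_halfplane(full, alpha, beta, mp$d)
        if (nrow(v) >= 3L) add("LV", layer, ang, v)
      }
    }
    if ("LA" %in% chambers && has_la) {
      s <- phantom$la_semiaxes
      zc <- la_center_z(phantom)
      m <- max(8L, floor(n_vertices / 2))
      zs <- zc - s[3] + 2 * s[3] * (seq_len(m) - 0.5) / m
      r_right <- vapply(zs, function(z) la_radius(phantom, th, z), numeric(1))
      r_left <- vapply(zs, function(z) la_radius(phantom, th + pi, z),
                       numeric(1))
      v <- rbind(cbind(r_right, zs), cbind(-rev(r_left), rev(zs)))
      colnames(v) <- NULL
      add("LA", "endo", ang, v)
    }
  }
  if (!length(rows)) abort("no LAX plane intersects the requested chambers")
  out <- purrr::map_dfr(rows, as_tibble)
  pose <- phantom$pose
  out$plane <- lapply(out$plane, pose_plane, pose = pose)
  mp_n <- pose_dir(pose, mp$normal)
  mp_p <- pose_point(pose, mp$point)
  new_contour_set(out, "lax_set", list(
    thickness = NA_real_, gap = NA_real_,
    mitral_plane = list(normal = mp_n, d = sum(mp_n * mp_p), point = mp_p),
    long_axis = list(point = pose_point(pose, c(0, 0, 0)),
                     direction = pose_dir(pose, c(0, 0, 1))),
    plane_angles = angles,
    n_vertices = as.integer(n_vertices),
    basal_extra = NULL))
}
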