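# Short-axis volumetry: slice summation with effective-spacing gap handling,
# cross-referenced basal clipping at the mitral plane, LV mass and global
# function parameters.

# in-plane half-plane coefficients of "mitral-ventricular side" for a contour's
# plane: alpha*u + beta*v <= dd keeps the ventricular side
mitral_line_coeffs <- function(plane, mitral_plane) {
  n <- mitral_plane$normal
  alpha <- sum(n * plane$basis[, 1])
  beta <- sum(n * plane$basis[, 2])
  dd <- mitral_plane$d - sum(n * plane$origin)
  list(alpha = alpha, beta = beta, d = dd)
}

clip_vertices_mitral <- function(v, plane, mitral_plane, keep = c("ventricular", "atrial")) {
  keep <- match.arg(keep)
  co <- mitral_line_coeffs(plane, mitral_plane)
  s <- if (keep == "ventricular") 1 else -1
  a <- s * co$alpha; b <- s * co$beta; d <- s * co$d
  if (abs(a) < 1e-10 && abs(b) < 1e-10) {
    # mitral plane parallel to the slice plane: all-or-nothing
    if (d >= 0) return(v)
    return(v[0, , drop = FALSE])
  }
  clip_poly_halfplane(v, a, b, d)
}

#' Clip a basal short-axis contour at the mitral plane
#'
#' Returns the sub-polygon of the contour on the ventricular side of the
#' mitral plane (the in-plane half-plane bounded by the line where the mitral
#' plane intersects the slice plane). The contour is returned unchanged when
#' the mitral plane does not cross the slice, and an empty (zero-row) result
#' when the whole contour is atrial or the clip degenerates to fewer than 3
#' vertices.
#'
#' @param contour A one-row subset of a `sax_stack`.
#' @param mitral_plane The mitral plane as `list(normal, d)` (world frame;
#'   ventricular side is `normal . p <= d`). Defaults to the stack's own
#'   mitral plane if `contour` carries one.
#' @param ... Unused.
#' @return A contour tibble with 0 or 1 rows.
#' @export
clip_basal <- function(contour, mitral_plane = NULL, ...) {
  if (!is.data.frame(contour) || nrow(contour) != 1L) {
    abort("clip_basal expects a one-row contour")
  }
  mitral_plane <- mitral_plane %||% attr(contour, "mitral_plane")
  if (is.null(mitral_plane)) abort("no mitral plane supplied")
  v <- clip_vertices_mitral(contour$vertices[[1L]], contour$plane[[1L]],
                            mitral_plane, "ventricular")
  if (nrow(v) < 3L) {
    inform("clip_basal: contour entirely atrial (empty result)")
    return(cs_subset(contour, FALSE))
  }
  out <- contour
  out$vertices[[1L]] <- v
  out
}

#' Slice-summation (Simpson) volume of a short-axis stack
#'
#' Sums contour areas times the effective spacing `thickness + gap` (the gap's
#' volume is attributed to its slice). With `clip = TRUE`, contours crossed by
#' the mitral plane are clipped to their ventricular (for LV) or atrial (for
#' LA) side, formalising the cross-referenced basal-slice procedure; slices
#' whose blood pool is entirely on the wrong side contribute nothing.
#'
#' @param stack A `sax_stack`.
#' @param clip Apply mitral-plane cross-referencing (default `TRUE`).
#' @param chamber,layer,phase Select the contours to sum; after selection the
#'   stack must contain a single chamber/layer/phase combination.
#' @return Volume in ml.
#' @examples
#' ph <- make_phantom("canine", seed = 1)
#' stack_volume(slice_sax(ph, 5), chamber = "LV", layer = "endo")
#' @export
stack_volume <- function(stack, clip = TRUE, chamber = "LV", layer = "endo",
                         phase = NULL) {
  if (!inherits(stack, "sax_stack")) abort("stack must be a sax_stack")
  x <- cs_filter(stack, chamber = chamber, layer = layer, phase = phase)
  if (nrow(x) == 0L) abort("no contours match the requested chamber/layer/phase")
  if (length(unique(x$chamber)) > 1L || length(unique(x$layer)) > 1L ||
      length(unique(x$phase)) > 1L) {
    abort("stack_volume requires contours of a single chamber/layer/phase")
  }
  spacing <- cs_spacing(x)
  mp <- attr(x, "mitral_plane")
  side <- if (x$chamber[1] == "LA") "atrial" else "ventricular"
  areas <- vapply(seq_len(nrow(x)), function(i) {
    v <- x$vertices[[i]]
    if (clip && !is.null(mp)) {
      v <- clip_vertices_mitral(v, x$plane[[i]], mp, side)
      if (nrow(v) < 3L) return(0)
    }
    shoelace_area(v)
  }, numeric(1))
  sum(areas) * spacing / 1000
}

#' LV mass from endocardial and epicardial short-axis stacks
#'
#' `(stack_volume(epi) - stack_volume(endo)) * density`. Both stacks must
#' share phase and slice spacing (conventionally end-systole).
#'
#' @param endo_stack,epi_stack `sax_stack`s of LV endocardial and epicardial
#'   contours.
#' @param density Myocardial density g/ml (default 1.05).
#' @param clip Apply mitral-plane cross-referencing (default `TRUE`).
#' @return Mass in g.
#' @export
mass_sax <- function(endo_stack, epi_stack, density = 1.05, clip = TRUE) {
  if (!inherits(endo_stack, "sax_stack") || !inherits(epi_stack, "sax_stack")) {
    abort("mass_sax expects two sax_stacks")
  }
  en <- cs_filter(endo_stack, chamber = "LV", layer = "endo")
  ep <- cs_filter(epi_stack, chamber = "LV", layer = "epi")
  if (nrow(en) == 0L || nrow(ep) == 0L) {
    abort("mass_sax: stacks must contain LV endo and LV epi contours")
  }
  if (!identical(unique(en$phase), unique(ep$phase))) {
    abort("mass_sax: endo and epi stacks must share the cardiac phase")
  }
  if (abs(cs_spacing(en) - cs_spacing(ep)) > 1e-9) {
    abort("mass_sax: endo and epi stacks must share the slice spacing")
  }
  wall <- stack_volume(ep, clip = clip, chamber = "LV", layer = "epi") -
    stack_volume(en, clip = clip, chamber = "LV", layer = "endo")
  if (wall < 0) abort("mass_sax: epicardial volume smaller than endocardial volume")
  wall * density
}

#' Global function parameters from EDV and ESV
#'
#' @param edv,esv End-diastolic / end-systolic volume, ml.
#' @param mass LV mass in g (optional).
#' @param chamber,method Labels carried into the result.
#' @return A one-row tibble with `edv`, `esv`, `sv`, `ef` (percent), `mass`,
#'   `chamber`, `method`. `esv > edv` triggers a warning and a negative EF.
#' @examples
#' function_params(120, 48)
#' @export
function_params <- function(edv, esv, mass = NA_real_, chamber = "LV",
                            method = NA_character_) {
  if (!is.numeric(edv) || !is.numeric(esv) || length(edv) != 1L ||
      length(esv) != 1L || edv < 0 || esv < 0) {
    abort("edv and esv must be single non-negative numbers")
  }
  if (edv == 0) abort("ejection fraction undefined for edv = 0")
  if (esv > edv) warn("esv exceeds edv; reporting a negative ejection fraction")
  sv <- edv - esv
  tibble(edv = edv, esv = esv, sv = sv, ef = 100 * sv / edv,
         mass = as.numeric(mass), chamber = chamber, method = method)
}
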