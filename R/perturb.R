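# Observer-variability emulation: each contour vertex is displaced radially
# (about the contour centroid) by a smooth, zero-mean, angularly correlated
# random field; SAX stacks can additionally gain or lose their basal slice
# (basal_shift), the dominant short-axis error source.

#' Describe an observer noise model
#'
#' @param radial_sd SD of the radial vertex displacement, mm (>= 0).
#' @param smoothness_scale Angular correlation length of the displacement
#'   field along the contour, degrees (Gaussian kernel SD).
#' @param basal_shift Integer: `+1` include an extra (atrial-side) basal
#'   slice, `-1` drop the true basal slice, `0` none. SAX stacks only.
#' @param seed Integer seed; perturbation is deterministic per seed.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(radial_sd = 0.5, smoothness_scale = 30, seed = 7)
#' @export
noise_model <- function(radial_sd = 0, smoothness_scale = 30, basal_shift = 0L,
                        seed = 1L) {
  if (!is.numeric(radial_sd) || length(radial_sd) != 1L || radial_sd < 0) {
    abort("radial_sd must be >= 0")
  }
  if (!is.numeric(smoothness_scale) || length(smoothness_scale) != 1L ||
      smoothness_scale < 0) {
    abort("smoothness_scale must be >= 0")
  }
  if (!basal_shift %in% c(-1L, 0L, 1L)) {
    abort("basal_shift must be -1, 0 or +1")
  }
  structure(list(radial_sd = radial_sd,
                 smoothness_scale = smoothness_scale,
                 basal_shift = as.integer(basal_shift),
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Smooth zero-mean periodic field of length n with unit SD, scaled to
# sd_target. Gaussian circular smoothing of white noise via FFT.
radial_field <- function(n, sd_target, smooth_deg, seed) {
  withr::with_seed(seed, {
    w <- rnorm(n)
    sd_idx <- smooth_deg * n / 360
    f <- if (sd_idx > 1e-9) {
      idx <- seq_len(n) - 1L
      circ <- pmin(idx, n - idx)
      kern <- dnorm(circ, sd = sd_idx)
      kern <- kern / sum(kern)
      Re(fft(fft(w) * fft(kern), inverse = TRUE)) / n
    } else {
      w
    }
    f <- f - mean(f)
    s <- sd(f)
    if (s < 1e-12) rep(0, n) else f / s * sd_target
  })
}

# deterministic per-contour sub-seed (kept exactly representable in doubles)
sub_seed <- function(seed, i, attempt = 0L) {
  as.integer((seed * 1009 + i * 9176 + attempt * 31 + 1) %% 2147483647)
}

perturb_vertices <- function(v, noise, sseed) {
  ctr <- polygon_centroid(v)
  du <- v[, 1] - ctr[1]
  dv <- v[, 2] - ctr[2]
  r <- sqrt(du^2 + dv^2)
  for (attempt in 0:9) {
    delta <- radial_field(nrow(v), noise$radial_sd, noise$smoothness_scale,
                          sseed + attempt * 31L)
    r2 <- r + delta
    # radial displacement preserves the angular order of vertices about the
    # centroid, so the polygon stays simple (star-shaped) iff all radii > 0
    if (all(r2 > 1e-9)) {
      scale <- r2 / pmax(r, 1e-12)
      return(cbind(ctr[1] + du * scale, ctr[2] + dv * scale))
    }
  }
  abort("perturbation produced a degenerate (non-simple) polygon after 10 attempts")
}

#' Perturb a contour set with an observer noise model
#'
#' Radial displacement is deterministic for a fixed `noise$seed`; zero noise
#' with zero basal shift is the identity. `basal_shift` applies to SAX stacks
#' only and acts on the LV endocardial (blood-pool) contours: `-1` drops the
#' basal-most slice, `+1` appends the blood cross-section of the next
#' atrial-side plane (stored by [slice_sax()]), emulating erroneous inclusion
#' of atrial volume.
#'
#' @param x A `sax_stack` or `lax_set`.
#' @param noise A [noise_model()].
#' @param ... Unused.
#' @return An object of the same type as `x`.
#' @export
perturb <- function(x, noise, ...) UseMethod("perturb")

#' @export
perturb.sax_stack <- function(x, noise, ...) {
  stopifnot(inherits(noise, "noise_model"))
  out <- x
  if (noise$basal_shift == -1L) {
    lv <- which(out$chamber == "LV" & out$layer == "endo")
    if (!length(lv)) abort("basal_shift: stack has no LV endocardial contours")
    basal <- min(out$slice[lv])
    out <- cs_subset(out, !(out$chamber == "LV" & out$layer == "endo" &
                              out$slice == basal))
  } else if (noise$basal_shift == 1L) {
    extra <- attr(x, "basal_extra")
    if (is.null(extra)) {
      abort("basal_shift = +1: no atrial-side contour available in this stack")
    }
    saved <- attributes(out)[cv_attrs]
    cls <- class(out)
    y <- dplyr::bind_rows(as_tibble(extra), as_tibble(out))
    class(y) <- cls
    for (a in cv_attrs) attr(y, a) <- saved[[a]]
    out <- y
  }
  apply_radial(out, noise)
}

#' @export
perturb.lax_set <- function(x, noise, ...) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$basal_shift != 0L) {
    abort("basal_shift applies only to SAX stacks")
  }
  apply_radial(x, noise)
}

apply_radial <- function(x, noise) {
  if (noise$radial_sd == 0) return(x)
  verts <- x$vertices
  for (i in seq_along(verts)) {
    verts[[i]] <- perturb_vertices(verts[[i]], noise, sub_seed(noise$seed, i))
  }
  x$vertices <- verts
  x
}
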