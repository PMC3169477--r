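# Contour collections are tibbles (one row per closed planar polygon) with the
# columns chamber, layer, phase, slice (SAX index; basal = 1, atrial side
# <= 0), angle (LAX plane azimuth, deg), vertices (list of n x 2 matrices in
# the plane basis, mm) and plane (list of cv_plane). Collection-level geometry
# (slice spacing, mitral plane, long axis, ...) lives in attributes; class
# `sax_stack` or `lax_set` on top of `contour_set`.

cv_attrs <- c("thickness", "gap", "mitral_plane", "long_axis", "plane_angles",
              "n_vertices", "basal_extra")

new_contour_set <- function(rows, subclass, attrs = list()) {
  x <- as_tibble(rows)
  class(x) <- c(subclass, "contour_set", class(tibble()))
  for (a in names(attrs)) attr(x, a) <- attrs[[a]]
  x
}

#' @export
print.contour_set <- function(x, ...) {
  kind <- if (inherits(x, "sax_stack")) "sax_stack" else
    if (inherits(x, "lax_set")) "lax_set" else "contour_set"
  cat(sprintf("<%s: %d contours>\n", kind, nrow(x)))
  if (kind == "sax_stack") {
    cat(sprintf("  thickness %g mm, gap %g mm (spacing %g mm)\n",
                attr(x, "thickness"), attr(x, "gap"), cs_spacing(x)))
  }
  if (kind == "lax_set") {
    cat(sprintf("  plane angles: %s deg\n",
                paste(attr(x, "plane_angles"), collapse = ", ")))
  }
  NextMethod()
}

cs_spacing <- function(x) attr(x, "thickness") + attr(x, "gap")

# row subset preserving class and geometry attributes
cs_subset <- function(x, keep) {
  saved <- attributes(x)[cv_attrs]
  cls <- class(x)
  y <- as_tibble(x)[keep, ]
  class(y) <- cls
  for (a in cv_attrs) attr(y, a) <- saved[[a]]
  y
}

cs_filter <- function(x, chamber = NULL, layer = NULL, phase = NULL) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(chamber)) keep <- keep & x$chamber %in% chamber
  if (!is.null(layer)) keep <- keep & x$layer %in% layer
  if (!is.null(phase)) keep <- keep & x$phase %in% phase
  cs_subset(x, keep)
}

check_contour_row <- function(vertices, what = "contour") {
  if (!is.matrix(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L) {
    abort(sprintf("%s must have >= 3 two-column vertices", what))
  }
  if (any(!is.finite(vertices))) {
    abort(sprintf("%s has non-finite vertices", what))
  }
  invisible(TRUE)
}

#' Area enclosed by a contour
#'
#' Absolute shoelace area of the vertex polygon, independent of orientation.
#'
#' @param contour Either an `n x 2` vertex matrix or a one-row subset of a
#'   contour set (tibble with a `vertices` list-column).
#' @return Area in mm^2.
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' @export
polygon_area <- function(contour) {
  v <- contour_vertices(contour)
  check_contour_row(v)
  shoelace_area(v)
}

contour_vertices <- function(contour) {
  if (is.matrix(contour)) return(contour)
  if (is.data.frame(contour)) {
    if (nrow(contour) != 1L || is.null(contour$vertices)) {
      abort("expected a one-row contour (tibble with a 'vertices' list-column) or a vertex matrix")
    }
    return(contour$vertices[[1L]])
  }
  abort("expected a vertex matrix or a one-row contour tibble")
}

#' Plot a contour set
#'
#' Draws each contour in its in-plane (u, v) coordinates, faceted by slice
#' index (SAX) or plane angle (LAX) and coloured by chamber/layer.
#'
#' @param object A `contour_set` (e.g. from [slice_sax()] or [slice_lax()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contour_set <- function(object, ...) {
  if (nrow(object) == 0) abort("empty contour set")
  df <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    v <- object$vertices[[i]]
    tibble(u = c(v[, 1], v[1, 1]), v = c(v[, 2], v[1, 2]),
           panel = if (inherits(object, "lax_set")) {
             sprintf("%g deg", object$angle[i])
           } else {
             sprintf("slice %d", object$slice[i])
           },
           what = paste(object$chamber[i], object$layer[i]),
           id = i)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v, group = .data$id,
                                   colour = .data$what)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "u (mm)", y = "v (mm)", colour = NULL)
}
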