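# Low-level planar/3D geometry primitives shared by the slicing and
# quantification code. Lengths are mm throughout; volumes returned by callers
# are ml (1 ml = 1000 mm^3).

#' Construct an imaging plane
#'
#' A plane is stored as an origin, a unit normal and two in-plane orthonormal
#' basis vectors; contour vertices are expressed as (u, v) coordinates in that
#' basis. World coordinates of a vertex are `origin + u * basis[, 1] + v *
#' basis[, 2]`.
#'
#' @param origin Numeric length-3, a point on the plane (mm).
#' @param normal Numeric length-3 normal vector (normalised internally).
#' @param basis 3 x 2 matrix of in-plane basis vectors (orthonormalised check).
#' @return An object of class `cv_plane`.
#' @export
new_plane <- function(origin, normal, basis) {
  origin <- as.numeric(origin)
  normal <- as.numeric(normal)
  basis <- matrix(as.numeric(basis), nrow = 3L)
  if (length(origin) != 3L || length(normal) != 3L || ncol(basis) != 2L) {
    abort("plane requires a length-3 origin, length-3 normal and 3x2 basis")
  }
  nl <- sqrt(sum(normal^2))
  if (nl < 1e-12) abort("plane normal must be non-zero")
  normal <- normal / nl
  for (j in 1:2) {
    bl <- sqrt(sum(basis[, j]^2))
    if (bl < 1e-12) abort("plane basis vectors must be non-zero")
    basis[, j] <- basis[, j] / bl
  }
  if (abs(sum(basis[, 1] * basis[, 2])) > 1e-8 ||
      abs(sum(basis[, 1] * normal)) > 1e-8 ||
      abs(sum(basis[, 2] * normal)) > 1e-8) {
    abort("plane basis vectors must be orthogonal to each other and to the normal")
  }
  structure(list(origin = origin, normal = normal, basis = basis),
            class = "cv_plane")
}

# Short-axis plane at axial position z (anatomical frame: long axis = +z).
sax_plane <- function(z) {
  new_plane(c(0, 0, z), c(0, 0, 1), cbind(c(1, 0, 0), c(0, 1, 0)))
}

# Long-axis plane through the z axis at azimuth theta (degrees from +x).
# In-plane coordinates: u along (cos t, sin t, 0), v along +z.
lax_plane <- function(theta_deg) {
  t <- theta_deg * pi / 180
  e1 <- c(cos(t), sin(t), 0)
  e2 <- c(0, 0, 1)
  new_plane(c(0, 0, 0), c(-sin(t), cos(t), 0), cbind(e1, e2))
}

plane_point <- function(plane, uv) {
  plane$origin + uv[1] * plane$basis[, 1] + uv[2] * plane$basis[, 2]
}

# Rotation about x axis by tau degrees.
rot_x <- function(tau_deg) {
  t <- tau_deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(t), sin(t),
           0, -sin(t), cos(t)), nrow = 3L)
}

identity_pose <- function() {
  list(rotation = diag(3), translation = c(0, 0, 0))
}

validate_pose <- function(pose) {
  if (is.null(pose)) return(identity_pose())
  if (!is.list(pose) || is.null(pose$rotation) || is.null(pose$translation)) {
    abort("pose must be a list with elements 'rotation' (3x3) and 'translation' (length 3)")
  }
  R <- matrix(as.numeric(pose$rotation), 3L, 3L)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0) {
    abort("pose$rotation must be a proper rotation matrix")
  }
  list(rotation = R, translation = as.numeric(pose$translation))
}

pose_point <- function(pose, p) as.numeric(pose$rotation %*% p + pose$translation)
pose_dir <- function(pose, v) as.numeric(pose$rotation %*% v)

pose_plane <- function(pose, plane) {
  new_plane(pose_point(pose, plane$origin),
            pose_dir(pose, plane$normal),
            cbind(pose_dir(pose, plane$basis[, 1]),
                  pose_dir(pose, plane$basis[, 2])))
}

# Absolute shoelace area of an (n x 2) vertex matrix (closed implicitly).
shoelace_area <- function(v) {
  n <- nrow(v)
  if (is.null(n) || n < 3L) abort("polygon needs at least 3 vertices")
  i2 <- c(2:n, 1L)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}

polygon_centroid <- function(v) {
  # area-weighted centroid; falls back to vertex mean for degenerate polygons
  n <- nrow(v)
  i2 <- c(2:n, 1L)
  cr <- v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(v))
  cx <- sum((v[, 1] + v[i2, 1]) * cr) / (6 * a)
  cy <- sum((v[, 2] + v[i2, 2]) * cr) / (6 * a)
  c(cx, cy)
}

# Sutherland-Hodgman clip of polygon `v` against half-plane a*u + b*v <= d.
# Returns a matrix with 0 rows when the polygon lies entirely outside.
clip_poly_halfplane <- function(v, a, b, d) {
  s <- a * v[, 1] + b * v[, 2] - d
  if (all(s <= 1e-12)) return(v)
  if (all(s >= -1e-12)) return(v[0, , drop = FALSE])
  n <- nrow(v)
  out <- matrix(NA_real_, nrow = 2L * n, ncol = 2L)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    si <- s[i]; sj <- s[j]
    if (si <= 0) {
      k <- k + 1L
      out[k, ] <- v[i, ]
    }
    if ((si < 0 && sj > 0) || (si > 0 && sj < 0)) {
      t <- si / (si - sj)
      k <- k + 1L
      out[k, ] <- v[i, ] + t * (v[j, ] - v[i, ])
    }
  }
  out <- out[seq_len(k), , drop = FALSE]
  if (nrow(out) < 3L) return(out[0, , drop = FALSE])
  out
}

# Parametric ellipse polygon (semi-axes ra, rb), n vertices, counter-clockwise.
ellipse_poly <- function(ra, rb, n = 360L) {
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(ra * cos(phi), rb * sin(phi))
}

# Radius of the origin-centred ellipse with semi-axes (a, b) along direction
# theta (radians).
ellipse_radius <- function(a, b, theta) {
  1 / sqrt(cos(theta)^2 / a^2 + sin(theta)^2 / b^2)
}

# Smallest absolute angular difference in degrees, result in [-180, 180].
wrap_angle_deg <- function(x) {
  ((x + 180) %% 360) - 180
}
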