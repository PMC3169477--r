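# Schema-validated JSON readers/writers for contour sets and deterministic
# CSV/JSON emission of study results. Serialized numbers carry no unit
# suffixes; units are fixed repo-wide (mm, ml, g, percent) and documented in
# the schema header.

CONTOUR_SCHEMA_VERSION <- "1.0"

plane_to_list <- function(p) {
  list(origin = p$origin, normal = p$normal,
       basis = list(p$basis[, 1], p$basis[, 2]))
}

plane_from_list <- function(l, where) {
  for (f in c("origin", "normal", "basis")) {
    if (is.null(l[[f]])) {
      abort(sprintf("contour schema violation at %s: missing plane %s", where, f))
    }
  }
  new_plane(unlist(l$origin), unlist(l$normal),
            cbind(unlist(l$basis[[1]]), unlist(l$basis[[2]])))
}

#' Write a contour set to JSON
#'
#' One record per contour (plane origin/normal/basis, vertex array, chamber,
#' layer, phase, slice index or plane angle) plus the collection-level
#' geometry, under a versioned schema.
#'
#' @param x A `sax_stack` or `lax_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(x, path) {
  if (!inherits(x, "contour_set")) abort("x must be a contour_set")
  type <- if (inherits(x, "sax_stack")) "sax_stack" else "lax_set"
  extra <- attr(x, "basal_extra")
  doc <- list(
    schema_version = CONTOUR_SCHEMA_VERSION,
    units = list(length = "mm", volume = "ml", mass = "g"),
    type = type,
    thickness = attr(x, "thickness"),
    gap = attr(x, "gap"),
    plane_angles = attr(x, "plane_angles"),
    n_vertices = attr(x, "n_vertices"),
    mitral_plane = attr(x, "mitral_plane"),
    long_axis = attr(x, "long_axis"),
    contours = contour_records(x),
    basal_extra = if (!is.null(extra)) contour_records(extra) else NULL)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

contour_records <- function(x) {
  lapply(seq_len(nrow(x)), function(i) {
    list(chamber = x$chamber[i], layer = x$layer[i], phase = x$phase[i],
         slice = if (is.na(x$slice[i])) NULL else x$slice[i],
         angle = if (is.na(x$angle[i])) NULL else x$angle[i],
         plane = plane_to_list(x$plane[[i]]),
         vertices = x$vertices[[i]])
  })
}

record_to_row <- function(rec, i) {
  where <- sprintf("contour %d", i)
  for (f in c("chamber", "layer", "phase", "plane", "vertices")) {
    if (is.null(rec[[f]])) {
      abort(sprintf("contour schema violation at %s: missing field %s", where, f))
    }
  }
  v <- rec$vertices
  if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
  v <- matrix(as.numeric(v), ncol = 2L)
  if (nrow(v) < 3L) {
    abort(sprintf("contour schema violation at %s: fewer than 3 vertices", where))
  }
  if (shoelace_area(v) <= 0) {
    abort(sprintf("contour schema violation at %s: zero enclosed area", where))
  }
  tibble(chamber = rec$chamber, layer = rec$layer, phase = rec$phase,
         slice = if (is.null(rec$slice)) NA_integer_ else as.integer(rec$slice),
         angle = if (is.null(rec$angle)) NA_real_ else as.numeric(rec$angle),
         vertices = list(v), plane = list(plane_from_list(rec$plane, where)))
}

#' Read a contour set from JSON
#'
#' Validates the document against the shipped schema (version, required
#' fields, vertex count, plane geometry) and rebuilds a typed `sax_stack` or
#' `lax_set`; round-trips objects written by [write_contours()].
#'
#' @param path File path.
#' @return A `sax_stack` or `lax_set`.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version)) abort("contour file has no schema_version")
  if (!identical(doc$schema_version, CONTOUR_SCHEMA_VERSION)) {
    abort(sprintf("unsupported contour schema version '%s' (supported: %s)",
                  doc$schema_version, CONTOUR_SCHEMA_VERSION))
  }
  if (!doc$type %in% c("sax_stack", "lax_set")) {
    abort(sprintf("unknown contour set type '%s'", doc$type))
  }
  rows <- dplyr::bind_rows(
    lapply(seq_along(doc$contours),
           function(i) record_to_row(doc$contours[[i]], i)))
  extra <- NULL
  if (!is.null(doc$basal_extra) && length(doc$basal_extra)) {
    extra <- dplyr::bind_rows(
      lapply(seq_along(doc$basal_extra),
             function(i) record_to_row(doc$basal_extra[[i]], i)))
  }
  mp <- doc$mitral_plane
  if (!is.null(mp)) {
    mp <- list(normal = unlist(mp$normal), d = as.numeric(mp$d),
               point = unlist(mp$point))
  }
  la <- doc$long_axis
  if (!is.null(la)) {
    la <- list(point = unlist(la$point), direction = unlist(la$direction))
  }
  new_contour_set(rows, doc$type, list(
    thickness = null_na(doc$thickness), gap = null_na(doc$gap),
    mitral_plane = mp, long_axis = la,
    plane_angles = if (is.null(doc$plane_angles)) NULL else unlist(doc$plane_angles),
    n_vertices = if (is.null(doc$n_vertices)) NULL else as.integer(doc$n_vertices),
    basal_extra = extra))
}

null_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' Write study result tables to disk
#'
#' Emits `volumes.csv`, `bias.csv`, `interobserver.csv` and `report.json`
#' (fixed column order, full-precision deterministic formatting) into `dir`.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_results <- function(report, dir) {
  if (!inherits(report, "study_report")) abort("report must be a study_report")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(volumes = file.path(dir, "volumes.csv"),
             bias = file.path(dir, "bias.csv"),
             interobserver = file.path(dir, "interobserver.csv"),
             report = file.path(dir, "report.json"))
  readr::write_csv(report$volumes, paths[["volumes"]])
  readr::write_csv(report$bias, paths[["bias"]])
  readr::write_csv(report$interobserver, paths[["interobserver"]])
  jsonlite::write_json(
    list(config = unclass(report$config_echo), truth = report$truth),
    paths[["report"]], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paths)
}
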