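#' Read and write annotation scenes as GeoJSON
#'
#' The GeoJSON dialect used here is a plain `FeatureCollection` whose
#' features carry pixel coordinates (x right, y down — image convention, not
#' geographic; ratios are unaffected by the axis flip). Closed contours are
#' `Polygon` geometries (first ring only), open traces are `LineString`s.
#' Required properties per feature: `role` (one of [scene_roles]) and
#' `micrograph_id`; `magnification`, `object_id` and `mitochondrion_id` are
#' carried when present.
#'
#' @param path File path.
#' @return [read_geojson_scene()] returns a scene tibble;
#'   [write_geojson_scene()] returns `path` invisibly.
#' @examples
#' f <- system.file("extdata", "example_scene_5000x.geojson",
#'                  package = "mitomorph")
#' sc <- read_geojson_scene(f)
#' taim_for_scene(sc)
#'
#' f15 <- system.file("extdata", "example_scene_15000x.geojson",
#'                    package = "mitomorph")
#' scene_oimr(read_geojson_scene(f15))
#' @name geojson_io
NULL

#' @rdname geojson_io
#' @export
read_geojson_scene <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection") || is.null(gj$features)) {
    abort(paste0(path, " is not a GeoJSON FeatureCollection"))
  }
  if (length(gj$features) == 0L) abort(paste0("no features found in ", path))
  rows <- purrr::imap(gj$features, function(f, i) {
    props <- f$properties
    if (is.null(props$role)) {
      abort(paste0("feature ", i, " has no 'role' property; allowed roles: ",
                   paste(scene_roles, collapse = ", ")))
    }
    if (!props$role %in% scene_roles) {
      abort(paste0("feature ", i, " has unknown role '", props$role,
                   "'; allowed roles: ", paste(scene_roles, collapse = ", ")))
    }
    if (is.null(props$micrograph_id)) {
      abort(paste0("feature ", i, " has no 'micrograph_id' property"))
    }
    gtype <- f$geometry$type
    coords <- switch(gtype,
      Polygon = f$geometry$coordinates[[1]],
      LineString = f$geometry$coordinates,
      abort(paste0("feature ", i, ": unsupported geometry type '", gtype, "'"))
    )
    xy <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    closed <- identical(gtype, "Polygon")
    # GeoJSON polygons repeat the first vertex at the end; we store it once
    if (closed && nrow(xy) > 1L && all(xy[1, ] == xy[nrow(xy), ])) {
      xy <- xy[-nrow(xy), , drop = FALSE]
    }
    colnames(xy) <- c("x", "y")
    tibble(
      micrograph_id = as.character(props$micrograph_id),
      magnification = as.numeric(props$magnification %||% NA_real_),
      role = props$role,
      object_id = as.character(props$object_id %||% paste0("feature_", i)),
      mitochondrion_id = as.character(props$mitochondrion_id %||% NA_character_),
      closed = closed,
      xy = list(xy)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (length(unique(out$micrograph_id)) > 1L) {
    abort(paste0(path, " mixes micrograph_ids: ",
                 paste(unique(out$micrograph_id), collapse = ", "),
                 "; one scene file per micrograph"))
  }
  out <- structure(out, class = scene_class)
  validate_scene(out)
  out
}

#' @param x A scene tibble.
#' @rdname geojson_io
#' @export
write_geojson_scene <- function(x, path) {
  validate_scene(x)
  features <- purrr::map(seq_len(nrow(x)), function(i) {
    xy <- x$xy[[i]]
    coords <- lapply(seq_len(nrow(xy)), function(r) c(xy[r, 1], xy[r, 2]))
    geom <- if (isTRUE(x$closed[i])) {
      list(type = "Polygon", coordinates = list(c(coords, coords[1])))
    } else {
      list(type = "LineString", coordinates = coords)
    }
    props <- list(
      role = x$role[i],
      micrograph_id = x$micrograph_id[i],
      magnification = x$magnification[i],
      object_id = x$object_id[i]
    )
    if (!is.na(x$mitochondrion_id[i])) {
      props$mitochondrion_id <- x$mitochondrion_id[i]
    }
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}
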