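#' Read and write ImageJ ROI annotations
#'
#' Minimal codec for the ImageJ `.roi` binary format (big-endian, "Iout"
#' magic), covering the trace types a membrane/region annotation workflow
#' produces: polygon, freehand and traced selections (closed contours),
#' polyline and freeline (open traces), and rectangles (converted to
#' 4-vertex polygons). Point, oval, angle and straight-line ROIs are
#' rejected by name. Coordinates are stored by the format as integer pixel
#' offsets, so a write/read roundtrip is exact only to the pixel grid
#' (sub-pixel float coordinates are read when present, never written).
#'
#' Since ImageJ ROI names carry no role semantics, roles come from an
#' explicit manifest table with columns `roi_name`, `role` and (for membrane
#' roles) `mitochondrion_id`.
#'
#' @name imagej_io
NULL

roi_types <- c(polygon = 0L, rect = 1L, oval = 2L, line = 3L, freeline = 4L,
               polyline = 5L, noroi = 6L, freehand = 7L, traced = 8L,
               angle = 9L, point = 10L)

read_u2 <- function(con) readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                                 endian = "big")
read_s2 <- function(con) readBin(con, "integer", 1L, size = 2L, signed = TRUE,
                                 endian = "big")

# Decode one .roi blob into list(xy, closed).
decode_roi <- function(raw, roi_name) {
  con <- rawConnection(raw, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "Iout")) {
    abort(paste0("'", roi_name, "' is not an ImageJ ROI (bad magic)"))
  }
  readBin(con, "raw", 2L)                     # version
  type <- as.integer(readBin(con, "raw", 1L)) # byte 6
  readBin(con, "raw", 1L)                     # byte 7, unused
  top <- read_s2(con); left <- read_s2(con)
  read_s2(con); read_s2(con)                  # bottom, right
  n <- read_u2(con)
  readBin(con, "raw", 32L)                    # x1..y2, stroke, shape, colors
  options <- read_u2(con)                     # bytes 50-51
  readBin(con, "raw", 12L)                    # rest of the 64-byte header
  closed <- type %in% roi_types[c("polygon", "freehand", "traced", "rect")]
  open <- type %in% roi_types[c("freeline", "polyline")]
  if (type == roi_types[["rect"]]) {
    # reconstruct from bounding box; re-read bottom/right
    con2 <- rawConnection(raw, "rb")
    on.exit(close(con2), add = TRUE)
    readBin(con2, "raw", 12L)
    bottom <- read_s2(con2); right <- read_s2(con2)
    xy <- cbind(x = c(left, right, right, left), y = c(top, top, bottom, bottom))
    return(list(xy = xy, closed = TRUE))
  }
  if (!closed && !open) {
    abort(paste0("ROI '", roi_name, "' has unsupported type ",
                 names(roi_types)[match(type, roi_types)] %||% type,
                 "; supported: polygon, freehand, traced, polyline, freeline, rect"))
  }
  if (n < 1L) abort(paste0("ROI '", roi_name, "' has no coordinates"))
  xs <- readBin(con, "integer", n, size = 2L, signed = TRUE, endian = "big")
  ys <- readBin(con, "integer", n, size = 2L, signed = TRUE, endian = "big")
  if (bitwAnd(options, 128L) > 0L && length(raw) >= 64L + 4L * n + 8L * n) {
    # SUB_PIXEL_RESOLUTION: absolute float coordinates follow the integers
    fx <- readBin(con, "double", n, size = 4L, endian = "big")
    fy <- readBin(con, "double", n, size = 4L, endian = "big")
    xy <- cbind(x = fx, y = fy)
  } else {
    xy <- cbind(x = left + xs, y = top + ys)
  }
  list(xy = xy, closed = closed)
}

encode_roi <- function(xy, closed) {
  left <- floor(min(xy[, 1])); top <- floor(min(xy[, 2]))
  xs <- as.integer(round(xy[, 1] - left)); ys <- as.integer(round(xy[, 2] - top))
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "big")
  writeBin(charToRaw("Iout"), con)
  w2(228L)                                             # version
  type <- if (closed) roi_types[["polygon"]] else roi_types[["polyline"]]
  writeBin(as.raw(c(type, 0L)), con)
  w2(top); w2(left)
  w2(top + max(ys)); w2(left + max(xs))                # bottom, right
  w2(nrow(xy))
  writeBin(raw(46L), con)                              # rest of header zeroed
  w2(xs); w2(ys)
  rawConnectionValue(con)
}

read_manifest <- function(manifest) {
  manifest <- as_tibble(manifest)
  if (!all(c("roi_name", "role") %in% names(manifest))) {
    abort("ROI manifest must have columns roi_name and role")
  }
  if (!"mitochondrion_id" %in% names(manifest)) {
    manifest$mitochondrion_id <- NA_character_
  }
  bad <- setdiff(unique(manifest$role), scene_roles)
  if (length(bad)) {
    abort(paste0("manifest contains unknown role(s) ",
                 paste0("'", bad, "'", collapse = ", "),
                 "; allowed roles: ", paste(scene_roles, collapse = ", ")))
  }
  manifest
}

#' @param path A `.roi` file, a `.zip` archive of ROIs, or a directory of
#'   `.roi` files.
#' @param manifest Role-mapping table (data frame with columns `roi_name`,
#'   `role`, optional `mitochondrion_id`); ROI names are file names without
#'   the `.roi` extension.
#' @param micrograph_id,magnification Scene metadata (the ROI format carries
#'   neither).
#' @return [read_imagej_rois()] returns a scene tibble.
#' @rdname imagej_io
#' @export
read_imagej_rois <- function(path, manifest, micrograph_id, magnification) {
  manifest <- read_manifest(manifest)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.roi$", full.names = TRUE)
    blobs <- lapply(files, function(f) readBin(f, "raw", file.size(f)))
    names(blobs) <- sub("\\.roi$", "", basename(files))
  } else if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("rois_")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE))
    files <- unzip(path, exdir = exdir)
    files <- files[grepl("\\.roi$", files)]
    blobs <- lapply(files, function(f) readBin(f, "raw", file.size(f)))
    names(blobs) <- sub("\\.roi$", "", basename(files))
  } else {
    blobs <- list(readBin(path, "raw", file.size(path)))
    names(blobs) <- sub("\\.roi$", "", basename(path))
  }
  if (length(blobs) == 0L) abort(paste0("no ROIs found in ", path))
  unmapped <- setdiff(names(blobs), manifest$roi_name)
  if (length(unmapped)) {
    abort(paste0("ROI name(s) absent from manifest: ",
                 paste(unmapped, collapse = ", ")))
  }
  rows <- purrr::imap(blobs, function(blob, nm) {
    dec <- decode_roi(blob, nm)
    m <- manifest[match(nm, manifest$roi_name), ]
    tibble(
      micrograph_id = micrograph_id,
      magnification = as.numeric(magnification),
      role = m$role, object_id = nm,
      mitochondrion_id = as.character(m$mitochondrion_id),
      closed = dec$closed, xy = list(dec$xy)
    )
  })
  out <- structure(dplyr::bind_rows(rows), class = scene_class)
  validate_scene(out)
  out
}

#' @param x A scene tibble.
#' @rdname imagej_io
#' @export
#' @return [write_imagej_rois()] writes `<object_id>.roi` entries into a zip
#'   archive at `path` and returns the matching manifest tibble, invisibly.
write_imagej_rois <- function(x, path) {
  validate_scene(x)
  tmp <- tempfile("rois_out_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  for (i in seq_len(nrow(x))) {
    writeBin(encode_roi(x$xy[[i]], x$closed[i]),
             file.path(tmp, paste0(x$object_id[i], ".roi")))
  }
  zip::zip(normalizePath(path, mustWork = FALSE),
           files = list.files(tmp), root = tmp)
  invisible(tibble(
    roi_name = x$object_id, role = x$role,
    mitochondrion_id = x$mitochondrion_id
  ))
}
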