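#' Annotation scenes
#'
#' A *scene* collects every labeled geometric primitive traced on one
#' micrograph, as a tidy tibble with one row per traced object and columns:
#'
#' * `micrograph_id` — identifier of the micrograph (non-empty, one per scene)
#' * `magnification` — nominal magnification (e.g. 5000 or 15000); metadata
#'   that routes the scene to the area-fraction (5000x) or membrane-ratio
#'   (15000x) computation, never used to rescale coordinates
#' * `role` — one of `"interfibrillar"`, `"mitochondrion"`,
#'   `"outer_membrane"`, `"inner_membrane"`
#' * `object_id` — identifier of the traced object (unique within the scene)
#' * `mitochondrion_id` — for membrane roles, which mitochondrion the trace
#'   belongs to; `NA` otherwise
#' * `closed` — whether the trace is a closed contour (polygon) or an open
#'   polyline; inner-membrane traces may be either
#' * `xy` — list column of two-column vertex matrices
#'
#' @name scene
NULL

#' Role vocabulary for scene annotations
#' @export
scene_roles <- c("interfibrillar", "mitochondrion", "outer_membrane", "inner_membrane")

scene_class <- c("mito_scene", "tbl_df", "tbl", "data.frame")

#' Build an annotation scene
#'
#' Convenience constructor assembling the tidy scene tibble from geometry
#' lists. `membranes` describes one mitochondrion per element:
#' `list(outer = <xy>, inner = list(<xy>, ...))`; element names become
#' `mitochondrion_id`s.
#'
#' @param micrograph_id Micrograph identifier (non-empty string).
#' @param magnification Nominal magnification, e.g. `5000` or `15000`.
#' @param regions List of interfibrillar-region polygons (vertex matrices).
#' @param mitochondria List of mitochondrion outline polygons.
#' @param membranes Named list of membrane sets (see above).
#' @param validate Run [validate_scene()] on the result.
#' @return A scene tibble (see [scene]).
#' @examples
#' sq <- function(s) cbind(x = c(0, s, s, 0), y = c(0, 0, s, s))
#' scene("m1", 5000, regions = list(sq(10)), mitochondria = list(sq(2)))
#' @export
scene <- function(micrograph_id, magnification,
                  regions = list(), mitochondria = list(),
                  membranes = list(), validate = TRUE) {
  rows <- list()
  add <- function(role, id, mito_id, closed, xy) {
    rows[[length(rows) + 1L]] <<- tibble(
      micrograph_id = micrograph_id,
      magnification = as.numeric(magnification),
      role = role, object_id = id, mitochondrion_id = mito_id,
      closed = closed, xy = list(as_xy(xy, id))
    )
  }
  for (i in seq_along(regions)) {
    add("interfibrillar", paste0("ifs_", i), NA_character_, TRUE, regions[[i]])
  }
  for (i in seq_along(mitochondria)) {
    add("mitochondrion", paste0("mito_", i), NA_character_, TRUE, mitochondria[[i]])
  }
  mito_ids <- names(membranes) %||% as.character(seq_along(membranes))
  for (i in seq_along(membranes)) {
    ms <- membranes[[i]]
    add("outer_membrane", paste0("outer_", mito_ids[i]), mito_ids[i], TRUE, ms$outer)
    for (j in seq_along(ms$inner)) {
      inner <- ms$inner[[j]]
      add("inner_membrane", paste0("inner_", mito_ids[i], "_", j), mito_ids[i],
          isTRUE(attr(inner, "closed")), inner)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(
      micrograph_id = character(), magnification = numeric(),
      role = character(), object_id = character(),
      mitochondrion_id = character(), closed = logical(), xy = list()
    )
  }
  out <- structure(out, class = scene_class)
  if (validate && nrow(out) > 0L) validate_scene(out)
  out
}

#' Validate an annotation scene
#'
#' Checks the scene contract: a single non-empty `micrograph_id`, roles drawn
#' from [scene_roles], unique `object_id`s, valid polygons for closed roles,
#' and for each annotated mitochondrion exactly one outer contour with at
#' least one inner trace of positive total length.
#'
#' @param x A scene tibble.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_scene <- function(x) {
  required <- c("micrograph_id", "magnification", "role", "object_id",
                "mitochondrion_id", "closed", "xy")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0("scene is missing columns: ", paste(missing, collapse = ", ")))
  }
  ids <- unique(x$micrograph_id)
  if (length(ids) != 1L || is.na(ids) || !nzchar(ids)) {
    abort("scene must carry exactly one non-empty micrograph_id")
  }
  bad_roles <- setdiff(unique(x$role), scene_roles)
  if (length(bad_roles)) {
    abort(paste0(
      "unknown role(s) ", paste0("'", bad_roles, "'", collapse = ", "),
      "; allowed roles are: ", paste(scene_roles, collapse = ", ")
    ))
  }
  if (anyDuplicated(x$object_id)) {
    abort("object_id values must be unique within a scene")
  }
  for (i in seq_len(nrow(x))) {
    if (isTRUE(x$closed[i])) {
      validate_polygon(x$xy[[i]], id = x$object_id[i])
    } else if (nrow(as_xy(x$xy[[i]], x$object_id[i])) < 2L) {
      abort(paste0("polyline", label(x$object_id[i]), " needs at least 2 vertices"))
    }
  }
  memb <- x[x$role %in% c("outer_membrane", "inner_membrane"), ]
  if (nrow(memb)) {
    if (anyNA(memb$mitochondrion_id)) {
      abort("membrane traces must carry a mitochondrion_id")
    }
    for (mid in unique(memb$mitochondrion_id)) {
      m <- memb[memb$mitochondrion_id == mid, ]
      n_outer <- sum(m$role == "outer_membrane")
      n_inner <- sum(m$role == "inner_membrane")
      if (n_outer != 1L) {
        abort(paste0("mitochondrion '", mid, "' has ", n_outer,
                     " outer contours; exactly 1 required"))
      }
      if (n_inner < 1L) {
        abort(paste0("mitochondrion '", mid, "' has no inner-membrane traces"))
      }
    }
  }
  invisible(x)
}

#' Extract membrane sets from a 15000x scene
#'
#' @param x A scene tibble.
#' @return A tibble with one row per annotated mitochondrion: columns
#'   `mitochondrion_id`, `outer` (vertex matrix), `inner` (list of vertex
#'   matrices) and `inner_closed` (list of logicals).
#' @export
membrane_sets <- function(x) {
  validate_scene(x)
  memb <- x[x$role %in% c("outer_membrane", "inner_membrane"), ]
  if (nrow(memb) == 0L) {
    return(tibble(mitochondrion_id = character(), outer = list(),
                  inner = list(), inner_closed = list()))
  }
  memb |>
    dplyr::group_by(.data$mitochondrion_id) |>
    dplyr::summarise(
      outer = .data$xy[.data$role == "outer_membrane"],
      inner = list(.data$xy[.data$role == "inner_membrane"]),
      inner_closed = list(.data$closed[.data$role == "inner_membrane"]),
      .groups = "drop"
    )
}

#' @export
print.mito_scene <- function(x, ...) {
  cat(sprintf(
    "<annotation scene '%s' at %gx: %d region(s), %d mitochondria, %d membrane trace(s)>\n",
    x$micrograph_id[1] %||% "?", x$magnification[1] %||% NA,
    sum(x$role == "interfibrillar"), sum(x$role == "mitochondrion"),
    sum(x$role %in% c("outer_membrane", "inner_membrane"))
  ))
  NextMethod()
}

#' Plot the traced geometry of a scene
#'
#' @param object A scene tibble.
#' @param ... Unused.
#' @return A ggplot; the y axis is reversed to match image coordinates.
#' @exportS3Method ggplot2::autoplot
autoplot.mito_scene <- function(object, ...) {
  df <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    xy <- object$xy[[i]]
    tibble(
      x = xy[, 1], y = xy[, 2],
      role = object$role[i], object_id = object$object_id[i],
      closed = object$closed[i]
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$object_id,
                                   colour = .data$role)) +
    ggplot2::geom_path(data = df[!df$closed, ]) +
    ggplot2::geom_polygon(data = df[df$closed, ], fill = NA) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = object$micrograph_id[1],
      subtitle = paste0(object$magnification[1], "x"),
      x = "x (px)", y = "y (px)"
    )
}
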