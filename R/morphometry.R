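#' Total area of interfibrillar mitochondria (TAIM) for one scene
#'
#' Area fraction, in percent, of the interfibrillar space occupied by
#' mitochondria: `100 * sum(clipped mitochondrial areas) / sum(region areas)`.
#' A mitochondrion extending beyond the annotated interfibrillar region
#' contributes only its clipped (intersection) part, so partially overlapping
#' outlines never inflate the fraction. The denominator is the total
#' annotated interfibrillar area, mitochondria included — consistent with
#' mitochondria lying *within* the counted space. Regions are expected to be
#' disjoint; the numerator clips against their union.
#'
#' @param x A 5000x scene tibble with at least one `interfibrillar` region
#'   and one `mitochondrion` outline.
#' @return TAIM in percent, in `(0, 100]` for mitochondria inside the region.
#' @seealso [patient_taim()], [oimr_for_mitochondrion()]
#' @export
taim_for_scene <- function(x) {
  validate_scene(x)
  regions <- x$xy[x$role == "interfibrillar"]
  mitos <- x$xy[x$role == "mitochondrion"]
  if (length(regions) == 0L) {
    abort("scene has no interfibrillar region; TAIM is undefined")
  }
  if (length(mitos) == 0L) {
    abort("scene has no mitochondrion outlines; TAIM is undefined (not zero)")
  }
  denom <- sum(vapply(regions, polygon_area, numeric(1), check_simple = FALSE))
  if (denom <= 0) abort("total interfibrillar region area is zero")
  region_paths <- lapply(regions, function(r) list(x = r[, 1], y = r[, 2]))
  eps <- clip_eps(do.call(rbind, c(regions, mitos)))
  union <- if (length(region_paths) == 1L) {
    region_paths
  } else {
    polyclip::polyclip(region_paths, list(), op = "union", eps = eps)
  }
  num <- sum(vapply(mitos, function(m) {
    pieces <- polyclip::polyclip(list(list(x = m[, 1], y = m[, 2])), union,
                                 op = "intersection", eps = eps)
    if (length(pieces) == 0L) 0 else
      sum(vapply(pieces, function(p) abs(shoelace(cbind(p$x, p$y))), numeric(1)))
  }, numeric(1)))
  100 * num / denom
}

#' Outer-to-inner membrane length ratio (OIMR) for one mitochondrion
#'
#' `100 * length(outer contour) / sum(lengths of inner traces)`. The inner
#' length is the total of *all* traces labeled `inner_membrane` for the
#' mitochondrion — the inner boundary membrane, if traced, plus every crista.
#' Since cristae add inner length, values are typically well below 100%;
#' cristae loss drives the ratio towards 100%.
#'
#' @param outer Closed outer-membrane contour (vertex matrix).
#' @param inner List of inner-membrane traces (vertex matrices).
#' @param inner_closed Logical vector: which inner traces are closed contours
#'   (their closing segment counts towards the length).
#' @param id Optional mitochondrion label for error messages.
#' @return OIMR in percent.
#' @export
oimr_for_mitochondrion <- function(outer, inner, inner_closed = FALSE, id = NULL) {
  outer <- validate_polygon(outer, id)
  if (!is.list(inner)) inner <- list(inner)
  if (length(inner) == 0L) {
    abort(paste0("mitochondrion", label(id), " has no inner-membrane traces"))
  }
  inner_closed <- rep_len(inner_closed, length(inner))
  inner_len <- sum(vapply(seq_along(inner), function(j) {
    path_length(inner[[j]], closed = inner_closed[j], id = id)
  }, numeric(1)))
  if (inner_len <= 0) {
    abort(paste0("mitochondrion", label(id), " has zero total inner-membrane length"))
  }
  100 * path_length(outer, closed = TRUE) / inner_len
}

#' Per-mitochondrion OIMR values of a 15000x scene
#'
#' @param x A scene tibble containing membrane traces.
#' @return A tibble with columns `mitochondrion_id` and `oimr_pct`.
#' @export
scene_oimr <- function(x) {
  ms <- membrane_sets(x)
  if (nrow(ms) == 0L) {
    abort(paste0("scene '", x$micrograph_id[1], "' has no membrane sets"))
  }
  ms |>
    dplyr::mutate(oimr_pct = purrr::pmap_dbl(
      list(.data$outer, .data$inner, .data$inner_closed, .data$mitochondrion_id),
      oimr_for_mitochondrion
    )) |>
    dplyr::select("mitochondrion_id", "oimr_pct")
}

check_protocol <- function(counts, expected, what, strict) {
  off <- counts != expected
  if (!any(off)) return(invisible())
  msg <- paste0(
    "protocol expects ", expected, " ", what, "; observed: ",
    paste0(names(counts), "=", counts, collapse = ", ")
  )
  if (strict) {
    abort(msg, class = "mitomorph_protocol_error")
  }
  warn(msg)
}

#' Per-patient TAIM: mean over 5000x scenes
#'
#' The measurement protocol analyses three 5000x micrographs per patient and
#' averages their area fractions. By default a deviation from three scenes
#' only warns; `strict = TRUE` enforces the protocol.
#'
#' @param scenes List of 5000x scene tibbles for one patient.
#' @param strict Enforce exactly 3 scenes.
#' @return Mean TAIM in percent.
#' @export
patient_taim <- function(scenes, strict = FALSE) {
  if (length(scenes) == 0L) abort("no 5000x scenes supplied")
  check_protocol(setNames(length(scenes), "scenes"), 3L, "micrographs at 5000x", strict)
  mean(vapply(scenes, taim_for_scene, numeric(1)))
}

#' Per-patient OIMR: grand mean over all measured mitochondria
#'
#' The protocol analyses three 15000x micrographs per patient, three
#' mitochondria each, and averages. The grand mean over all mitochondria is
#' used; under the balanced 3 x 3 design it coincides exactly with the mean
#' of per-scene means. For unbalanced inputs the grand mean weights every
#' mitochondrion equally (documented choice).
#'
#' @param scenes List of 15000x scene tibbles for one patient.
#' @param strict Enforce exactly 3 scenes with 3 mitochondria each.
#' @return Mean OIMR in percent.
#' @export
patient_oimr <- function(scenes, strict = FALSE) {
  if (length(scenes) == 0L) abort("no 15000x scenes supplied")
  per_scene <- lapply(scenes, scene_oimr)
  n_mito <- vapply(per_scene, nrow, integer(1))
  names(n_mito) <- vapply(scenes, function(s) s$micrograph_id[1], character(1))
  check_protocol(setNames(length(scenes), "scenes"), 3L, "micrographs at 15000x", strict)
  check_protocol(n_mito, 3L, "mitochondria per micrograph", strict)
  mean(unlist(lapply(per_scene, `[[`, "oimr_pct")))
}

#' Total ultrastructure index
#'
#' `taim_pct / oimr_pct`: combines mitochondrial packing density and inner
#' membrane elaboration into one number. The two components move in opposite
#' directions under ultrastructural deterioration (packing falls, the
#' membrane ratio rises), so the index amplifies their joint signal. Carried
#' at full precision; round only for display (2 decimals).
#'
#' @param taim_pct,oimr_pct Percentages, strictly positive. Vectorized.
#' @return Dimensionless ratio.
#' @examples
#' total_index(43.7, 31) # 1.4097
#' @export
total_index <- function(taim_pct, oimr_pct) {
  if (length(taim_pct) != length(oimr_pct)) {
    abort("taim_pct and oimr_pct must have equal length")
  }
  if (any(!is.finite(taim_pct)) || any(!is.finite(oimr_pct)) ||
      any(taim_pct <= 0) || any(oimr_pct <= 0)) {
    abort("taim_pct and oimr_pct must be finite and strictly positive")
  }
  taim_pct / oimr_pct
}

#' Patient-level morphometry for a cohort of scenes
#'
#' Takes a tidy cohort table with one row per scene and computes the three
#' morphometric parameters per patient. Scenes are routed by magnification:
#' `taim_mag` scenes feed the area fraction, `oimr_mag` scenes feed the
#' membrane ratio. The total index is computed from the patient-level means
#' (not per scene).
#'
#' @param cohort A tibble with columns `patient_id`, `group_label` and
#'   `scene` (list column of scene tibbles).
#' @param strict Enforce the 3-micrograph / 3-mitochondria protocol.
#' @param taim_mag,oimr_mag Magnifications routed to each computation.
#' @return A tibble with one row per patient: `patient_id`, `group_label`,
#'   `taim_pct`, `oimr_pct`, `total_index`, `n_micrographs_5000x`,
#'   `n_mitochondria_15000x`.
#' @export
compute_morphometry <- function(cohort, strict = FALSE,
                                taim_mag = 5000, oimr_mag = 15000) {
  required <- c("patient_id", "group_label", "scene")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    abort(paste0("cohort is missing columns: ", paste(missing, collapse = ", ")))
  }
  cohort |>
    dplyr::group_by(.data$patient_id, .data$group_label) |>
    dplyr::group_modify(function(d, key) {
      mags <- vapply(d$scene, function(s) s$magnification[1], numeric(1))
      s_taim <- d$scene[mags == taim_mag]
      s_oimr <- d$scene[mags == oimr_mag]
      taim <- patient_taim(s_taim, strict = strict)
      oimr <- patient_oimr(s_oimr, strict = strict)
      tibble(
        taim_pct = taim, oimr_pct = oimr,
        total_index = total_index(taim, oimr),
        n_micrographs_5000x = length(s_taim),
        n_mitochondria_15000x = sum(vapply(
          s_oimr, function(s) nrow(membrane_sets(s)), integer(1)
        ))
      )
    }) |>
    dplyr::ungroup()
}
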