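#' Specification objects for the synthetic-annotation generator
#'
#' The generator exists so that every stage of the pipeline can be exercised
#' against known ground truth: scenes whose mitochondrial packing fraction
#' is exact by construction, membrane sets whose outer/inner length ratio is
#' exact by construction, and two-group cohorts drawn from distributions
#' matched to published summary statistics. All generators are deterministic
#' given their spec and seed.
#'
#' @param region_size Width and height of the rectangular interfibrillar
#'   region, px.
#' @param target_packing Ground-truth mitochondrial area fraction, in
#'   (0, 0.8); high fractions near the geometric limit of disjoint convex
#'   packings may be rejected as infeasible.
#' @param n_mitochondria Number of mitochondrion outlines; `NULL` uses every
#'   placement cell.
#' @param mito_size_range Range of mitochondrion radii, px.
#' @param seed RNG seed (local to the generator call).
#' @return A spec list used by [generate_scene()],
#'   [generate_membrane_set()] or [generate_cohort()].
#' @name synthetic_specs
NULL

#' @rdname synthetic_specs
#' @export
scene_spec <- function(region_size = c(1200, 900), target_packing = 0.437,
                       n_mitochondria = NULL, mito_size_range = c(40, 90),
                       seed = 1L) {
  if (!is.numeric(target_packing) || target_packing <= 0 || target_packing >= 0.8) {
    abort("target_packing must lie in (0, 0.8); disjoint convex outlines cannot pack denser",
          class = "mitomorph_feasibility_error")
  }
  if (length(region_size) != 2L || any(region_size <= 0)) {
    abort("region_size must be two positive lengths")
  }
  if (mito_size_range[1] <= 0 || mito_size_range[2] < mito_size_range[1]) {
    abort("mito_size_range must be an increasing positive range")
  }
  structure(list(
    region_size = region_size, target_packing = target_packing,
    n_mitochondria = n_mitochondria, mito_size_range = mito_size_range,
    seed = seed
  ), class = "scene_spec")
}

ellipse_poly <- function(cx, cy, a, b, n = 20L, phase = 0) {
  th <- phase + seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + a * cos(th), y = cy + b * sin(th))
}

#' Generate a 5000x scene with known packing fraction
#'
#' Places disjoint convex (elliptical) mitochondrion outlines inside a
#' rectangular interfibrillar region on a jittered grid — one candidate
#' outline per cell, sized by seeded draws — then rescales every outline
#' about its centroid by a single factor so the realized area fraction
#' equals `target_packing` exactly (shrinking convex outlines about their
#' centroids preserves disjointness and containment). Grid placement is used
#' instead of naive sequential rejection sampling because random sequential
#' placement of disjoint convex bodies jams near a fraction of 0.55, well
#' below fractions the generator must reach.
#'
#' @param spec A [scene_spec()].
#' @param micrograph_id Identifier for the generated scene.
#' @return A scene tibble (magnification 5000) with attributes
#'   `target_packing` and `realized_packing`; [taim_for_scene()] recovers
#'   `100 * realized_packing`.
#' @export
generate_scene <- function(spec, micrograph_id = "sim_5000_1") {
  stopifnot(inherits(spec, "scene_spec"))
  W <- spec$region_size[1]; H <- spec$region_size[2]
  target_area <- spec$target_packing * W * H
  g <- 2 * spec$mito_size_range[2]
  nx <- max(1L, round(W / g)); ny <- max(1L, round(H / g))
  w <- W / nx; h <- H / ny
  cells <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  if (!is.null(spec$n_mitochondria) && spec$n_mitochondria > nrow(cells)) {
    abort(paste0("cannot place ", spec$n_mitochondria, " outlines: only ",
                 nrow(cells), " placement cells at this size range; ",
                 "lower the count or the size range"))
  }
  with_local_seed(spec$seed, {
    if (!is.null(spec$n_mitochondria)) {
      cells <- cells[sample.int(nrow(cells), spec$n_mitochondria), ]
    }
    n <- nrow(cells)
    u_min <- spec$mito_size_range[1] / spec$mito_size_range[2]
    u <- runif(n, u_min, 1)
    aspect <- runif(n, 0.9, 1)
    # semi-axes at full size u = 1 nearly fill the cell
    a0 <- 0.995 * w / 2; b0 <- 0.995 * h / 2
    # exact area of the 20-vertex polygon inscribed in an ellipse:
    # (n/2) sin(2*pi/n) a b (affine image of a regular polygon)
    k20 <- 10 * sin(pi / 10)
    cell_area <- function(u) k20 * (u * a0) * (u * b0 * aspect)
    # inflate the draws towards the cell bound: solve the exact scale for
    # the still-uncapped cells each pass (a pass either caps a new cell or
    # lands the total exactly on target)
    for (k in seq_len(n + 1L)) {
      placed <- sum(cell_area(u))
      if (placed >= target_area) break
      free <- u < 1
      if (!any(free)) break
      need <- target_area - sum(cell_area(u)[!free])
      u[free] <- pmin(u[free] * sqrt(need / sum(cell_area(u)[free])), 1)
    }
    placed <- sum(cell_area(u))
    if (placed < target_area * (1 - 1e-9)) {
      abort(paste0(
        "packing fraction ", signif(spec$target_packing, 3),
        " is infeasible for this region and size range (max reachable ~",
        signif(placed / (W * H), 3), "); lower target_packing"
      ), class = "mitomorph_feasibility_error")
    }
    f <- sqrt(target_area / placed)   # exact global shrink, f <= 1
    mitos <- lapply(seq_len(n), function(i) {
      ai <- f * u[i] * a0; bi <- f * u[i] * b0 * aspect[i]
      jx <- runif(1, -(w / 2 - ai - 0.001 * w), w / 2 - ai - 0.001 * w)
      jy <- runif(1, -(h / 2 - bi - 0.001 * h), h / 2 - bi - 0.001 * h)
      ellipse_poly(cells$ix[i] * w + w / 2 + jx,
                   cells$iy[i] * h + h / 2 + jy,
                   ai, bi, phase = runif(1, 0, 2 * pi))
    })
    region <- cbind(x = c(0, W, W, 0), y = c(0, 0, H, H))
    out <- scene(micrograph_id, 5000, regions = list(region),
                 mitochondria = mitos, validate = FALSE)
    realized <- sum(vapply(mitos, function(m) abs(shoelace(m)), numeric(1))) / (W * H)
    attr(out, "target_packing") <- spec$target_packing
    attr(out, "realized_packing") <- realized
    out
  })
}

#' @rdname synthetic_specs
#' @param target_oimr Ground-truth outer-to-inner membrane length ratio, %,
#'   in (5, 100].
#' @param n_cristae Number of inner-membrane (crista) traces.
#' @param outer_axes Semi-axes of the elliptical outer membrane, px.
#' @export
membrane_spec <- function(target_oimr = 31, n_cristae = 15L,
                          outer_axes = c(60, 40), seed = 1L) {
  if (!is.numeric(target_oimr) || target_oimr <= 5 || target_oimr > 100) {
    abort("target_oimr must lie in (5, 100]")
  }
  if (n_cristae < 1L) abort("n_cristae must be at least 1")
  structure(list(
    target_oimr = target_oimr, n_cristae = as.integer(n_cristae),
    outer_axes = outer_axes, seed = seed
  ), class = "membrane_spec")
}

#' Generate a membrane set with known outer/inner length ratio
#'
#' The outer membrane is a 96-vertex elliptical contour of perimeter P. The
#' inner membrane is laid down as `n_cristae` chords of the ellipse, drawn
#' near-diametral by seeded sampling and then contracted about their
#' midpoints by one common factor so their total length equals
#' `100 * P / target_oimr` exactly (contraction about a midpoint keeps a
#' chord inside the convex outer contour). [oimr_for_mitochondrion()] on the
#' result recovers `target_oimr` to floating-point precision.
#'
#' @param spec A [membrane_spec()].
#' @param center Center of the outer contour, px.
#' @return `list(outer = <polygon>, inner = <list of 2-point polylines>)`,
#'   ready for the `membranes` argument of [scene()], with attribute
#'   `target_oimr`.
#' @export
generate_membrane_set <- function(spec, center = c(0, 0)) {
  stopifnot(inherits(spec, "membrane_spec"))
  a <- spec$outer_axes[1]; b <- spec$outer_axes[2]
  outer <- ellipse_poly(center[1], center[2], a, b, n = 96L)
  P <- path_length(outer, closed = TRUE)
  L <- 100 * P / spec$target_oimr
  max_chord <- 2 * max(a, b)
  if (L > spec$n_cristae * max_chord) {
    abort(paste0(
      "total inner length ", round(L), " px cannot fit in ", spec$n_cristae,
      " chords of an ellipse with axes ", a, " x ", b,
      "; increase n_cristae or target_oimr"
    ), class = "mitomorph_feasibility_error")
  }
  with_local_seed(spec$seed, {
    for (try in 1:50) {
      t1 <- runif(spec$n_cristae, 0, 2 * pi)
      t2 <- t1 + pi * runif(spec$n_cristae, 0.8, 1.2)
      p1 <- cbind(center[1] + a * cos(t1), center[2] + b * sin(t1))
      p2 <- cbind(center[1] + a * cos(t2), center[2] + b * sin(t2))
      lens <- sqrt(rowSums((p2 - p1)^2))
      if (sum(lens) >= L) break
    }
    if (sum(lens) < L) {
      abort("could not draw chords totalling the required inner length; increase n_cristae",
            class = "mitomorph_feasibility_error")
    }
    f <- L / sum(lens)    # f <= 1: contract about midpoints
    inner <- lapply(seq_len(spec$n_cristae), function(i) {
      m <- (p1[i, ] + p2[i, ]) / 2
      d <- (p2[i, ] - p1[i, ]) / 2
      seg <- rbind(m - f * d, m + f * d)
      colnames(seg) <- c("x", "y")
      seg
    })
    structure(list(outer = outer, inner = inner),
              target_oimr = spec$target_oimr)
  })
}

#' @rdname synthetic_specs
#' @param n_per_group Patients in group 0 (reference) and group 1 (positive
#'   class).
#' @param taim_location,taim_scale Per-group mean and SD of the TAIM
#'   distribution (percent). Defaults reproduce published group medians and
#'   interquartile ranges (49 \[36; 64\] vs 42 \[33; 49\]) under a normal
#'   model: location = median, scale = IQR / 1.34898.
#' @param oimr_location,oimr_scale Same for OIMR; defaults reproduce
#'   31 \[25; 36\] vs 35 \[30; 45\].
#' @param family Distribution family; only `"truncnorm"` (normal truncated
#'   to `trunc`) is implemented.
#' @param trunc Truncation bounds, percent.
#' @export
cohort_spec <- function(n_per_group = c(27L, 12L),
                        taim_location = c(49, 42),
                        taim_scale = c(64 - 36, 49 - 33) / (2 * qnorm(0.75)),
                        oimr_location = c(31, 35),
                        oimr_scale = c(36 - 25, 45 - 30) / (2 * qnorm(0.75)),
                        family = "truncnorm",
                        trunc = c(1, 99),
                        seed = 1L) {
  if (any(n_per_group < 2L)) abort("n_per_group must be at least 2 per group")
  if (!identical(family, "truncnorm")) {
    abort("only the 'truncnorm' family is implemented")
  }
  if (any(taim_scale <= 0) || any(oimr_scale <= 0)) {
    abort("scales must be strictly positive")
  }
  structure(list(
    n_per_group = as.integer(n_per_group),
    taim_location = taim_location, taim_scale = taim_scale,
    oimr_location = oimr_location, oimr_scale = oimr_scale,
    family = family, trunc = trunc, seed = seed
  ), class = "cohort_spec")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= lo | x >= hi)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

#' @importFrom stats qnorm
NULL

#' Draw a synthetic two-group cohort of morphometry parameters
#'
#' Draws per-patient TAIM and OIMR from the spec's truncated normal
#' distributions (independently within patient) and computes the total
#' index. With `materialize = TRUE`, each patient's parameter values are
#' additionally realized as full annotation scenes following the
#' measurement protocol — `scenes_per_patient` 5000x scenes whose packing
#' fractions average exactly to the drawn TAIM, and the same number of
#' 15000x scenes with `mitos_per_scene` membrane sets whose ratios average
#' exactly to the drawn OIMR — so the scene-level pipeline recovers the
#' drawn values. For materialization, drawn TAIM is clamped to the
#' packing-feasible window (2, 65)% (clamping is recorded in the returned
#' truth table).
#'
#' @param spec A [cohort_spec()].
#' @param materialize Also build full annotation scenes?
#' @param scenes_per_patient,mitos_per_scene Protocol counts (3 and 3).
#' @return With `materialize = FALSE`: a results tibble (`patient_id`,
#'   `group_label`, `taim_pct`, `oimr_pct`, `total_index`). With
#'   `materialize = TRUE`: a list with `truth` (that tibble) and `scenes`
#'   (a cohort tibble of `patient_id`, `group_label`, `scene` list column
#'   suitable for [compute_morphometry()]).
#' @export
generate_cohort <- function(spec, materialize = FALSE,
                            scenes_per_patient = 3L, mitos_per_scene = 3L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    rows <- purrr::map(1:2, function(g) {
      n <- spec$n_per_group[g]
      tibble(
        patient_id = sprintf("g%d_p%02d", g - 1L, seq_len(n)),
        group_label = g - 1L,
        taim_pct = rtruncnorm(n, spec$taim_location[g], spec$taim_scale[g],
                              spec$trunc[1], spec$trunc[2]),
        oimr_pct = rtruncnorm(n, spec$oimr_location[g], spec$oimr_scale[g],
                              spec$trunc[1], spec$trunc[2])
      )
    })
    truth <- dplyr::bind_rows(rows)
    truth$total_index <- total_index(truth$taim_pct, truth$oimr_pct)
    if (!materialize) return(truth)

    truth$taim_materialized <- pmin(pmax(truth$taim_pct, 2), 65)
    truth$oimr_materialized <- pmin(pmax(truth$oimr_pct, 6.5), 98.5)
    scene_rows <- purrr::map(seq_len(nrow(truth)), function(i) {
      pid <- truth$patient_id[i]
      t_taim <- truth$taim_materialized[i]
      t_oimr <- truth$oimr_materialized[i]
      seeds <- sample.int(.Machine$integer.max %/% 2L, 2L * scenes_per_patient)
      # per-scene packing targets average exactly to the patient value
      d <- runif(1, 0, max(0, min(3, 67 - t_taim, t_taim - 2.5)))
      taim_targets <- t_taim + d * seq(-1, 1, length.out = scenes_per_patient)
      n_mito <- scenes_per_patient * mitos_per_scene
      d2 <- runif(1, 0, max(0, min(4, 98 - t_oimr, t_oimr - 6)))
      oimr_targets <- t_oimr + d2 * seq(-1, 1, length.out = n_mito)
      s5000 <- lapply(seq_len(scenes_per_patient), function(k) {
        generate_scene(
          scene_spec(target_packing = taim_targets[k] / 100, seed = seeds[k]),
          micrograph_id = sprintf("%s_5000_%d", pid, k)
        )
      })
      s15000 <- lapply(seq_len(scenes_per_patient), function(k) {
        targets <- oimr_targets[(k - 1L) * mitos_per_scene + seq_len(mitos_per_scene)]
        membranes <- lapply(seq_along(targets), function(j) {
          # enough chords to carry the required inner length (mean
          # near-diametral chord of the default ellipse is ~0.7 max chord)
          n_cristae <- max(15, ceiling(100 * 320 / targets[j] / (0.65 * 120)))
          generate_membrane_set(
            membrane_spec(target_oimr = targets[j], n_cristae = n_cristae,
                          seed = seeds[scenes_per_patient + k] + j),
            center = c(150 * j, 0)
          )
        })
        names(membranes) <- paste0("mito_", seq_along(membranes))
        scene(sprintf("%s_15000_%d", pid, k), 15000, membranes = membranes)
      })
      tibble(
        patient_id = pid, group_label = truth$group_label[i],
        scene = c(s5000, s15000)
      )
    })
    list(truth = truth, scenes = dplyr::bind_rows(scene_rows))
  })
}
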