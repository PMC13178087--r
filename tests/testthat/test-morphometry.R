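test_that("taim_for_scene computes the interfibrillar area fraction", {
  s <- scene("m1", 5000,
             regions = list(square_xy(10)),
             mitochondria = list(square_xy(5, 0, 0), square_xy(5, 5, 5)))
  expect_equal(taim_for_scene(s), 50)

  # mitochondrion straddling the region edge counts only its clipped part:
  # 2x2 square half inside a 10x10 region -> 2 / 100 -> 2%
  s2 <- scene("m2", 5000,
              regions = list(square_xy(10)),
              mitochondria = list(cbind(x = c(-1, 1, 1, -1), y = c(4, 4, 6, 6))))
  expect_equal(taim_for_scene(s2), 2)
})

test_that("taim_for_scene distinguishes unannotated from empty", {
  no_region <- scene("m1", 5000, mitochondria = list(square_xy(2)))
  expect_error(taim_for_scene(no_region), "no interfibrillar region")
  no_mito <- scene("m1", 5000, regions = list(square_xy(10)))
  expect_error(taim_for_scene(no_mito), "no mitochondrion outlines")
})

test_that("oimr_for_mitochondrion is the outer/inner length percentage", {
  outer <- square_xy(10) # perimeter 40
  expect_equal(oimr_for_mitochondrion(outer, list(cbind(c(0, 40), c(5, 5)))), 100)
  # inner traces sized so 100 * 40 / (4000/31) = 31 exactly
  inner <- list(cbind(c(0, 4000 / 31), c(5, 5)))
  expect_equal(oimr_for_mitochondrion(outer, inner), 31, tolerance = 1e-12)
  # scaling the whole mitochondrion leaves the ratio unchanged
  expect_equal(oimr_for_mitochondrion(outer * 3, lapply(inner, `*`, 3)), 31,
               tolerance = 1e-12)
  expect_error(oimr_for_mitochondrion(outer, list()), "no inner-membrane")
})

test_that("closed inner traces count their closing segment", {
  outer <- square_xy(10)
  inner_sq <- square_xy(5) # perimeter 20 when closed
  expect_equal(
    oimr_for_mitochondrion(outer, list(inner_sq), inner_closed = TRUE),
    100 * 40 / 20
  )
})

test_that("patient averaging follows the 3-micrograph protocol", {
  sc <- function(id, total) membrane_square_scene(id, side = 10, inner_total = total)
  # three scenes x constant ratio -> that ratio
  same <- lapply(1:3, function(i) {
    membrane_square_scene(paste0("s", i), side = 10, inner_total = 4000 / 31,
                          n_mito = 3)
  })
  expect_equal(patient_oimr(same), 31, tolerance = 1e-12)
  # values {20, 30, 40} average to 30 (inner lengths 200, 400/3, 100)
  mixed <- suppressWarnings(patient_oimr(list(
    sc("a", 4000 / 20), sc("b", 4000 / 30), sc("c", 4000 / 40)
  )))
  expect_equal(mixed, 30, tolerance = 1e-12)
})

test_that("grand mean equals mean of scene means only for balanced designs", {
  sc2 <- membrane_square_scene("u1", inner_total = 4000 / 10, n_mito = 2) # two at 10
  sc1 <- membrane_square_scene("u2", inner_total = 4000 / 40, n_mito = 1) # one at 40
  grand <- suppressWarnings(patient_oimr(list(sc2, sc1)))
  expect_equal(grand, (10 + 10 + 40) / 3, tolerance = 1e-12) # per-mitochondrion
  expect_false(isTRUE(all.equal(grand, (10 + 40) / 2)))      # not scene-mean rule
})

test_that("strict mode enforces the protocol and reports counts", {
  two <- lapply(1:2, function(i) membrane_square_scene(paste0("s", i)))
  w <- testthat::capture_warnings(patient_oimr(two))
  expect_match(w, "protocol expects 3", all = TRUE)
  expect_length(w, 2) # scene count and per-micrograph mitochondrion count
  err <- expect_error(patient_oimr(two, strict = TRUE),
                      class = "mitomorph_protocol_error")
  expect_match(conditionMessage(err), "scenes=2")
  taims <- lapply(1:2, function(i) {
    scene(paste0("t", i), 5000, regions = list(square_xy(10)),
          mitochondria = list(square_xy(5)))
  })
  expect_warning(patient_taim(taims), "protocol expects 3")
  expect_error(patient_taim(taims, strict = TRUE),
               class = "mitomorph_protocol_error")
  expect_error(patient_taim(list()), "no 5000x scenes")
})

test_that("patient_taim averages per-scene fractions", {
  mk <- function(id, frac) {
    scene(id, 5000, regions = list(square_xy(10)),
          mitochondria = list(square_xy(sqrt(frac) * 10)))
  }
  scenes <- list(mk("a", 0.40), mk("b", 0.45), mk("c", 0.50))
  expect_equal(patient_taim(scenes), 45, tolerance = 1e-9)
  expect_equal(suppressWarnings(patient_taim(scenes[1])), 40, tolerance = 1e-9)
})

test_that("total_index is the ratio of the two percentages", {
  expect_equal(total_index(43.7, 31), 43.7 / 31)
  expect_equal(round(total_index(43.7, 31), 2), 1.41)
  expect_equal(round(total_index(42, 35), 1), 1.2)
  for (x in c(0.5, 31, 99)) expect_equal(total_index(x, x), 1)
  expect_error(total_index(-1, 10), "strictly positive")
  expect_error(total_index(10, 0), "strictly positive")
  # opposite directionality: increasing OIMR lowers the index and vice versa
  expect_lt(total_index(43.7, 35), total_index(43.7, 31))
  expect_gt(total_index(50, 31), total_index(43.7, 31))
})

test_that("morphometric quantities are similarity-invariant at scene level", {
  sc5 <- generate_scene(scene_spec(target_packing = 0.4, seed = 2), "inv5")
  ms <- generate_membrane_set(membrane_spec(31, seed = 2))
  sc15 <- scene("inv15", 15000, membranes = list(m1 = ms))
  t0 <- taim_for_scene(sc5)
  o0 <- scene_oimr(sc15)$oimr_pct
  for (f in list(
    function(xy) xy * 2.7,
    function(xy) rotate_xy(xy, 1.1),
    function(xy) cbind(xy[, 1] + 300, xy[, 2] - 80)
  )) {
    expect_equal(taim_for_scene(transform_scene(sc5, f)), t0, tolerance = 1e-9)
    expect_equal(scene_oimr(transform_scene(sc15, f))$oimr_pct, o0,
                 tolerance = 1e-9)
  }
})

test_that("TAIM is monotone when a mitochondrion is added inside the region", {
  base <- scene("m", 5000, regions = list(square_xy(20)),
                mitochondria = list(square_xy(4, 1, 1)))
  more <- scene("m", 5000, regions = list(square_xy(20)),
                mitochondria = list(square_xy(4, 1, 1), square_xy(3, 10, 10)))
  expect_gt(taim_for_scene(more), taim_for_scene(base))
})

test_that("compute_morphometry aggregates per patient across magnifications", {
  sim <- generate_cohort(cohort_spec(n_per_group = c(2, 2), seed = 5),
                         materialize = TRUE)
  res <- compute_morphometry(sim$scenes)
  expect_equal(nrow(res), 4)
  expect_named(res, c("patient_id", "group_label", "taim_pct", "oimr_pct",
                      "total_index", "n_micrographs_5000x",
                      "n_mitochondria_15000x"))
  expect_equal(res$n_micrographs_5000x, rep(3L, 4))
  expect_equal(res$n_mitochondria_15000x, rep(9L, 4))
  truth <- sim$truth[match(res$patient_id, sim$truth$patient_id), ]
  expect_equal(res$taim_pct, truth$taim_materialized, tolerance = 1e-6)
  expect_equal(res$oimr_pct, truth$oimr_materialized, tolerance = 1e-9)
  expect_equal(res$total_index,
               res$taim_pct / res$oimr_pct, tolerance = 1e-12)
})
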