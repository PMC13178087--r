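test_that("scene constructor builds a valid tidy scene", {
  s <- scene("m1", 5000, regions = list(square_xy(10)),
             mitochondria = list(square_xy(2), square_xy(2, 5, 5)))
  expect_s3_class(s, "mito_scene")
  expect_equal(nrow(s), 3)
  expect_setequal(unique(s$role), c("interfibrillar", "mitochondrion"))
  expect_output(print(s), "annotation scene 'm1'")
})

test_that("validate_scene enforces the scene contract", {
  s <- scene("m1", 5000, regions = list(square_xy(10)))
  bad_role <- s
  bad_role$role <- "nucleus"
  expect_error(validate_scene(bad_role), "interfibrillar.*inner_membrane")
  two_ids <- dplyr::bind_rows(s, dplyr::mutate(s, micrograph_id = "m2",
                                               object_id = "other"))
  expect_error(validate_scene(two_ids), "exactly one")
  dup <- dplyr::bind_rows(s, s)
  expect_error(validate_scene(dup), "unique")
  # membrane sets: exactly one outer and at least one inner per mitochondrion
  no_inner <- scene("m1", 15000, validate = FALSE,
                    membranes = list(m1 = list(outer = square_xy(4),
                                               inner = list())))
  expect_error(validate_scene(no_inner), "no inner-membrane traces")
})

test_that("GeoJSON write/read is a lossless roundtrip", {
  withr::local_seed(3)
  dir <- withr::local_tempdir()
  for (i in 1:6) {
    sc <- generate_scene(
      scene_spec(target_packing = runif(1, 0.1, 0.6), seed = i),
      micrograph_id = paste0("rt_", i)
    )
    ms <- generate_membrane_set(membrane_spec(runif(1, 15, 90), seed = i))
    sc15 <- scene(paste0("rt15_", i), 15000, membranes = list(m1 = ms))
    for (s in list(sc, sc15)) {
      f <- file.path(dir, paste0(s$micrograph_id[1], ".geojson"))
      write_geojson_scene(s, f)
      back <- read_geojson_scene(f)
      expect_equal(back$role, s$role)
      expect_equal(back$object_id, s$object_id)
      expect_equal(back$closed, s$closed)
      expect_equal(back$magnification, s$magnification)
      for (j in seq_len(nrow(s))) {
        expect_equal(unname(back$xy[[j]]), unname(s$xy[[j]]), tolerance = 1e-12)
      }
    }
  }
})

test_that("GeoJSON reader rejects malformed annotation files", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.geojson")

  writeLines('{"type": "FeatureCollection", "features": []}', f)
  expect_error(read_geojson_scene(f), "no features")

  feature <- function(props) paste0(
    '{"type":"Feature","properties":', props, ',
      "geometry":{"type":"Polygon",
        "coordinates":[[[0,0],[4,0],[4,4],[0,4],[0,0]]]}}'
  )
  fc <- function(...) paste0('{"type":"FeatureCollection","features":[',
                             paste(..., sep = ","), "]}")

  writeLines(fc(feature('{"micrograph_id":"m1"}')), f)
  expect_error(read_geojson_scene(f), "no 'role'")

  writeLines(fc(feature('{"role":"nucleus","micrograph_id":"m1"}')), f)
  expect_error(read_geojson_scene(f),
               "interfibrillar, mitochondrion, outer_membrane, inner_membrane")

  writeLines(fc(feature('{"role":"interfibrillar","micrograph_id":"m1"}'),
                feature('{"role":"interfibrillar","micrograph_id":"m2"}')),
             f)
  expect_error(read_geojson_scene(f), "mixes micrograph_ids")
})

test_that("ImageJ ROI zip write/read roundtrips within pixel quantization", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(scene_spec(target_packing = 0.3, seed = 9), "ij_1")
  zip_path <- file.path(dir, "ij_1.zip")
  manifest <- write_imagej_rois(sc, zip_path)
  expect_true(file.exists(zip_path))
  back <- read_imagej_rois(zip_path, manifest,
                           micrograph_id = "ij_1", magnification = 5000)
  expect_setequal(back$object_id, sc$object_id)
  for (id in sc$object_id) {
    a <- sc$xy[[match(id, sc$object_id)]]
    b <- back$xy[[match(id, back$object_id)]]
    expect_equal(dim(a), dim(b))
    expect_lt(max(abs(a - b)), 0.5 + 1e-9) # format stores integer offsets
  }
})

test_that("ImageJ reader enforces manifest completeness and ROI support", {
  dir <- withr::local_tempdir()
  sc <- scene("ij_2", 5000, regions = list(square_xy(100)),
              mitochondria = list(square_xy(10, 20, 20)))
  zip_path <- file.path(dir, "ij_2.zip")
  manifest <- write_imagej_rois(sc, zip_path)
  expect_error(
    read_imagej_rois(zip_path, manifest[1, ], "ij_2", 5000),
    "absent from manifest: mito_1"
  )
  # directory with no .roi files
  empty <- file.path(dir, "empty")
  dir.create(empty)
  expect_error(read_imagej_rois(empty, manifest, "x", 5000), "no ROIs found")
  # corrupt the type byte of one ROI to an unsupported selection type (oval)
  roi_dir <- file.path(dir, "rois")
  utils::unzip(zip_path, exdir = roi_dir)
  f <- file.path(roi_dir, "mito_1.roi")
  raw <- readBin(f, "raw", file.size(f))
  raw[7] <- as.raw(2)
  writeBin(raw, f)
  expect_error(read_imagej_rois(roi_dir, manifest, "ij_2", 5000),
               "mito_1.*unsupported type oval")
  # manifest with a role outside the vocabulary
  manifest$role[1] <- "sarcomere"
  expect_error(read_imagej_rois(zip_path, manifest, "ij_2", 5000),
               "unknown role")
})

test_that("both serializations yield identical morphometry on grid-aligned scenes", {
  dir <- withr::local_tempdir()
  # integer coordinates survive the ROI format exactly
  sc <- scene("fmt", 5000,
              regions = list(square_xy(100)),
              mitochondria = list(square_xy(20, 10, 10), square_xy(30, 50, 50)))
  gj <- file.path(dir, "fmt.geojson")
  zp <- file.path(dir, "fmt.zip")
  write_geojson_scene(sc, gj)
  manifest <- write_imagej_rois(sc, zp)
  t1 <- taim_for_scene(read_geojson_scene(gj))
  t2 <- taim_for_scene(read_imagej_rois(zp, manifest, "fmt", 5000))
  expect_identical(t1, t2)
  expect_equal(t1, 100 * (400 + 900) / 10000)
})

test_that("results CSV roundtrips and rejects invalid inputs", {
  dir <- withr::local_tempdir()
  res <- generate_cohort(cohort_spec(n_per_group = c(2, 2), seed = 4))
  res$n_micrographs_5000x <- 3L
  res$n_mitochondria_15000x <- 9L
  f <- file.path(dir, "results.csv")
  write_results_csv(res, f)
  expect_length(readLines(f), nrow(res) + 1L)
  back <- read_results_csv(f)
  expect_equal(back$taim_pct, res$taim_pct, tolerance = 1e-6)
  expect_equal(back$total_index, res$total_index, tolerance = 1e-6)
  expect_equal(names(back)[1:7],
               c("patient_id", "group_label", "taim_pct", "oimr_pct",
                 "total_index", "n_micrographs_5000x", "n_mitochondria_15000x"))
  dup <- dplyr::bind_rows(res, res[1, ])
  expect_error(write_results_csv(dup, f), "duplicate patient_id")
  expect_error(write_results_csv(res[0, ], f), "no results")
})
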