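test_that("panoptic artifacts round-trip through disk losslessly", {
  dir <- withr::local_tempdir()
  mask <- matrix(rc[["stroma"]], 100, 100)
  mask[20:40, 20:40] <- rc[["epithelium"]]
  mpath <- file.path(dir, "mask.png")
  hips:::write_label_image(mask, mpath, mpp = 1)
  nuc <- make_nuclei(c(10, 50, 80), c(10, 50, 80),
                     c("cancer_epith", "fibroblast", "lymphocyte"))
  npath <- file.path(dir, "nuclei.csv")
  write_nuclei_csv(nuc, npath)
  s <- load_panoptic(mpath, npath)
  expect_identical(s$region_mask, mask)
  expect_equal(nrow(s$nuclei), 3)
  expect_equal(s$mpp, 1)
  # determinism: identical bytes in -> identical object out
  s2 <- load_panoptic(mpath, npath)
  expect_identical(s$nuclei, s2$nuclei)
  expect_identical(s$region_mask, s2$region_mask)
})

test_that("probability vectors are renormalized and bounds enforced", {
  nuc <- make_nuclei(10, 10, "lymphocyte")
  nuc[, paste0("prob_", hips_schema()$nucleus_subclasses)] <- 0.2
  s <- make_slide(nuc, side = 64)
  expect_equal(sum(s$nuclei[1, hips:::prob_cols()]), 1)
  expect_equal(unname(unlist(s$nuclei[1, hips:::prob_cols()])),
               rep(1 / 6, 6))
  # nucleus outside the mask is a validation error naming the offender
  bad <- make_nuclei(c(10, -5), c(10, 10), c("lymphocyte", "lymphocyte"))
  expect_error(make_slide(bad, side = 64), "outside mask bounds")
  # unknown region code is a schema error
  expect_error(slide_panoptic("x", 1, matrix(9L, 10, 10), make_nuclei(
    5, 5, "lymphocyte")), "unknown class code")
})

test_that("GeoJSON nuclei with point and polygon geometry are read", {
  dir <- withr::local_tempdir()
  pc <- hips:::prob_cols()
  props <- as.list(probs_row("fibroblast"))
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(12, 30)),
         properties = c(list(nucleus_id = "a"), props)),
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(5, 5), c(9, 5), c(9, 9),
                                                 c(5, 9), c(5, 5)))),
         properties = c(list(nucleus_id = "b"), props))))
  path <- file.path(dir, "n.geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  nuc <- read_nuclei_geojson(path)
  expect_equal(nrow(nuc), 2)
  expect_equal(nuc$x_um[1], 12)
  expect_equal(nuc$x_um[2], 7)  # polygon centroid
  expect_match(nuc$wkt_polygon[2], "^POLYGON")
})

test_that("feature tables survive write/read with precision and order", {
  dir <- withr::local_tempdir()
  df <- data.frame(patient_id = c("p1", "p2"),
                   A = c(1 / 3, 2.123456789012345),
                   B = c(NA, -4.5e-7), Zfirst = c(10, 20),
                   check.names = FALSE, stringsAsFactors = FALSE)
  path <- file.path(dir, "f.csv")
  write_feature_table(df, path)
  back <- read_feature_table(path)
  expect_identical(names(back), names(df))
  expect_equal(back$A, df$A, tolerance = 1e-12)
  expect_true(is.na(back$B[1]))
  # manifest/column mismatch is an error
  man <- jsonlite::fromJSON(paste0(path, ".manifest.json"))
  man$name[1] <- "renamed"
  jsonlite::write_json(man, paste0(path, ".manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  expect_error(read_feature_table(path), "manifest")
  # duplicate feature names are rejected at write time
  dup <- df; names(dup)[3] <- "A"
  expect_error(write_feature_table(dup, file.path(dir, "g.csv")), "duplicate")
})

test_that("validation reports violations without failing", {
  s <- make_slide(make_nuclei(c(10, 30), c(10, 30),
                              c("cancer_epith", "fibroblast")), side = 64)
  expect_length(validate_panoptic(s)$violations, 0)
  # probabilities summing to 1.5: build the raw list bypassing the constructor
  bad <- s
  bad$nuclei$prob_cancer_epith <- bad$nuclei$prob_cancer_epith + 0.5
  rep <- validate_panoptic(bad)
  expect_length(rep$violations, 1)
  expect_match(rep$violations, "summing to 1")
  # empty nuclei table: a warning entry, not a violation
  s0 <- make_slide(make_nuclei(numeric(0), numeric(0), character(0)),
                   side = 64)
  rep0 <- validate_panoptic(s0)
  expect_length(rep0$violations, 0)
  expect_match(rep0$warnings, "empty")
})
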