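test_that("the pipeline record recovers phantom ground truth and its identities", {
  ph <- default_phantom()
  rec <- default_run()
  tr <- ph$truth
  expect_lt(abs(rec$roota - tr$true_root_area) / tr$true_root_area, 0.03)
  expect_lt(abs(rec$stelea - tr$true_stele_area) / tr$true_stele_area, 0.03)
  expect_lt(abs(rec$cma - tr$true_cma) / tr$true_cma, 0.10)
  expect_equal(rec$ncm, tr$true_ncm)
  expect_equal(rec$ncl, tr$true_ncl)
  expect_equal(rec$ncf, tr$true_cells_per_file)
  # subtraction identities hold exactly
  expect_identical(rec$roota, rec$ela + rec$ctxa + rec$stelea)
  # no manual metaxylem count: NM is missing, not zero
  expect_true(is.na(rec$nm))
  expect_length(rec$ncf, 5)
  expect_match(rec$warnings, "5 candidate", all = FALSE)
})

test_that("manual counts flow through to the record", {
  ph <- default_phantom()
  rec <- run_pipeline(ph$image, pipeline_params(manual_nm = 7, manual_ncm = 3))
  expect_equal(rec$nm, 7L)
  expect_equal(rec$ncm, 3L)
})

test_that("the measurement table uses the standard column layout and round-trips", {
  rec <- default_run()
  rec2 <- rec
  rec2$image_id <- "second"
  rec2$nm <- 9L
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(list(rec, rec2), path)
  tab <- utils::read.delim(path, check.names = FALSE)
  expect_equal(names(tab),
               c("image_id", "unit", "ROOTA", "ELA", "CTXA", "STELEA", "CMA",
                 "NCM", "NM", "NCL", paste0("NCF", 1:5)))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$ROOTA, rep(rec$roota, 2))
  expect_true(is.na(tab$NM[1]) && tab$NM[2] == 9)
  expect_equal(tab$NCL, rep(round(rec$ncl, 2), 2))
  expect_equal(unlist(tab[1, paste0("NCF", 1:5)], use.names = FALSE), rec$ncf)

  # empty record list: header only
  write_table(list(), path)
  expect_equal(length(readLines(path)), 1L)
})

test_that("ROI JSON export round-trips every area and count exactly", {
  rec <- default_run()
  path <- withr::local_tempfile(fileext = ".json")
  export_rois(rec, path)
  doc <- load_rois(path)
  expect_equal(doc$measurements$roota, rec$roota)
  expect_equal(doc$measurements$stelea, rec$stelea)
  expect_equal(doc$measurements$cma, rec$cma)
  expect_equal(doc$measurements$ncl, rec$ncl)
  expect_equal(unlist(doc$measurements$ncf), rec$ncf)
  expect_true(is.null(doc$measurements$nm))
  expect_named(doc$selections,
               c("root", "stele", "central_metaxylem", "cortex"))
  expect_equal(doc$selections$root$area_px, rec$detail$selections$root$area_px)
  # counting lines carry geometry and counts
  line <- doc$counting_lines[[1]]
  expect_equal(line$orientation, "radial")
  expect_equal(line$raw_count, rec$detail$layer_profiles[[1]]$raw_count)
  expect_equal(unlist(line$maxima), rec$detail$layer_profiles[[1]]$maxima)
})

test_that("the overlay has the source dimensions and one contour per selection", {
  ph <- default_phantom()
  rec <- default_run()
  path <- withr::local_tempfile(fileext = ".png")
  export_overlay(ph$image, rec, path)
  e <- EBImage::readImage(path)
  expect_equal(dim(e)[1:2], c(ph$image$width, ph$image$height))
  n_contours <- sum(vapply(rec$detail$selections,
                           function(s) length(s$contour), integer(1)))
  expect_gte(n_contours, 4)
})

test_that("batch analysis continues past failures and is byte-deterministic", {
  d <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(image_size = c(320, 320),
                                      root_radius = 100, noise_sigma = 5,
                                      rng_seed = 12))
  EBImage::writeImage(EBImage::Image(t(ph$image$pixels) / 255),
                      file.path(d, "good.png"))
  EBImage::writeImage(EBImage::Image(matrix(0, 128, 128)),
                      file.path(d, "blank.png"))
  p <- pipeline_params(verbose = FALSE)
  out1 <- file.path(d, "out1"); out2 <- file.path(d, "out2")
  res1 <- analyze_batch(d, p, out1)
  res2 <- analyze_batch(d, p, out2)
  expect_length(res1$records, 1)
  expect_length(res1$failures, 1)
  expect_match(res1$failures[["blank.png"]], "no foreground")
  expect_equal(res1$exit_status, 2L)
  for (f in c("measurements.tsv", "good_rois.json")) {
    expect_identical(readBin(file.path(out1, f), "raw", n = 1e7),
                     readBin(file.path(out2, f), "raw", n = 1e7))
  }

  # an all-good batch exits 0
  d2 <- withr::local_tempdir()
  file.copy(file.path(d, "good.png"), file.path(d2, "good.png"))
  expect_equal(analyze_batch(d2, p, file.path(d2, "out"))$exit_status, 0L)
})

test_that("per-image configuration overrides reach the pipeline", {
  d <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(image_size = c(320, 320),
                                      root_radius = 100, rng_seed = 2))
  EBImage::writeImage(EBImage::Image(t(ph$image$pixels) / 255),
                      file.path(d, "img.png"))
  cfg_path <- file.path(d, "config.yaml")
  writeLines(c("noise_tolerance: 25",
               "images:",
               "  img.png:",
               "    manual_nm: 5",
               "    manual_ncm: 2"), cfg_path)
  res <- analyze_batch(file.path(d, "img.png"),
                       pipeline_params(verbose = FALSE),
                       file.path(d, "out"), config = cfg_path, overlay = FALSE)
  rec <- res$records[["img.png"]]
  expect_equal(rec$nm, 5L)
  expect_equal(rec$ncm, 2L)
  expect_error(rootcell:::.merge_params(pipeline_params(), list(bogus = 1)),
               "unknown parameter")
})
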