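test_that("experiments are reproducible end to end under one master seed", {
  cfg <- experimentConfig(conditions = c("NC", "MMC-0.025"), replicates = 2,
                          fieldsPerReplicate = 2, masterSeed = 42,
                          shape = smallShape, nCellsTarget = 13)
  r1 <- runExperiment(cfg)
  r2 <- runExperiment(cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$recovery, r2$recovery)
  expect_true(all(c("pct_bn", "freq_pct", "pct_cytotox_cn",
                    "pct_cytotox_cbpi", "fold_vs_NC") %in%
                    names(r1$summary)))
  expect_true(all(c("within_3se") %in% names(r1$recovery)))
  # written reports are byte-identical across runs
  d1 <- file.path(tempdir(), "exp1")
  d2 <- file.path(tempdir(), "exp2")
  cfg1 <- cfg
  cfg1$outputDir <- d1
  cfg2 <- cfg
  cfg2$outputDir <- d2
  runExperiment(cfg1)
  runExperiment(cfg2)
  for (f in c("summary.csv", "replicates.csv", "recovery.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("a control-only experiment is self-referential", {
  cfg <- experimentConfig(conditions = "NC", replicates = 1,
                          fieldsPerReplicate = 2, masterSeed = 7,
                          shape = smallShape, nCellsTarget = 13)
  r <- runExperiment(cfg)
  expect_equal(nrow(r$summary), 1)
  expect_equal(r$summary$fold_vs_NC, 1)
  expect_equal(r$summary$pct_cytotox_cn, 0)
  expect_equal(r$summary$pct_cytotox_cbpi, 0)
})

test_that("experiment configs validate and read from YAML", {
  expect_error(experimentConfig(conditions = "NOT-A-PRESET"),
               "unknown presets")
  expect_error(experimentConfig(replicates = 0), "replicate count")
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(conditions = list("NC"), replicates = 1,
                        fields_per_replicate = 2, master_seed = 9,
                        shape = list(760, 760),
                        microscopy = list(smoothSigma = 1.0)), path)
  cfg <- readExperimentConfig(path)
  expect_s3_class(cfg, "ExperimentConfig")
  expect_equal(cfg$masterSeed, 9L)
  expect_equal(cfg$microscopyCfg$smoothSigma, 1.0)
})

test_that("image and table IO round-trip through plain formats", {
  p <- smallPresets[["NC"]]
  f <- generateField(p, smallShape, seed = 3)
  tif <- tempfile(fileext = ".tif")
  writeFieldImage(f$image, tif)
  back <- readFieldImage(tif)
  expect_equal(dim(back), dim(f$image))
  # 16-bit quantisation: intensities agree to one grey level
  expect_lt(max(abs(back - f$image)), 1.01)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  writeGroundTruth(f$truth, csv, js)
  obj <- utils::read.csv(csv)
  expect_equal(sum(obj$object == "nucleus"), nrow(f$truth$nuclei))
  totals <- jsonlite::read_json(js)
  expect_equal(totals$n_cells, f$truth$totals$n_cells)
  # count-table validation
  bad <- data.frame(condition = "NC", replicate = 1, N1 = 10, N2 = 5,
                    N3 = 0, n_bi_with_mn = 9)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(readCountsCSV(path), "exceed")
})
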