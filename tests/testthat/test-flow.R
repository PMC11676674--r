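mkTile <- function(objectsDna, shape = c(128L, 128L), bfObjects = NULL) {
  dna <- drawImage(shape, objectsDna)
  bf <- matrix(20000, shape[1], shape[2])
  if (is.null(bfObjects))
    bfObjects <- list(list(r = 63.5, c = 63.5, a = 42, b = 40, value = 27000))
  for (o in bfObjects) {
    idx <- cbmnassay:::.ellipseIdx(o$r, o$c, o$a, o$b, 0, shape)
    bf[idx] <- o$value
  }
  list(bf = cbmnassay:::.gaussBlurC(bf, 2), dna = cbmnassay:::.gaussBlurC(dna, 2))
}

test_that("mask algebra is constructive and keeps MN clear of nuclei", {
  cfg <- flowConfig()
  blank <- list(bf = matrix(20000, 128, 128), dna = matrix(300, 128, 128))
  mb <- buildMasks(blank, cfg)
  for (nm in c("threshold", "spot", "range", "nuclear", "micronuclei"))
    expect_equal(sum(getMask(mb, nm)), 0)
  # binucleated tile with one clear micronucleus
  tile <- mkTile(list(disc(64, 46, 16), disc(64, 82, 16), disc(30, 90, 3.2)))
  m <- buildMasks(tile, cfg)
  expect_equal(max(EBImage::bwlabel(getMask(m, "micronuclei"))), 1)
  expect_gte(max(EBImage::bwlabel(getMask(m, "nuclear"))), 1)
  # a spot adjacent to the nucleus is removed by the AND NOT composition
  tile2 <- mkTile(list(disc(64, 64, 16), disc(64, 64 + 16 + 4, 3)))
  m2 <- buildMasks(tile2, cfg)
  expect_equal(sum(getMask(m2, "micronuclei")), 0)
  # disjointness invariant across random tiles
  ts <- generateTileSet(smallPresets[["MMC-0.025"]], 25, seed = 31)
  for (t in ts$tiles) {
    mm <- buildMasks(t, cfg)
    expect_false(any(getMask(mm, "micronuclei") & getMask(mm, "nuclear")))
  }
})

test_that("tile features behave on constructed cases", {
  cfg <- flowConfig()
  one <- mkTile(list(disc(64, 64, 16)))
  f1 <- computeTileFeatures(one, buildMasks(one, cfg), cfg)
  expect_equal(f1$lobe_count, 1L)
  expect_gt(f1$bf_aspect_ratio, 0.9)
  expect_true(f1$valid)
  two <- mkTile(list(disc(64, 46, 16), disc(64, 82, 16)))
  f2 <- computeTileFeatures(two, buildMasks(two, cfg), cfg)
  expect_equal(f2$lobe_count, 2L)
  expect_gt(f2$dna_area, f1$dna_area)
  # heavy extra blur lowers the focus measure
  blurred <- list(bf = cbmnassay:::.gaussBlurC(one$bf, 6),
                  dna = cbmnassay:::.gaussBlurC(one$dna, 6))
  fb <- computeTileFeatures(blurred, buildMasks(blurred, cfg), cfg)
  expect_lt(fb$gradient_rms, f1$gradient_rms)
  # empty nuclear mask flags the tile invalid
  empty <- list(bf = matrix(20000, 128, 128), dna = matrix(300, 128, 128))
  fe <- computeTileFeatures(empty, buildMasks(empty, cfg), cfg)
  expect_false(fe$valid)
})

test_that("spot counts are exact on noise-free tiles", {
  p <- smallPresets[["MMC-0.025"]]
  p@mnProbBi <- 0.6
  ts <- generateTileSet(p, 120, seed = 41, noiseFree = TRUE,
                        spoilers = c(oof = 0, doublet = 0, debris = 0))
  f <- scoreTiles(ts)
  sel <- ts$labels$is_bnc
  expect_true(all(f$mn_spot_count[sel] == ts$labels$mn_count[sel]))
})

test_that("the gate chain nests and behaves at the extremes", {
  p <- smallPresets[["NC"]]
  # clean binucleated tiles with a permissive config pass through entirely
  pBi <- p
  pBi@classFractions <- c(mono = 0, bi = 1, poly = 0)
  ts <- generateTileSet(pBi, 50, seed = 51,
                        spoilers = c(oof = 0, doublet = 0, debris = 0))
  f <- scoreTiles(ts)
  permissive <- gateConfig(focusMin = 0, bfAspectRatioMin = 0,
                           dnaAreaRange = c(1, 1e6), homogeneityMin = -1,
                           widthMin = 0, compactnessMax = 1e6,
                           aspectRatioIntensityRange = c(0, 1))
  res <- applyGates(f, permissive)
  expect_equal(sum(res$mn_hist), 50)
  # entirely out-of-focus tiles all fail the first gate
  tsOof <- generateTileSet(p, 30, seed = 52,
                           spoilers = c(oof = 1, doublet = 0, debris = 0))
  fOof <- scoreTiles(tsOof)
  resOof <- applyGates(fOof)
  expect_equal(resOof$gates$retained[resOof$gates$gate == "focus"], 0)
  expect_equal(sum(resOof$mn_hist), 0)
  # populations are non-increasing along the chain
  mixed <- scoreTiles(generateTileSet(p, 60, seed = 53))
  rMix <- applyGates(mixed)
  expect_true(all(diff(rMix$gates$retained) <= 0))
  # empty input is an empty result, not an error
  r0 <- applyGates(mixed[0, ])
  expect_equal(sum(r0$mn_hist), 0)
  # spot counts above 3 truncate into the top bin with a warning
  fx <- mixed[1:4, ]
  fx$mn_spot_count <- c(0L, 5L, 2L, 1L)
  expect_warning(rT <- applyGates(fx, permissive), "truncated")
  expect_equal(unname(rT$mn_hist["3"]), 1L)
})

test_that("gate calibration transfers across seeds", {
  p <- presetTable()[["MMC-FLOW"]]
  tsA <- generateTileSet(p, 350, seed = 61)
  tsB <- generateTileSet(p, 350, seed = 62)
  fA <- scoreTiles(tsA)
  fB <- scoreTiles(tsB)
  cal <- calibrateGates(fA, tsA$labels$is_bnc)
  expect_gte(cal$balanced_accuracy, 0.95)
  res <- applyGates(fB, cal$config)
  pred <- fB$tile %in% res$bnc_tiles
  isB <- tsB$labels$is_bnc
  ba <- (sum(pred & isB) / sum(isB) + sum(!pred & !isB) / sum(!isB)) / 2
  expect_gte(ba, 0.95)
  # degenerate labels are a calibration error
  expect_error(calibrateGates(fA, rep(TRUE, nrow(fA))), "calibration")
})
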