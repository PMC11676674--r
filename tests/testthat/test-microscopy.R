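test_that("preprocessing preserves constants and removes hot pixels", {
  cfg <- cfgDefault
  const <- matrix(1234, 64, 64)
  expect_equal(preprocessField(const, cfg), const, tolerance = 1e-9)
  hot <- matrix(500, 64, 64)
  hot[30, 30] <- 60000
  out <- preprocessField(hot, microscopyConfig(smoothSigma = 0))
  expect_lt(diff(range(out)), diff(range(hot)))
  expect_lt(max(out), 1000)
  expect_error(preprocessField(array(0, c(4, 4, 2)), cfg), "single-channel")
})

test_that("preprocessing increases signal-to-noise on a noisy field", {
  p <- smallPresets[["NC"]]
  f <- generateField(p, smallShape, seed = 11)
  clean <- generateField(p, smallShape, seed = 11, noiseFree = TRUE)
  nucMask <- clean$image > 6000
  bgMask <- clean$image < 400
  snr <- function(img) mean(img[nucMask]) / stats::sd(img[bgMask])
  expect_gt(snr(preprocessField(f$image, cfgDefault)), snr(f$image))
})

test_that("segmentation recovers ideal nuclei and respects size bounds", {
  objs <- lapply(seq(0, 4), function(k)
    disc(100 + 120 * (k %% 3), 100 + 120 * (k %/% 3), 18))
  img <- drawImage(c(400L, 400L), objs)
  nuc <- segmentNuclei(img, cfgDefault)
  expect_equal(nObjects(nuc), 5)
  expect_true(all(abs(objectTable(nuc)$area_px - pi * 18^2) <
                    0.05 * pi * 18^2))
  # two overlapping ellipses are declumped into two objects
  pair <- drawImage(c(300L, 300L), list(disc(150, 130, 18),
                                        disc(150, 162, 18)))
  expect_equal(nObjects(segmentNuclei(pair, cfgDefault)), 2)
  # micronucleus-sized spots are not nuclei
  spots <- drawImage(c(300L, 300L), list(disc(100, 100, 3),
                                         disc(200, 200, 3)))
  expect_equal(nObjects(segmentNuclei(spots, cfgDefault)), 0)
  # blank image: empty object set, not an error
  blank <- matrix(300, 200, 200)
  expect_equal(nObjects(segmentNuclei(blank, cfgDefault)), 0)
})

test_that("grouping classifies by member count and applies its rules", {
  # single isolated nucleus: mono with a positive-area cytoplasm annulus
  img <- drawImage(c(300L, 300L), list(disc(150, 150, 18)))
  nuc <- segmentNuclei(img, cfgDefault)
  grp <- groupCells(nuc, cfgDefault, computeMap = TRUE)
  g <- cellGroups(grp)
  expect_equal(nrow(g), 1)
  expect_equal(g$class, "mono")
  expect_gt(sum(cytoplasmMask(grp)), 0)
  expect_false(any(cytoplasmMask(grp) & labelMap(nuc) > 0))
  # two equal nuclei at 2.2 radii separation form one binucleated cell
  pair <- drawImage(c(300L, 300L), list(disc(150, 130, 18),
                                        disc(150, 130 + 2.2 * 18, 18)))
  g2 <- cellGroups(groupCells(segmentNuclei(pair, cfgDefault), cfgDefault,
                              computeMap = FALSE))
  expect_equal(g2$class, "bi")
  # area ratio 3 within grouping distance: rejected cluster
  odd <- drawImage(c(300L, 300L), list(disc(150, 120, 18),
                                       disc(150, 160, 10.4)))
  g3 <- cellGroups(groupCells(segmentNuclei(odd, cfgDefault), cfgDefault,
                              computeMap = FALSE))
  expect_true(all(g3$class == "rejected"))
  # far-apart nuclei stay separate mono cells
  far <- drawImage(c(400L, 400L), list(disc(100, 100, 18),
                                       disc(300, 300, 18)))
  g4 <- cellGroups(groupCells(segmentNuclei(far, cfgDefault), cfgDefault,
                              computeMap = FALSE))
  expect_equal(sort(g4$class), c("mono", "mono"))
})

test_that("micronucleus detection applies area, shape and contact rules", {
  cfg <- cfgDefault
  # nucleus + 2 clear micronuclei -> 2 calls
  img <- drawImage(c(300L, 300L), list(disc(150, 150, 18),
                                       disc(150, 190, 3.2),
                                       disc(110, 150, 3.5)))
  nuc <- segmentNuclei(img, cfg)
  calls <- detectMicronuclei(img, nuc, cfg)
  expect_equal(nrow(calls), 2)
  # a spot touching the nucleus boundary is not called
  touching <- drawImage(c(300L, 300L), list(disc(150, 150, 18),
                                            disc(150, 150 + 18 + 2, 3)))
  nt <- segmentNuclei(touching, cfg)
  expect_equal(nrow(detectMicronuclei(touching, nt, cfg)), 0)
  # an elongated debris streak of micronucleus-like area is rejected
  streak <- drawImage(c(300L, 300L),
                      list(disc(60, 60, 18),
                           list(r = 200, c = 150, a = 24, b = 0.45,
                                value = 15000)))
  ns <- segmentNuclei(streak, cfg)
  st <- detectMicronuclei(streak, ns, cfg)
  expect_equal(nrow(st), 0)
})

test_that("parent assignment follows containment, proximity and class", {
  cfg <- cfgDefault
  img <- drawImage(c(400L, 400L),
                   list(disc(200, 100, 18),               # cell 1 (mono)
                        disc(200, 300, 18),               # cell 2 (mono)
                        disc(200, 130, 3.2),              # MN near cell 1
                        disc(200, 200, 3.2),              # MN equidistant
                        disc(60, 390, 3.2)))              # orphan MN
  nuc <- segmentNuclei(img, cfg)
  grp <- groupCells(nuc, cfg, computeMap = FALSE)
  calls <- detectMicronuclei(img, nuc, cfg)
  expect_equal(nrow(calls), 3)
  assigned <- assignMicronuclei(calls, grp, cfg)
  assigned <- assigned[order(assigned$centroid_col), ]
  expect_equal(assigned$parent_cell_id[1], 1L)         # containment
  expect_equal(assigned$parent_class[1], "mono")
  # equidistant between the two cells: 100 px from either centroid is
  # outside both 30 px expansions -> no parent; move the tie case closer
  expect_true(is.na(assigned$parent_cell_id[2]))
  expect_true(is.na(assigned$parent_cell_id[3]))       # orphan
  # true tie within reach: equidistant spot assigned to the lower cell id
  img2 <- drawImage(c(300L, 300L),
                    list(disc(150, 100, 18), disc(150, 190, 18),
                         disc(150, 145, 3.2)))
  nuc2 <- segmentNuclei(img2, cfg)
  grp2 <- groupCells(nuc2, cfg, computeMap = FALSE)
  a2 <- assignMicronuclei(detectMicronuclei(img2, nuc2, cfg), grp2, cfg)
  expect_equal(a2$parent_cell_id, 1L)
  # a micronucleus landing in a polynucleated cell's region has no parent
  img3 <- drawImage(c(400L, 400L),
                    list(disc(200, 160, 18), disc(200, 200, 18),
                         disc(234, 180, 18), disc(160, 200, 3.2)))
  nuc3 <- segmentNuclei(img3, cfg)
  grp3 <- groupCells(nuc3, cfg, computeMap = FALSE)
  expect_equal(cellGroups(grp3)$class, "poly")
  a3 <- assignMicronuclei(detectMicronuclei(img3, nuc3, cfg), grp3, cfg)
  expect_true(all(is.na(a3$parent_cell_id)))
})

test_that("field scoring counts classes and enforces integrity", {
  mk <- function(classes) {
    g <- data.frame(cell_id = seq_along(classes), class = classes,
                    n_nuclei = ifelse(classes == "mono", 1,
                                      ifelse(classes == "bi", 2, 3)),
                    centroid_row = rep(0, length(classes)),
                    centroid_col = rep(0, length(classes)))
    new("CellGroupSet", groups = g,
        membership = data.frame(label = integer(), cell_id = integer(),
                                centroid_row = numeric(),
                                centroid_col = numeric(), r_eq = numeric(),
                                area_px = numeric()),
        cellMap = matrix(0L, 1, 1), nucleusMap = matrix(0L, 1, 1))
  }
  noCalls <- data.frame(call_id = integer(), area_px = numeric(),
                        compactness = numeric(), centroid_row = numeric(),
                        centroid_col = numeric(),
                        parent_cell_id = integer(),
                        parent_class = character())
  sc <- scoreField(mk(c(rep("mono", 59), rep("bi", 41))), noCalls)
  expect_equal(c(sc$N1, sc$N2, sc$N3, sc$n_bi_with_mn), c(59, 41, 0, 0))
  expect_equal(sc$N1 + sc$N2 + sc$N3 + sc$n_rejected, sc$n_groups)
  # 1000 binucleated cells, 56 carrying micronuclei
  grp <- mk(rep("bi", 1000))
  calls <- data.frame(call_id = 1:56, area_px = 30, compactness = 1,
                      centroid_row = 0, centroid_col = 0,
                      parent_cell_id = 1:56, parent_class = "bi")
  sc2 <- scoreField(grp, calls)
  expect_equal(sc2$n_bi_with_mn, 56)
  expect_equal(100 * sc2$n_bi_with_mn / sc2$N2, 5.6)
  # empty field scores to zero
  sc3 <- scoreField(mk(character()), noCalls)
  expect_true(all(unlist(sc3) == 0))
  # unknown parent ids are an integrity error
  bad <- calls
  bad$parent_cell_id[1] <- 99999L
  expect_error(scoreField(mk(rep("bi", 10)), bad), "integrity")
})

test_that("pipeline output is deterministic and internally conserved", {
  p <- smallPresets[["MMC-0.025"]]
  fields <- lapply(1:2, function(s) generateField(p, smallShape, seed = s))
  r1 <- runMicroscopyPipeline(fields, cfgDefault)
  r2 <- runMicroscopyPipeline(fields, cfgDefault)
  expect_identical(r1$scores, r2$scores)
  expect_true(all(r1$scores$N1 + r1$scores$N2 + r1$scores$N3 +
                    r1$scores$n_rejected == r1$scores$n_groups))
})

test_that("recovered counts degrade gracefully with added noise", {
  p <- smallPresets[["NC"]]
  totals <- function(gaussSd) {
    p2 <- p
    p2@noiseGaussianSd <- gaussSd
    s <- runMicroscopyPipeline(
      lapply(1:4, function(k) generateField(p2, smallShape, seed = 400 + k)),
      cfgDefault)$scores
    c(sum(s$N1), sum(s$N2))
  }
  clean <- totals(0)
  noisy <- totals(0.03)
  expect_true(all(abs(noisy - clean) <= pmax(0.1 * clean, 2)))
})
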