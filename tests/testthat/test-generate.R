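test_that("field generation is deterministic and ground truth is coherent", {
  p <- smallPresets[["NC"]]
  f1 <- generateField(p, smallShape, seed = 42)
  f2 <- generateField(p, smallShape, seed = 42)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$truth, f2$truth)
  t <- f1$truth$totals
  expect_equal(t$N1 + t$N2 + t$N3, t$n_cells)
  cls <- f1$truth$cells$class
  expect_equal(sum(cls == "mono"), t$N1)
  # every micronucleus references an existing binucleated cell
  mn <- f1$truth$micronuclei
  if (nrow(mn)) {
    host <- f1$truth$cells$class[match(mn$cell_id, f1$truth$cells$cell_id)]
    expect_true(all(host == "bi"))
  }
  expect_true(all(f1$image >= 0 & f1$image <= 65535))
})

test_that("zero micronucleus rate yields zero micronuclei", {
  p <- smallPresets[["NC"]]
  p@mnProbBi <- 0
  for (s in 1:3) {
    f <- generateField(p, smallShape, seed = s)
    expect_equal(nrow(f$truth$micronuclei), 0)
    expect_equal(f$truth$totals$n_mn_in_bi, 0)
  }
})

test_that("sampled class mixture matches the preset within binomial error", {
  p <- smallPresets[["NC"]]
  n2 <- 0
  nTot <- 0
  mnPos <- 0
  nBi <- 0
  for (s in 1:10) {
    t <- generateField(p, smallShape, seed = 100 + s)$truth$totals
    n2 <- n2 + t$N2
    nTot <- nTot + t$n_cells
    mnPos <- mnPos + t$n_bi_with_mn
    nBi <- nBi + t$N2
  }
  fBi <- classFractions(p)[["bi"]]
  expect_lt(abs(n2 / nTot - fBi), 3 * sqrt(fBi * (1 - fBi) / nTot))
  pMN <- mnProbBi(p)
  expect_lt(abs(mnPos / nBi - pMN), 3 * sqrt(pMN * (1 - pMN) / nBi))
})

test_that("micronuclei never touch a nucleus (pixel-level disjointness)", {
  p <- smallPresets[["MMC-0.025"]]
  p@mnProbBi <- 1  # force micronuclei into every binucleated cell
  checked <- 0
  for (s in 1:4) {
    f <- generateField(p, smallShape, seed = 200 + s)
    mn <- f$truth$micronuclei
    nuc <- f$truth$nuclei
    for (k in seq_len(nrow(mn))) {
      mnIdx <- cbmnassay:::.ellipseIdx(mn$centroid_row[k], mn$centroid_col[k],
                                       mn$radius[k] + 1, mn$radius[k] + 1, 0,
                                       smallShape)
      for (j in seq_len(nrow(nuc))) {
        nucIdx <- cbmnassay:::.ellipseIdx(nuc$centroid_row[j],
                                          nuc$centroid_col[j],
                                          nuc$a[j], nuc$b[j], nuc$theta[j],
                                          smallShape)
        expect_length(intersect(mnIdx, nucIdx), 0)
      }
      checked <- checked + 1
    }
  }
  expect_gt(checked, 5)
})

test_that("infeasible packing is rejected explicitly", {
  p <- smallPresets[["NC"]]
  expect_error(generateField(p, c(500L, 500L), seed = 1, nCells = 200),
               "infeasible packing")
})

test_that("tile sets are deterministic, labelled, and constructive", {
  p <- smallPresets[["MMC-0.025"]]
  t1 <- generateTileSet(p, 40, seed = 5)
  t2 <- generateTileSet(p, 40, seed = 5)
  expect_identical(t1$tiles, t2$tiles)
  expect_identical(t1$labels, t2$labels)
  # no spoilers: every tile is a mono/bi/poly cell tile
  t3 <- generateTileSet(p, 60, seed = 6,
                        spoilers = c(oof = 0, doublet = 0, debris = 0))
  expect_true(all(t3$labels$category %in% c("mono", "bi", "poly", "bi_mn")))
  # a bi + 1 MN tile carries exactly 3 bright components in the DNA channel
  p1 <- p
  p1@mnProbBi <- 1
  p1@mnCountDist <- c(1, 0, 0)
  t4 <- generateTileSet(p1, 30, seed = 7, noiseFree = TRUE,
                        spoilers = c(oof = 0, doublet = 0, debris = 0))
  k <- which(t4$labels$category == "bi_mn")[1]
  expect_false(is.na(k))
  comp <- EBImage::bwlabel(t4$tiles[[k]]$dna > 6000)
  areas <- tabulate(as.integer(comp), max(comp))
  # the micronucleus is a separate small bright component, apart from the
  # nuclear body (the touching binucleate pair may form one component)
  expect_equal(sum(areas < 200), 1)
  expect_gte(max(comp), 2)
})

test_that("viability tables follow the 4PL law and the seed", {
  conc <- 9.375 * 2^(0:6)
  tab <- generateViabilityTable(228, 1.5, 100, 0, conc, 3, 0, seed = 1)
  expect_equal(nrow(tab), 21)
  # noiseless value at c = IC50 equals the 4PL midpoint (50%)
  mid <- generateViabilityTable(228, 1.5, 100, 0, c(conc, 228), 1, 0,
                                seed = 1)
  expect_equal(mid$viability[mid$concentration == 228], 50)
  # low-dose limit approaches the top plateau
  lowc <- generateViabilityTable(228, 1.5, 100, 0, 0.001, 1, 0, seed = 1)
  expect_equal(lowc$viability, 100, tolerance = 1e-4)
  t1 <- generateViabilityTable(228, 1.5, 100, 0, conc, 3, 5, seed = 9)
  t2 <- generateViabilityTable(228, 1.5, 100, 0, conc, 3, 5, seed = 9)
  expect_identical(t1, t2)
  expect_true(all(t1$viability >= 0))
  expect_error(generateViabilityTable(228, 1.5, 100, 0, c(-1, 10), 3, 0,
                                      seed = 1),
               "positive")
})
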