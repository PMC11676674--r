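# Synthetic widefield field generator.
#
# A field is drawn as ellipses on a 16-bit-like intensity scale (background
# 300, nuclei 12000-20000), Gaussian-blurred as a point-spread proxy, then
# degraded with Poisson shot noise and Gaussian read noise. Ground truth
# records exactly what was drawn.

# Poisson-disc sampling (Bridson's algorithm): returns a near-maximal set of
# points with pairwise distance >= minDist inside the margin-inset rectangle.
.poissonDisc <- function(shape, minDist, margin, k = 30L) {
  lo <- c(margin, margin)
  hi <- c(shape[1] - margin, shape[2] - margin)
  if (any(hi <= lo)) stop("field shape too small for the placement margin")
  cs <- minDist / sqrt(2)
  gdim <- ceiling((hi - lo) / cs)
  grid <- matrix(0L, gdim[1], gdim[2])
  pts <- matrix(NA_real_, prod(gdim), 2)
  npts <- 0L
  gIndex <- function(p) pmin(pmax(floor((p - lo) / cs) + 1, 1), gdim)
  farEnough <- function(p) {
    g <- gIndex(p)
    r1 <- max(1, g[1] - 2):min(gdim[1], g[1] + 2)
    r2 <- max(1, g[2] - 2):min(gdim[2], g[2] + 2)
    ids <- grid[r1, r2]
    ids <- ids[ids > 0]
    if (!length(ids)) return(TRUE)
    d2 <- (pts[ids, 1] - p[1])^2 + (pts[ids, 2] - p[2])^2
    all(d2 >= minDist^2)
  }
  push <- function(p) {
    npts <<- npts + 1L
    pts[npts, ] <<- p
    g <- gIndex(p)
    grid[g[1], g[2]] <<- npts
    npts
  }
  active <- c(push(lo + stats::runif(2) * (hi - lo)))
  while (length(active)) {
    i <- active[length(active)]
    placed <- FALSE
    ang <- stats::runif(k, 0, 2 * pi)
    rad <- minDist * sqrt(stats::runif(k, 1, 4))
    for (j in seq_len(k)) {
      p <- pts[i, ] + rad[j] * c(cos(ang[j]), sin(ang[j]))
      if (any(p < lo) || any(p > hi)) next
      if (farEnough(p)) {
        active <- c(active, push(p))
        placed <- TRUE
        break
      }
    }
    if (!placed) active <- active[-length(active)]
  }
  pts[seq_len(npts), , drop = FALSE]
}

# Pixel indices (into a shape[1] x shape[2] matrix) inside an ellipse.
# 0-based centre coordinates (row, col); semi-axes a >= b; orientation theta.
.ellipseIdx <- function(cr, cc, a, b, theta, shape) {
  rr <- max(0, floor(cr - a)):min(shape[1] - 1, ceiling(cr + a))
  cc2 <- max(0, floor(cc - a)):min(shape[2] - 1, ceiling(cc + a))
  if (!length(rr) || !length(cc2)) return(integer())
  dr <- rep(rr - cr, times = length(cc2))
  dc <- rep(cc2 - cc, each = length(rr))
  ct <- cos(theta); st <- sin(theta)
  u <- dr * ct + dc * st
  v <- -dr * st + dc * ct
  inside <- (u / a)^2 + (v / b)^2 <= 1
  row <- rep(rr, times = length(cc2))[inside]
  col <- rep(cc2, each = length(rr))[inside]
  row + 1L + shape[1] * col  # column-major linear index, 1-based
}

# Sample the cell layout of one field: classes, nucleus ellipses, MN records.
.sampleLayout <- function(preset, anchors, nCells) {
  rMean <- preset@nucleusRadiusPx[1]
  rSd <- preset@nucleusRadiusPx[2]
  mnR <- preset@mnRadiusRatio * rMean
  classes <- sample(c("mono", "bi", "poly"), nCells, replace = TRUE,
                    prob = preset@classFractions)
  nuclei <- vector("list", nCells)
  mn <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    anc <- anchors[i, ]
    nn <- switch(classes[i], mono = 1L, bi = 2L, poly = 3L)
    r0 <- clamp(stats::rnorm(1, rMean, rSd), rMean - 2.5, rMean + 2.5)
    rs <- r0 * stats::runif(nn, 0.95, 1.05)  # near-equal members
    if (nn == 1L) {
      ctr <- matrix(anc, 1)
    } else if (nn == 2L) {
      sep <- stats::runif(1, 1.6, 2.1) * mean(rs)
      th <- stats::runif(1, 0, pi)
      u <- c(cos(th), sin(th))
      ctr <- rbind(anc + u * sep / 2, anc - u * sep / 2)
    } else {
      th0 <- stats::runif(1, 0, 2 * pi)
      ths <- th0 + c(0, 2 * pi / 3, 4 * pi / 3) +
        stats::runif(3, -0.2, 0.2)
      d0 <- stats::runif(1, 1.2, 1.35) * mean(rs)
      ctr <- cbind(anc[1] + d0 * cos(ths), anc[2] + d0 * sin(ths))
    }
    ax <- stats::runif(nn, 1.0, 1.3)       # ellipse axis ratio
    aAx <- rs * sqrt(ax)                   # semi-major axes
    nuclei[[i]] <- data.frame(
      cell_id = i, nucleus = seq_len(nn),
      centroid_row = ctr[, 1], centroid_col = ctr[, 2],
      a = aAx, b = rs / sqrt(ax),
      theta = stats::runif(nn, 0, pi))
    # micronuclei: binucleated cells only, per the assay's scoring restriction
    if (classes[i] == "bi" && stats::runif(1) < preset@mnProbBi) {
      kMN <- sample(1:3, 1, prob = preset@mnCountDist)
      recs <- list()
      for (m in seq_len(kMN)) {
        host <- sample(1:2, 1)
        ok <- FALSE
        for (try in 1:60) {
          dist <- stats::runif(1, 1.5, 1.9) * rMean
          thm <- stats::runif(1, 0, 2 * pi)
          pm <- c(ctr[host, 1] + dist * cos(thm),
                  ctr[host, 2] + dist * sin(thm))
          dAll <- sqrt((pm[1] - ctr[, 1])^2 + (pm[2] - ctr[, 2])^2)
          # clearance against the semi-major axis: never touch a nucleus
          clearN <- all(dAll >= aAx + mnR + 4)
          clearM <- TRUE
          if (length(recs)) {
            prev <- do.call(rbind, recs)
            clearM <- all(sqrt((pm[1] - prev$centroid_row)^2 +
                               (pm[2] - prev$centroid_col)^2) > 2 * mnR + 2)
          }
          if (clearN && clearM) { ok <- TRUE; break }
        }
        if (ok)
          recs[[length(recs) + 1L]] <- data.frame(
            cell_id = i, centroid_row = pm[1], centroid_col = pm[2],
            radius = mnR * stats::runif(1, 0.85, 1.15))
      }
      if (length(recs)) mn[[i]] <- do.call(rbind, recs)
    }
  }
  list(classes = classes,
       nuclei = do.call(rbind, nuclei),
       mn = if (any(!vapply(mn, is.null, TRUE))) do.call(rbind, mn) else
         data.frame(cell_id = integer(), centroid_row = numeric(),
                    centroid_col = numeric(), radius = numeric()))
}

# Render the clean (noise-free, unblurred) intensity image and per-object
# drawn pixel areas.
.renderLayout <- function(layout, shape, background = 300) {
  img <- matrix(background, shape[1], shape[2])
  nuc <- layout$nuclei
  nucArea <- numeric(nrow(nuc))
  cellInt <- stats::runif(max(nuc$cell_id), 12000, 20000)
  for (i in seq_len(nrow(nuc))) {
    idx <- .ellipseIdx(nuc$centroid_row[i], nuc$centroid_col[i],
                       nuc$a[i], nuc$b[i], nuc$theta[i], shape)
    img[idx] <- cellInt[nuc$cell_id[i]]
    nucArea[i] <- length(idx)
  }
  mn <- layout$mn
  mnArea <- numeric(nrow(mn))
  for (i in seq_len(nrow(mn))) {
    idx <- .ellipseIdx(mn$centroid_row[i], mn$centroid_col[i],
                       mn$radius[i], mn$radius[i], 0, shape)
    # condensed micronucleus chromatin stains densely: top of the range
    img[idx] <- stats::runif(1, 18000, 20000)
    mnArea[i] <- length(idx)
  }
  list(img = img, nucArea = nucArea, mnArea = mnArea)
}

# Optical blur + shot/read noise.
.degradeImage <- function(img, blurSigma, poissonScale, gaussianSd) {
  if (blurSigma > 0) img <- .gaussBlurC(img, blurSigma)
  .shotNoiseC(img, poissonScale, gaussianSd * .DYNAMIC_RANGE, .DYNAMIC_RANGE)
}

#' Generate one synthetic widefield field with ground truth
#'
#' Draws cells at Poisson-disc-sampled anchors: mononucleated cells as one
#' ellipse, binucleated as two near-equal, touching-but-distinct ellipses separated
#' by 1.6-2.1 nucleus radii, polynucleated as three ellipses; micronuclei as small discs
#' placed 1.5-1.9 nucleus radii from their host nucleus centroid (within the
#' assay's 1.5-3-radius convention), never touching any nucleus. The clean
#' image is then Gaussian-blurred and degraded with Poisson and Gaussian
#' noise. Deterministic given `(preset, shape, seed)`.
#'
#' @param preset a [ConditionPreset-class].
#' @param shape `c(rows, cols)` in pixels (default 1800 x 1800).
#' @param seed integer seed.
#' @param nCells optional override of the realised cell count; by default
#'   `round(nCellsTarget * survivalFraction)`.
#' @param noiseFree if `TRUE`, skip blur and noise (ideal image).
#' @return a list with elements `image` (numeric matrix, intensities in
#'   `[0, 65535]`) and `truth`, a `FieldGroundTruth` list carrying `cells`,
#'   `nuclei` and `micronuclei` data frames plus per-field `totals`
#'   (`N1`, `N2`, `N3`, `n_cells`, `n_bi_with_mn`, `n_mn_in_bi`).
#' @export
generateField <- function(preset, shape = c(1800L, 1800L), seed,
                          nCells = NULL, noiseFree = FALSE) {
  stopIfNot(is(preset, "ConditionPreset"), "preset must be a ConditionPreset")
  shape <- as.integer(shape)
  if (is.null(nCells))
    nCells <- max(1L, as.integer(round(preset@nCellsTarget *
                                         preset@survivalFraction)))
  rMean <- preset@nucleusRadiusPx[1]
  minDist <- 7.2 * rMean
  margin <- ceiling(3.4 * rMean)
  withLocalSeed(seed, {
    anchors <- .poissonDisc(shape, minDist, margin)
    if (nrow(anchors) < nCells)
      stop(sprintf(
        "infeasible packing: %d cells requested but only %d anchors fit a %dx%d field",
        nCells, nrow(anchors), shape[1], shape[2]))
    anchors <- anchors[sample.int(nrow(anchors), nCells), , drop = FALSE]
    layout <- .sampleLayout(preset, anchors, nCells)
    rend <- .renderLayout(layout, shape)
    img <- if (noiseFree) rend$img else
      .degradeImage(rend$img, preset@blurSigmaPx, preset@noisePoissonScale,
                    preset@noiseGaussianSd)
    nuc <- layout$nuclei
    nuc$area_px <- rend$nucArea
    mn <- layout$mn
    if (nrow(mn)) mn$area_px <- rend$mnArea
    mnPerCell <- table(factor(mn$cell_id, levels = seq_len(nCells)))
    cells <- data.frame(
      cell_id = seq_len(nCells), class = layout$classes,
      anchor_row = anchors[, 1], anchor_col = anchors[, 2],
      mn_count = as.integer(mnPerCell))
    totals <- list(
      N1 = sum(layout$classes == "mono"),
      N2 = sum(layout$classes == "bi"),
      N3 = sum(layout$classes == "poly"),
      n_cells = nCells,
      n_bi_with_mn = sum(cells$mn_count > 0 & cells$class == "bi"),
      n_mn_in_bi = nrow(mn))
    truth <- structure(
      list(cells = cells,
           nuclei = nuc[, c("cell_id", "nucleus", "centroid_row",
                            "centroid_col", "a", "b", "theta", "area_px")],
           micronuclei = mn, totals = totals),
      class = "FieldGroundTruth")
    list(image = img, truth = truth)
  })
}

#' @export
print.FieldGroundTruth <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "FieldGroundTruth: %d cells (N1=%d, N2=%d, N3=%d); %d MN in %d binucleated cells\n",
    t$n_cells, t$N1, t$N2, t$N3, t$n_mn_in_bi, t$n_bi_with_mn))
  invisible(x)
}
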