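# Imaging-flow-cytometry-style analysis: morphological mask algebra,
# per-tile features, the sequential gate chain to the binucleated-cell (BNC)
# population, and the micronucleus spot-count readout.

#' Flow-route mask/feature configuration
#'
#' @param expectedNucleusArea expected nucleus area in px.
#' @param nucAreaMin minimum component area for the nuclear mask.
#' @param mnAreaMin,mnAreaMax micronucleus spot area window (px).
#' @param mnCompactnessMax maximum spot compactness.
#' @param topHatRadius structuring-element radius of the white top-hat spot
#'   filter (about one micronucleus radius).
#' @param spotThreshold absolute top-hat threshold as a fraction of the
#'   dynamic range.
#' @param dilateRadius dilation radius used both for the dilate mask and for
#'   the NOT-nuclear exclusion zone.
#' @param levelsetGrow radius of the region-growing neighbourhood refining
#'   the nuclear boundary.
#' @param preSmoothSigma denoising (3x3 median + Gaussian) applied to both
#'   channels before masks and features.
#' @param lobeSmoothSigma Gaussian sigma before lobe (local-maximum)
#'   counting (about half a nucleus radius, so each nucleus carries one
#'   dome).
#' @param lobeMergeDist maxima closer than this merge into one lobe (about
#'   one micronucleus diameter).
#' @return list of class `FlowConfig`.
#' @export
flowConfig <- function(expectedNucleusArea = pi * 18^2,
                       nucAreaMin = 0.3 * expectedNucleusArea,
                       mnAreaMin = expectedNucleusArea / 300,
                       mnAreaMax = expectedNucleusArea / 9,
                       mnCompactnessMax = 1.6,
                       topHatRadius = 6, spotThreshold = 0.05,
                       dilateRadius = 3, levelsetGrow = 4,
                       preSmoothSigma = 1.0,
                       lobeSmoothSigma = 7,
                       lobeMergeDist = 7) {
  cfg <- list(expectedNucleusArea = expectedNucleusArea,
              nucAreaMin = nucAreaMin, mnAreaMin = mnAreaMin,
              mnAreaMax = mnAreaMax, mnCompactnessMax = mnCompactnessMax,
              topHatRadius = topHatRadius, spotThreshold = spotThreshold,
              dilateRadius = dilateRadius, levelsetGrow = levelsetGrow,
              preSmoothSigma = preSmoothSigma,
              lobeSmoothSigma = lobeSmoothSigma, lobeMergeDist = lobeMergeDist)
  class(cfg) <- "FlowConfig"
  cfg
}

.discBrush <- function(r) EBImage::makeBrush(2 * as.integer(r) + 1, "disc")

# channel denoising shared by masks and features (median + light Gaussian)
.prepTile <- function(tile, cfg) {
  if (is.null(cfg$preSmoothSigma) || cfg$preSmoothSigma <= 0) return(tile)
  list(bf = .gaussBlurC(.median3C(tile$bf), cfg$preSmoothSigma),
       dna = .gaussBlurC(.median3C(tile$dna), cfg$preSmoothSigma))
}

#' Build the morphological mask set for one tile
#'
#' Mirrors the instrument-software mask functions combined by Boolean logic:
#' `threshold` (DNA >= Otsu), `dilate` (its dilation), `spot` (white top-hat
#' of the DNA channel, thresholded), `range` (spot components within the
#' micronucleus area window), `levelset` (intensity region growing refining
#' the nuclear boundary), `nuclear` (the refined large components), and
#' `micronuclei` composed as `range AND NOT dilate(nuclear)` so a spot
#' adjacent to a nucleus is excluded by construction.
#'
#' @param tile a `list(bf=, dna=)` two-channel tile.
#' @param cfg a [flowConfig()].
#' @param prepped set when `tile` was already denoised by the caller.
#' @return a [MaskSet-class].
#' @export
buildMasks <- function(tile, cfg = flowConfig(), prepped = FALSE) {
  stopIfNot(is.matrix(tile$dna), "tile must carry a 'dna' channel matrix")
  dna <- if (prepped) tile$dna else .prepTile(tile, cfg)$dna
  d <- dim(dna)
  blank <- matrix(FALSE, d[1], d[2])
  x <- dna / .DYNAMIC_RANGE
  if (diff(range(x)) < 1e-6) {
    masks <- list(threshold = blank, dilate = blank, spot = blank,
                  range = blank, levelset = blank, nuclear = blank,
                  micronuclei = blank)
    return(new("MaskSet", masks = masks))
  }
  thr <- .otsuThreshold(x)
  threshold <- x > thr
  dil <- matrix(as.logical(
    EBImage::dilate(threshold, .discBrush(cfg$dilateRadius))), d[1], d[2])
  lab <- matrix(as.integer(EBImage::bwlabel(threshold)), d[1], d[2])
  areas <- if (max(lab) > 0) tabulate(lab, max(lab)) else integer()
  bigIds <- which(areas >= cfg$nucAreaMin)
  seed <- matrix(lab %in% bigIds & lab > 0, d[1], d[2])
  # level-set stand-in: intensity region growing around the seed components
  if (any(seed)) {
    lvl <- 0.6 * stats::median(x[seed])
    grow <- matrix(as.logical(
      EBImage::dilate(seed, .discBrush(cfg$levelsetGrow))), d[1], d[2])
    levelset <- grow & (x >= lvl)
    nuclear <- matrix(as.logical(EBImage::fillHull(levelset | seed)),
                      d[1], d[2])
  } else {
    levelset <- blank
    nuclear <- blank
  }
  th <- matrix(as.numeric(
    EBImage::whiteTopHat(EBImage::Image(x), .discBrush(cfg$topHatRadius))),
    d[1], d[2])
  spot <- th > cfg$spotThreshold
  slab <- matrix(as.integer(EBImage::bwlabel(spot)), d[1], d[2])
  sareas <- if (max(slab) > 0) tabulate(slab, max(slab)) else integer()
  keep <- which(sareas >= cfg$mnAreaMin & sareas <= cfg$mnAreaMax)
  rng <- matrix(slab %in% keep & slab > 0, d[1], d[2])
  excl <- matrix(as.logical(
    EBImage::dilate(nuclear, .discBrush(cfg$dilateRadius))), d[1], d[2])
  micronuclei <- rng & !excl
  new("MaskSet", masks = list(threshold = threshold, dilate = dil,
                              spot = spot, range = rng, levelset = levelset,
                              nuclear = nuclear, micronuclei = micronuclei))
}

# aspect ratio (minor/major, in (0,1]) from pixel or weighted coordinates
.aspectRatio <- function(rows, cols, w = NULL) {
  if (length(rows) < 3) return(1)
  if (is.null(w)) w <- rep(1, length(rows))
  W <- sum(w)
  cr <- sum(w * rows) / W
  cc <- sum(w * cols) / W
  mrr <- sum(w * (rows - cr)^2) / W
  mcc <- sum(w * (cols - cc)^2) / W
  mrc <- sum(w * (rows - cr) * (cols - cc)) / W
  half <- (mrr + mcc) / 2
  dd <- sqrt(((mrr - mcc) / 2)^2 + mrc^2)
  l1 <- half + dd
  l2 <- max(half - dd, 0)
  if (l1 <= 0) return(1)
  sqrt(l2 / l1)
}

# minor-axis extent of the moment-aligned bounding box
.minorExtent <- function(rows, cols) {
  if (length(rows) < 2) return(length(rows))
  cr <- mean(rows); cc <- mean(cols)
  mrr <- mean((rows - cr)^2); mcc <- mean((cols - cc)^2)
  mrc <- mean((rows - cr) * (cols - cc))
  th <- 0.5 * atan2(2 * mrc, mrr - mcc)  # major-axis angle
  # projection onto the minor axis
  proj <- -(rows - cr) * sin(th) + (cols - cc) * cos(th)
  proj2 <- (rows - cr) * cos(th) + (cols - cc) * sin(th)
  min(diff(range(proj)), diff(range(proj2))) + 1
}

#' Compute the per-tile feature vector
#'
#' Features follow open definitions of the classical imaging-flow gating
#' parameters: `gradient_rms` is the RMS Sobel gradient of the brightfield
#' channel normalised by its mean (focus); `bf_aspect_ratio` is minor/major
#' of the thresholded BF object (singlet discrimination); `dna_area` and
#' `dna_intensity` are the nuclear mask area and integrated DNA signal;
#' `lobe_count` counts merged local maxima of the smoothed DNA channel
#' within the nuclear mask (2 = binucleated); `homogeneity_mean` is the mean
#' gray-level co-occurrence homogeneity (inverse difference moment; 8 gray
#' levels, distance 1, 4 directions averaged) of the DNA channel over the
#' nuclear mask; `dna_width` is the minor-axis extent of the moment-aligned
#' nuclear bounding box; `dna_aspect_ratio_intensity` uses intensity-weighted
#' moments; `dna_compactness` is perimeter^2/(4 pi area) of the nuclear
#' mask; `mn_spot_count` counts micronucleus-mask components passing the
#' area/compactness spot rules.
#'
#' An empty nuclear mask yields `valid = FALSE` and zeroed features; such
#' tiles fail every gate.
#'
#' @param tile a `list(bf=, dna=)` tile.
#' @param masks the tile's [MaskSet-class] from [buildMasks()].
#' @param cfg a [flowConfig()].
#' @param prepped set when `tile` was already denoised by the caller.
#' @return one-row `data.frame` of features.
#' @export
computeTileFeatures <- function(tile, masks, cfg = flowConfig(),
                                prepped = FALSE) {
  if (!prepped) tile <- .prepTile(tile, cfg)
  bf <- tile$bf
  dna <- tile$dna
  nuclear <- getMask(masks, "nuclear")
  gradientRms <- .sobelRmsC(bf) / max(mean(bf), 1)
  out <- data.frame(gradient_rms = gradientRms, bf_aspect_ratio = 0,
                    dna_area = 0, dna_intensity = 0, lobe_count = 0L,
                    homogeneity_mean = 0, dna_width = 0,
                    dna_aspect_ratio_intensity = 0, dna_compactness = Inf,
                    mn_spot_count = 0L, valid = FALSE)
  xbf <- bf / .DYNAMIC_RANGE
  if (diff(range(xbf)) > 1e-6) {
    bmask <- xbf > .otsuThreshold(xbf)
    if (sum(bmask) >= 3) {
      bi <- which(bmask)
      out$bf_aspect_ratio <- .aspectRatio((bi - 1) %% nrow(bf),
                                          (bi - 1) %/% nrow(bf))
    }
  }
  if (!any(nuclear)) return(out)
  ni <- which(nuclear)
  nr <- nrow(dna)
  rows <- (ni - 1) %% nr
  cols <- (ni - 1) %/% nr
  out$valid <- TRUE
  out$dna_area <- length(ni)
  out$dna_intensity <- sum(dna[ni])
  out$dna_width <- .minorExtent(rows, cols)
  w <- pmax(dna[ni] - 300, 0)
  out$dna_aspect_ratio_intensity <- .aspectRatio(rows, cols, w + 1e-9)
  # compactness of the nuclear mask (per-object boundary-count perimeter)
  lab1 <- matrix(0L, nrow(nuclear), ncol(nuclear))
  lab1[nuclear] <- 1L
  mm <- .measureObjects(lab1, dna)
  out$dna_compactness <- mm$perimeter_px[1]^2 / (4 * pi * mm$area_px[1])
  # homogeneity: Haralick inverse difference moment on 8 gray levels
  har <- tryCatch(
    EBImage::computeFeatures.haralick(lab1, dna / .DYNAMIC_RANGE,
                                      haralick.nbins = 8,
                                      haralick.scales = 1),
    error = function(e) NULL)
  if (!is.null(har) && "h.idm.s1" %in% colnames(har))
    out$homogeneity_mean <- unname(har[1, "h.idm.s1"])
  # lobe count: merged local maxima of the smoothed DNA within the mask
  sm <- .gaussBlurC(dna, cfg$lobeSmoothSigma)
  mx <- .maxFilter3(sm)
  peak <- which(nuclear & sm >= mx - 1e-9 & sm > 0.5 * max(sm[ni]))
  if (length(peak)) {
    pr <- (peak - 1) %% nr
    pc <- (peak - 1) %/% nr
    o <- order(-sm[peak])
    keepR <- numeric(0)
    keepC <- numeric(0)
    for (k in o) {
      if (!length(keepR) ||
          all((keepR - pr[k])^2 + (keepC - pc[k])^2 >
                cfg$lobeMergeDist^2)) {
        keepR <- c(keepR, pr[k])
        keepC <- c(keepC, pc[k])
      }
    }
    out$lobe_count <- length(keepR)
  }
  # micronucleus spots passing the area/compactness rules
  mnMask <- getMask(masks, "micronuclei")
  if (any(mnMask)) {
    ml <- matrix(as.integer(EBImage::bwlabel(mnMask)), nrow(mnMask),
                 ncol(mnMask))
    sm2 <- .measureObjects(ml, dna)
    out$mn_spot_count <- sum(sm2$area_px >= cfg$mnAreaMin &
                               sm2$area_px <= cfg$mnAreaMax &
                               sm2$compactness <= cfg$mnCompactnessMax)
  }
  out
}

# 3x3 maximum filter via shifted comparisons
.maxFilter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs - dr, cs - dc] <- m[rs, cs]
    out
  }
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- pmax(out, sh(dr, dc))
  out
}

#' Score a set of tiles: masks + features
#'
#' Convenience driver: builds masks and computes features for each tile.
#'
#' @param tileSet result of [generateTileSet()] (or a list of tiles).
#' @param cfg a [flowConfig()].
#' @return `data.frame` with one feature row per tile (column `tile` first).
#' @export
scoreTiles <- function(tileSet, cfg = flowConfig()) {
  tiles <- if (!is.null(tileSet$tiles)) tileSet$tiles else tileSet
  rows <- vector("list", length(tiles))
  for (i in seq_along(tiles)) {
    prepped <- .prepTile(tiles[[i]], cfg)
    masks <- buildMasks(prepped, cfg, prepped = TRUE)
    rows[[i]] <- cbind(tile = i,
                       computeTileFeatures(prepped, masks, cfg,
                                           prepped = TRUE))
  }
  do.call(rbind, rows)
}

#' Apply the sequential BNC gate chain
#'
#' Gates are applied in the published order: focus (gradient RMS), lobe
#' count, single-cell brightfield aspect ratio, DNA area window, texture
#' (homogeneity and width), and the final aspect-ratio-intensity /
#' compactness box. Survivors form the binucleated-cell (BNC) population,
#' whose micronucleus spot counts are histogrammed into 0/1/2/3 bins (counts
#' above 3 are truncated to 3 with a warning). Population sizes are
#' non-increasing along the chain by construction.
#'
#' @param features feature table from [scoreTiles()].
#' @param cfg a [gateConfig()].
#' @return object of class `PopulationResult`: list with `gates`
#'   (`data.frame` of per-gate retained counts), `bnc_tiles` (tile ids),
#'   `mn_hist` (named counts for 0-3 micronuclei), and `mn_freq_pct`
#'   (normalized frequency: % of BNC with >= 1 micronucleus).
#' @export
applyGates <- function(features, cfg = gateConfig()) {
  f <- features
  steps <- list(
    focus = function(d) d$gradient_rms >= cfg@focusMin & d$valid,
    lobes = function(d) d$lobe_count == cfg@lobeCountRequired,
    singlets = function(d) d$bf_aspect_ratio > cfg@bfAspectRatioMin,
    dna_area = function(d) d$dna_area >= cfg@dnaAreaRange[1] &
      d$dna_area <= cfg@dnaAreaRange[2],
    texture = function(d) d$homogeneity_mean > cfg@homogeneityMin &
      d$dna_width > cfg@widthMin,
    bnc = function(d) d$dna_compactness <= cfg@compactnessMax &
      d$dna_aspect_ratio_intensity >= cfg@aspectRatioIntensityRange[1] &
      d$dna_aspect_ratio_intensity <= cfg@aspectRatioIntensityRange[2]
  )
  keep <- rep(TRUE, nrow(f))
  gates <- data.frame(gate = c("all", names(steps)),
                      retained = NA_integer_)
  gates$retained[1] <- nrow(f)
  for (k in seq_along(steps)) {
    if (nrow(f)) keep <- keep & steps[[k]](f)
    gates$retained[k + 1] <- sum(keep)
  }
  bnc <- f[keep, , drop = FALSE]
  counts <- bnc$mn_spot_count
  if (length(counts) && any(counts > 3)) {
    warning(sum(counts > 3), " BNC with > 3 spots truncated to 3")
    counts <- pmin(counts, 3L)
  }
  hist <- vapply(0:3, function(k) sum(counts == k), 0L)
  names(hist) <- as.character(0:3)
  res <- list(gates = gates,
              bnc_tiles = if ("tile" %in% names(bnc)) bnc$tile else
                which(keep),
              mn_hist = hist,
              mn_freq_pct = if (sum(hist) > 0)
                100 * sum(hist[-1]) / sum(hist) else NA_real_)
  class(res) <- "PopulationResult"
  res
}

#' @export
print.PopulationResult <- function(x, ...) {
  cat("PopulationResult:\n")
  for (i in seq_len(nrow(x$gates)))
    cat(sprintf("  %-9s %6d\n", x$gates$gate[i], x$gates$retained[i]))
  cat("  MN histogram (0/1/2/3):", paste(x$mn_hist, collapse = "/"), "\n")
  cat(sprintf("  normalized MN frequency: %.2f%%\n", x$mn_freq_pct))
  invisible(x)
}

#' Calibrate gate thresholds on labelled tiles
#'
#' Coordinate-wise grid search over candidate thresholds (feature quantiles)
#' maximising the balanced accuracy of BNC identification against the truth
#' labels, run for two passes; deterministic given its inputs.
#'
#' @param features feature table from [scoreTiles()].
#' @param isBnc logical truth: which tiles a perfect gate accepts.
#' @param cfg0 starting [gateConfig()].
#' @return list with `config` (the calibrated [GateConfig-class]),
#'   `balanced_accuracy`, and `report` (per-parameter chosen values).
#' @export
calibrateGates <- function(features, isBnc, cfg0 = gateConfig()) {
  stopIfNot(length(unique(isBnc)) == 2,
            "calibration needs both BNC and non-BNC tiles")
  ba <- function(cfg) {
    pred <- logical(nrow(features))
    res <- applyGates(features, cfg)
    pred[features$tile %in% res$bnc_tiles] <- TRUE
    sens <- sum(pred & isBnc) / max(sum(isBnc), 1)
    spec <- sum(!pred & !isBnc) / max(sum(!isBnc), 1)
    (sens + spec) / 2
  }
  qs <- function(v, probs) unique(stats::quantile(v[is.finite(v)], probs,
                                                  names = FALSE))
  cfg <- cfg0
  best <- ba(cfg)
  probs <- seq(0.02, 0.98, by = 0.08)
  for (pass in 1:2) {
    for (par in c("focusMin", "bfAspectRatioMin", "homogeneityMin",
                  "widthMin", "compactnessMax")) {
      cands <- switch(par,
        focusMin = qs(features$gradient_rms, probs),
        bfAspectRatioMin = qs(features$bf_aspect_ratio, probs),
        homogeneityMin = qs(features$homogeneity_mean, probs),
        widthMin = qs(features$dna_width, probs),
        compactnessMax = qs(features$dna_compactness, probs))
      for (v in cands) {
        trial <- cfg
        slot(trial, par) <- v
        sc <- ba(trial)
        if (sc > best + 1e-12) {
          best <- sc
          cfg <- trial
        }
      }
    }
    # DNA area window from candidate quantile pairs
    lo <- qs(features$dna_area, seq(0.02, 0.5, by = 0.08))
    hi <- qs(features$dna_area, seq(0.5, 0.98, by = 0.08))
    for (a in lo) for (b in hi) {
      if (b <= a) next
      trial <- cfg
      trial@dnaAreaRange <- c(a, b)
      sc <- ba(trial)
      if (sc > best + 1e-12) {
        best <- sc
        cfg <- trial
      }
    }
  }
  report <- data.frame(
    parameter = c("focusMin", "bfAspectRatioMin", "homogeneityMin",
                  "widthMin", "compactnessMax", "dnaAreaMin", "dnaAreaMax"),
    value = c(cfg@focusMin, cfg@bfAspectRatioMin, cfg@homogeneityMin,
              cfg@widthMin, cfg@compactnessMax, cfg@dnaAreaRange))
  list(config = cfg, balanced_accuracy = best, report = report)
}
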