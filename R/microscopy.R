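# Widefield scoring pipeline: preprocess -> segment nuclei -> group into
# cells -> detect micronuclei -> assign parents -> score.
#
# Mirrors the classical three-block CellProfiler-style design: nuclei as
# primary objects (with watershed declumping and area/shape filtering), cells
# as secondary objects by fixed-distance expansion of the nuclei, cytoplasm as
# the doughnut-shaped difference, then micronucleus recognition by area and
# compactness with parent assignment to mono- or binucleated cells.

#' Microscopy pipeline configuration
#'
#' All area and shape criteria of the scoring pipeline. The criteria
#' themselves (area, compactness, eccentricity, expansion distance) follow
#' the standard automated-CBMN design; the numeric defaults were calibrated
#' once on this package's synthetic fixtures and frozen.
#'
#' @param expectedNucleusArea expected nucleus area in px (default: a disc of
#'   radius 18).
#' @param cropBorder pixels to crop from each edge before analysis.
#' @param smoothSigma Gaussian smoothing sigma in px.
#' @param medianRadius radius of the median noise-reduction filter (1 = 3x3;
#'   0 disables).
#' @param areaMin,areaMax nucleus area bounds (defaults 0.3x and 3x the
#'   expected area).
#' @param eccMax maximum nucleus eccentricity.
#' @param mnAreaMin,mnAreaMax micronucleus area bounds (defaults 1/300 and
#'   1/9 of the expected nucleus area: the floor admits the few-pixel caps
#'   that small blurred micronuclei leave above the global threshold, which
#'   background noise cannot reach).
#' @param mnCompactnessMax maximum micronucleus compactness.
#' @param expandDist cell-expansion distance in px (secondary objects).
#' @param groupDistFactor grouping cut: centroid distance <= this factor
#'   times the mean equivalent radius.
#' @param areaRatioMax maximum member-nucleus area ratio within one cell.
#' @param watershedTolFrac declumping h-maxima suppression as a fraction of
#'   the expected nucleus radius.
#' @return a list of class `MicroscopyConfig`.
#' @export
microscopyConfig <- function(expectedNucleusArea = pi * 18^2,
                             cropBorder = 0L, smoothSigma = 1.5,
                             medianRadius = 1L,
                             areaMin = 0.3 * expectedNucleusArea,
                             areaMax = 3 * expectedNucleusArea,
                             eccMax = 0.92,
                             mnAreaMin = expectedNucleusArea / 300,
                             mnAreaMax = expectedNucleusArea / 9,
                             mnCompactnessMax = 1.6,
                             expandDist = 30,
                             groupDistFactor = 3,
                             areaRatioMax = 2,
                             watershedTolFrac = 0.05) {
  cfg <- list(expectedNucleusArea = expectedNucleusArea,
              cropBorder = as.integer(cropBorder),
              smoothSigma = smoothSigma, medianRadius = as.integer(medianRadius),
              areaMin = areaMin, areaMax = areaMax, eccMax = eccMax,
              mnAreaMin = mnAreaMin, mnAreaMax = mnAreaMax,
              mnCompactnessMax = mnCompactnessMax, expandDist = expandDist,
              groupDistFactor = groupDistFactor, areaRatioMax = areaRatioMax,
              watershedTolFrac = watershedTolFrac)
  class(cfg) <- "MicroscopyConfig"
  cfg
}

#' Preprocess a field image
#'
#' Optional border crop, Gaussian smoothing, then a 3x3 median
#' noise-reduction filter. Intensities stay on the input scale.
#'
#' @param image single-channel numeric matrix.
#' @param cfg a [microscopyConfig()].
#' @return the processed matrix.
#' @export
preprocessField <- function(image, cfg = microscopyConfig()) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("preprocessField expects a single-channel numeric matrix")
  b <- cfg$cropBorder
  if (b > 0)
    image <- image[(b + 1):(nrow(image) - b), (b + 1):(ncol(image) - b)]
  x <- image
  if (cfg$smoothSigma > 0) x <- .gaussBlurC(x, cfg$smoothSigma)
  if (cfg$medianRadius > 0) x <- .median3C(x)
  clamp(x, 0, .DYNAMIC_RANGE)
}

# Global Otsu threshold (on a 2x-subsampled histogram for speed) + hole
# filling; shared by nucleus segmentation and micronucleus detection.
.fieldMask <- function(image) {
  x <- image / .DYNAMIC_RANGE
  sub <- x[seq(1, nrow(x), 2), seq(1, ncol(x), 2)]
  if (diff(range(sub)) < 1e-6)
    return(matrix(FALSE, nrow(x), ncol(x)))
  thr <- .otsuThreshold(sub)
  mask <- EBImage::fillHull(x > thr)
  matrix(as.logical(mask), nrow(x), ncol(x))
}

# Per-object measurements for an integer label map: area, perimeter (boundary
# pixel count), compactness, eccentricity from second central moments,
# centroid (0-based row/col), mean intensity. Vectorized single pass.
.measureObjects <- function(labels, image) {
  n <- max(labels)
  empty <- data.frame(label = integer(), area_px = numeric(),
                      perimeter_px = numeric(), compactness = numeric(),
                      eccentricity = numeric(), centroid_row = numeric(),
                      centroid_col = numeric(), mean_intensity = numeric())
  if (n == 0) return(empty)
  nr <- nrow(labels)
  idx <- which(labels > 0L)
  l <- labels[idx]
  r <- as.numeric((idx - 1L) %% nr)
  cl <- as.numeric((idx - 1L) %/% nr)
  area <- tabulate(l, n)
  # one grouped-sum pass for all moment accumulators
  acc <- rowsum(cbind(r, cl, r * r, cl * cl, r * cl, image[idx]), l)
  got <- as.integer(rownames(acc))
  S <- matrix(0, n, 6)
  S[got, ] <- acc
  cr <- S[, 1] / area
  cc <- S[, 2] / area
  mrr <- S[, 3] / area - cr^2
  mcc <- S[, 4] / area - cc^2
  mrc <- S[, 5] / area - cr * cc
  half <- (mrr + mcc) / 2
  d <- sqrt(((mrr - mcc) / 2)^2 + mrc^2)
  lam1 <- pmax(half + d, 1e-12)
  lam2 <- pmax(half - d, 0)
  ecc <- sqrt(pmax(0, 1 - lam2 / lam1))
  meanI <- S[, 6] / area
  # boundary pixels: any 4-neighbour with a different label (or image edge)
  pad <- function(m, dr, dc) {
    nr2 <- nrow(m); nc2 <- ncol(m)
    out <- matrix(-1L, nr2, nc2)
    rs <- max(1, 1 + dr):min(nr2, nr2 + dr)
    cs <- max(1, 1 + dc):min(nc2, nc2 + dc)
    out[rs - dr, cs - dc] <- m[rs, cs]
    out
  }
  bd <- labels > 0L & (pad(labels, 1L, 0L) != labels |
                       pad(labels, -1L, 0L) != labels |
                       pad(labels, 0L, 1L) != labels |
                       pad(labels, 0L, -1L) != labels)
  per <- tabulate(labels[bd], n)
  data.frame(label = seq_len(n), area_px = area, perimeter_px = per,
             compactness = pmax(1, per^2 / (4 * pi * area)),
             eccentricity = pmin(ecc, 1 - 1e-12),
             centroid_row = cr, centroid_col = cc, mean_intensity = meanI,
             row.names = NULL)
}

# Label the foreground (8-connected) and measure every component once.
.labelAndMeasure <- function(mask, image) {
  labels <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
  list(labels = labels, meas = .measureObjects(labels, image))
}

# Declump merged multi-nucleus components by local distance-transform
# watershed. Only components whose area or elongation indicates a merge are
# processed, each within its own bounding-box crop.
.splitComponents <- function(labels, meas, cfg) {
  expA <- cfg$expectedNucleusArea
  cand <- meas$label[meas$area_px > 1.55 * expA |
                       (meas$area_px > 0.9 * expA & meas$eccentricity > 0.75)]
  if (!length(cand))
    return(list(labels = labels, changed = FALSE, jobs = list()))
  tol <- max(0.5, cfg$watershedTolFrac * sqrt(expA / pi))
  nr <- nrow(labels)
  idx <- which(labels > 0L)
  l <- labels[idx]
  nextLab <- max(labels)
  jobs <- list()
  for (id in cand) {
    sel <- idx[l == id]
    r <- (sel - 1L) %% nr
    cl <- (sel - 1L) %/% nr
    r0 <- min(r); c0 <- min(cl)
    sub <- matrix(FALSE, max(r) - r0 + 1L, max(cl) - c0 + 1L)
    sub[cbind(r - r0 + 1L, cl - c0 + 1L)] <- TRUE
    w <- EBImage::watershed(EBImage::distmap(sub), tolerance = tol, ext = 1)
    k <- max(w)
    if (k > 1) {
      parts <- as.integer(w)[as.logical(sub)]
      parts[parts == 0L] <- 1L
      newIds <- c(id, nextLab + seq_len(k - 1L))
      labels[sel] <- newIds[parts]
      nextLab <- nextLab + k - 1L
      jobs[[length(jobs) + 1L]] <- list(
        ids = newIds, r0 = max(min(r) - 1L, 0L), r1 = min(max(r) + 1L, nr - 1L),
        c0 = max(min(cl) - 1L, 0L), c1 = min(max(cl) + 1L, ncol(labels) - 1L))
    }
  }
  list(labels = labels, changed = length(jobs) > 0, jobs = jobs)
}

# Re-measure only the components affected by declumping, each within its
# padded bounding-box crop, and merge into the base measurement table.
.remeasureSplit <- function(meas, labels, image, jobs) {
  oldIds <- vapply(jobs, function(j) j$ids[1], 1L)
  meas <- meas[!(meas$label %in% oldIds), , drop = FALSE]
  add <- vector("list", length(jobs))
  for (k in seq_along(jobs)) {
    j <- jobs[[k]]
    rows <- (j$r0 + 1L):(j$r1 + 1L)
    cols <- (j$c0 + 1L):(j$c1 + 1L)
    sub <- labels[rows, cols]
    loc <- match(sub, j$ids)
    loc[is.na(loc)] <- 0L
    subLab <- matrix(as.integer(loc), nrow(sub), ncol(sub))
    mm <- .measureObjects(subLab, image[rows, cols])
    mm$label <- j$ids[mm$label]
    mm$centroid_row <- mm$centroid_row + j$r0
    mm$centroid_col <- mm$centroid_col + j$c0
    add[[k]] <- mm
  }
  out <- rbind(meas, do.call(rbind, add))
  out[order(out$label), , drop = FALSE]
}

#' Segment nuclei as primary objects
#'
#' Global Otsu threshold, hole filling, distance-transform watershed
#' declumping of touching nuclei, then filtering on area bounds and
#' eccentricity. Micronucleus-sized objects fall below the area minimum and
#' are intentionally not returned here (see [detectMicronuclei()]); objects
#' touching the image border are excluded as partial cells.
#'
#' @param image preprocessed single-channel matrix.
#' @param cfg a [microscopyConfig()].
#' @param mask optional precomputed foreground mask (threshold + hole fill),
#'   to share the threshold pass with [detectMicronuclei()].
#' @param base optional precomputed label/measure pass (internal use by the
#'   pipeline driver).
#' @return a [LabeledObjects-class] with measured, consecutively relabelled
#'   nuclei. A blank image yields an empty object set.
#' @export
segmentNuclei <- function(image, cfg = microscopyConfig(), mask = NULL,
                          base = NULL) {
  if (is.null(base)) {
    if (is.null(mask)) mask <- .fieldMask(image)
    base <- .labelAndMeasure(mask, image)
  }
  sp <- .splitComponents(base$labels, base$meas, cfg)
  labels <- sp$labels
  m <- if (sp$changed)
    .remeasureSplit(base$meas, labels, image, sp$jobs) else base$meas
  if (nrow(m)) {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    keep <- m$area_px >= cfg$areaMin & m$area_px <= cfg$areaMax &
      m$eccentricity <= cfg$eccMax & !(m$label %in% border)
    drop <- m$label[!keep]
    if (length(drop)) {
      labels[labels %in% drop] <- 0L
      m <- m[keep, , drop = FALSE]
    }
    if (nrow(m)) {
      old <- sort(m$label)
      remap <- integer(max(old))
      remap[old] <- seq_along(old)
      pos <- labels > 0L
      labels[pos] <- remap[labels[pos]]
      m <- m[order(m$label), , drop = FALSE]
      m$label <- seq_len(nrow(m))
      rownames(m) <- NULL
    }
  }
  new("LabeledObjects", labels = labels, measurements = m)
}

#' Group nuclei into cells by fixed-distance expansion
#'
#' Each nucleus is expanded by `expandDist` px (the secondary-object annulus).
#' Two nuclei belong to one cell when their expanded regions overlap, their
#' centroid distance is at most `groupDistFactor` times the mean equivalent
#' radius, and their area ratio is at most `areaRatioMax`. Groups of 1/2/>=3
#' nuclei are classed mono/bi/poly; groups containing an adjacent pair that
#' violates the area-ratio rule are classed `rejected` (confluent clusters,
#' excluded from all counts). The cell region is the union of member expanded
#' regions (a nearest-nucleus tessellation within the expansion distance) and
#' the cytoplasm is the cell region minus the nuclei.
#'
#' @param nuclei a [LabeledObjects-class] from [segmentNuclei()].
#' @param cfg a [microscopyConfig()].
#' @param computeMap build the pixel-level cell-region map (needed for
#'   cytoplasm masks; assignment itself is analytic).
#' @return a [CellGroupSet-class].
#' @export
groupCells <- function(nuclei, cfg = microscopyConfig(), computeMap = TRUE) {
  m <- objectTable(nuclei)
  labels <- labelMap(nuclei)
  n <- nrow(m)
  if (n == 0) {
    return(new("CellGroupSet",
               groups = data.frame(cell_id = integer(), class = character(),
                                   n_nuclei = integer(),
                                   centroid_row = numeric(),
                                   centroid_col = numeric()),
               membership = data.frame(label = integer(), cell_id = integer(),
                                       centroid_row = numeric(),
                                       centroid_col = numeric(),
                                       r_eq = numeric(), area_px = numeric()),
               cellMap = matrix(0L, nrow(labels), ncol(labels)),
               nucleusMap = labels))
  }
  rEq <- sqrt(m$area_px / pi)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  rejectA <- integer(0)
  rejectB <- integer(0)
  # candidate pairs by centroid distance (vectorized prefilter)
  dMaxAbs <- cfg$groupDistFactor * max(rEq)
  ord <- order(m$centroid_row)
  for (oi in seq_len(n - 1)) {
    i <- ord[oi]
    for (oj in (oi + 1):n) {
      j <- ord[oj]
      if (m$centroid_row[j] - m$centroid_row[i] > dMaxAbs) break
      dc <- sqrt((m$centroid_row[i] - m$centroid_row[j])^2 +
                 (m$centroid_col[i] - m$centroid_col[j])^2)
      overlap <- (dc - rEq[i] - rEq[j]) < 2 * cfg$expandDist
      near <- dc <= cfg$groupDistFactor * mean(c(rEq[i], rEq[j]))
      if (overlap && near) {
        ratio <- max(m$area_px[i], m$area_px[j]) /
          min(m$area_px[i], m$area_px[j])
        if (ratio <= cfg$areaRatioMax) {
          ri <- findRoot(i); rj <- findRoot(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        } else {
          rejectA <- c(rejectA, i)
          rejectB <- c(rejectB, j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), findRoot, 1L)
  cellId <- match(roots, sort(unique(roots)))
  rejected <- logical(max(cellId))
  if (length(rejectA))
    rejected[unique(c(cellId[rejectA], cellId[rejectB]))] <- TRUE
  sizes <- tabulate(cellId)
  cls <- ifelse(rejected, "rejected",
                ifelse(sizes == 1, "mono", ifelse(sizes == 2, "bi", "poly")))
  groups <- data.frame(
    cell_id = seq_along(sizes), class = cls, n_nuclei = sizes,
    centroid_row = as.numeric(tapply(m$centroid_row, cellId, mean)),
    centroid_col = as.numeric(tapply(m$centroid_col, cellId, mean)))
  membership <- data.frame(label = m$label, cell_id = cellId,
                           centroid_row = m$centroid_row,
                           centroid_col = m$centroid_col,
                           r_eq = rEq, area_px = m$area_px)
  cellMapM <- matrix(0L, nrow(labels), ncol(labels))
  if (computeMap) {
    mask <- EBImage::distmap(labels == 0) <= cfg$expandDist | labels > 0
    prop <- EBImage::propagate(EBImage::Image(labels * 0), labels,
                               mask = mask)
    pm <- matrix(as.integer(prop), nrow(labels), ncol(labels))
    lut <- integer(n)
    lut[m$label] <- cellId
    pos <- pm > 0
    cellMapM[pos] <- lut[pm[pos]]
  }
  new("CellGroupSet", groups = groups, membership = membership,
      cellMap = cellMapM, nucleusMap = labels)
}

#' Detect micronucleus candidates
#'
#' Keeps connected components of the thresholded field within the
#' micronucleus area window and compactness cut. Components 8-adjacent to a
#' nucleus are part of that nucleus's component and therefore never called:
#' a spot touching a nucleus is not a micronucleus.
#'
#' @param image preprocessed single-channel matrix.
#' @param nuclei a [LabeledObjects-class] from [segmentNuclei()] (its label
#'   map defines the nucleus regions the calls must avoid).
#' @param cfg a [microscopyConfig()].
#' @param mask optional precomputed foreground mask (see [segmentNuclei()]).
#' @param base optional precomputed label/measure pass (internal).
#' @return `data.frame` of unassigned calls: `call_id`, `area_px`,
#'   `compactness`, `centroid_row`, `centroid_col`, `parent_cell_id` (NA),
#'   `parent_class` (NA).
#' @export
detectMicronuclei <- function(image, nuclei, cfg = microscopyConfig(),
                              mask = NULL, base = NULL) {
  if (is.null(base)) {
    if (is.null(mask)) mask <- .fieldMask(image)
    base <- .labelAndMeasure(mask, image)
  }
  m <- base$meas
  empty <- data.frame(call_id = integer(), area_px = numeric(),
                      compactness = numeric(), centroid_row = numeric(),
                      centroid_col = numeric(), parent_cell_id = integer(),
                      parent_class = character())
  if (!nrow(m)) return(empty)
  keep <- m$area_px >= cfg$mnAreaMin & m$area_px <= cfg$mnAreaMax &
    m$compactness <= cfg$mnCompactnessMax
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) return(empty)
  data.frame(call_id = seq_len(nrow(m)), area_px = m$area_px,
             compactness = m$compactness, centroid_row = m$centroid_row,
             centroid_col = m$centroid_col,
             parent_cell_id = NA_integer_, parent_class = NA_character_,
             row.names = NULL)
}

#' Assign micronucleus calls to parent cells
#'
#' A call whose centroid lies in exactly one cell region (within the
#' expansion distance of that cell's nuclei) gets that parent; if it lies in
#' several, the nearest nucleus edge wins, ties going to the lower `cell_id`;
#' if in none, the parent is none. Only mono- and binucleated parents are
#' valid: calls landing in polynucleated or rejected groups are recorded with
#' no parent and excluded from frequency counts.
#'
#' @param calls `data.frame` from [detectMicronuclei()].
#' @param groups a [CellGroupSet-class].
#' @param cfg a [microscopyConfig()].
#' @return the calls with `parent_cell_id` and `parent_class` filled in.
#' @export
assignMicronuclei <- function(calls, groups, cfg = microscopyConfig()) {
  if (!nrow(calls)) return(calls)
  g <- cellGroups(groups)
  mem <- groups@membership
  for (i in seq_len(nrow(calls))) {
    if (!nrow(mem)) break
    # edge distance from the call centroid to each nucleus (equivalent-radius
    # approximation of the nucleus boundary)
    edge <- sqrt((calls$centroid_row[i] - mem$centroid_row)^2 +
                 (calls$centroid_col[i] - mem$centroid_col)^2) - mem$r_eq
    insideCells <- unique(mem$cell_id[edge <= cfg$expandDist])
    if (!length(insideCells)) next
    if (length(insideCells) == 1L) {
      pick <- insideCells
    } else {
      # nearest nucleus-edge distance wins; ties to the lower cell_id
      best <- vapply(insideCells,
                     function(cid) min(edge[mem$cell_id == cid]), 0)
      pick <- insideCells[best <= min(best) + 1e-9]
      pick <- min(pick)
    }
    cls <- g$class[g$cell_id == pick]
    if (cls %in% c("mono", "bi")) {
      calls$parent_cell_id[i] <- pick
      calls$parent_class[i] <- cls
    }
  }
  calls
}

#' Score one field
#'
#' Tallies nucleation classes and assigned micronuclei into the per-field
#' counts used by the CBMN statistics: `N1`/`N2`/`N3` (mono/bi/poly),
#' rejected groups, binucleated cells carrying at least one assigned
#' micronucleus, total micronuclei in binucleated cells, and mononucleated
#' cells with micronuclei (recorded but excluded from frequency statistics,
#' which score binucleated cells only).
#'
#' @param groups a [CellGroupSet-class].
#' @param calls assigned calls from [assignMicronuclei()].
#' @return one-row `data.frame`: `N1`, `N2`, `N3`, `n_rejected`,
#'   `n_bi_with_mn`, `n_mn_total_in_bi`, `n_mono_with_mn`, `n_groups`.
#' @export
scoreField <- function(groups, calls) {
  g <- cellGroups(groups)
  if (nrow(calls)) {
    known <- is.na(calls$parent_cell_id) | calls$parent_cell_id %in% g$cell_id
    if (!all(known)) stop("integrity error: call parent ids not in groups")
  }
  biIds <- g$cell_id[g$class == "bi"]
  monoIds <- g$cell_id[g$class == "mono"]
  inBi <- calls$parent_cell_id[!is.na(calls$parent_cell_id) &
                                 calls$parent_cell_id %in% biIds]
  inMono <- calls$parent_cell_id[!is.na(calls$parent_cell_id) &
                                   calls$parent_cell_id %in% monoIds]
  data.frame(
    N1 = length(monoIds), N2 = length(biIds),
    N3 = sum(g$class == "poly"), n_rejected = sum(g$class == "rejected"),
    n_bi_with_mn = length(unique(inBi)),
    n_mn_total_in_bi = length(inBi),
    n_mono_with_mn = length(unique(inMono)),
    n_groups = nrow(g))
}

#' Run the full microscopy pipeline on a set of fields
#'
#' Applies the five stages in order (preprocess, segment, group, detect,
#' assign, score) to each field and returns the per-field score table plus
#' per-object tables and a per-stage object-count log. Deterministic for
#' fixed input and configuration.
#'
#' @param images list of single-channel matrices (or of `generateField()`
#'   results, whose `$image` is used).
#' @param cfg a [microscopyConfig()].
#' @param computeMap build pixel-level cell maps (slower; off by default for
#'   batch scoring).
#' @return list with `scores` (one row per field), `objects` (per-field
#'   nucleus tables), `calls` (per-field assigned micronuclei) and `log`.
#' @export
runMicroscopyPipeline <- function(images, cfg = microscopyConfig(),
                                  computeMap = FALSE) {
  if (is.matrix(images)) images <- list(images)
  scores <- vector("list", length(images))
  objects <- vector("list", length(images))
  callsL <- vector("list", length(images))
  logL <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (is.list(img) && !is.null(img$image)) img <- img$image
    res <- tryCatch({
      pp <- preprocessField(img, cfg)
      msk <- .fieldMask(pp)
      base <- .labelAndMeasure(msk, pp)
      nuc <- segmentNuclei(pp, cfg, base = base)
      grp <- groupCells(nuc, cfg, computeMap = computeMap)
      mn <- detectMicronuclei(pp, nuc, cfg, base = base)
      mn <- assignMicronuclei(mn, grp, cfg)
      sc <- scoreField(grp, mn)
      list(sc = sc, nuc = objectTable(nuc), mn = mn,
           log = data.frame(field = i, n_nuclei = nObjects(nuc),
                            n_groups = nrow(cellGroups(grp)),
                            n_mn_calls = nrow(mn),
                            n_mn_assigned = sum(!is.na(mn$parent_cell_id))))
    }, error = function(e)
      stop("field ", i, ": ", conditionMessage(e), call. = FALSE))
    scores[[i]] <- cbind(field = i, res$sc)
    objects[[i]] <- res$nuc
    callsL[[i]] <- res$mn
    logL[[i]] <- res$log
  }
  list(scores = do.call(rbind, scores), objects = objects, calls = callsL,
       log = do.call(rbind, logL))
}
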