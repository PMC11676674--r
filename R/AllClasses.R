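#' @import methods
NULL

# ---------------------------------------------------------------------------
# ConditionPreset
# ---------------------------------------------------------------------------

#' ConditionPreset: generative parameters of one experimental condition
#'
#' A `ConditionPreset` bundles everything the synthetic-image generator needs
#' to emulate one CBMN assay condition: how many cells a field carries, the
#' treated/untreated yield ratio (which drives cell-number cytotoxicity), the
#' mixture of mono-/bi-/poly-nucleated cells (which drives CBPI and the
#' percentage of binucleated cells), the per-binucleate micronucleus
#' probability and count distribution, and the optical/noise model.
#'
#' @slot name condition label, e.g. `"NC"` or `"MMC-0.025"`.
#' @slot nCellsTarget target number of cells per generated field (untreated
#'   yield; the realised count is scaled by `survivalFraction`).
#' @slot survivalFraction treated/untreated cell yield in (0, 1].
#' @slot classFractions named numeric `(mono, bi, poly)` summing to 1.
#' @slot mnProbBi probability that a binucleated cell carries >= 1
#'   micronucleus.
#' @slot mnCountDist probability over micronucleus counts {1, 2, 3} given
#'   >= 1.
#' @slot nucleusRadiusPx `c(mean, sd)` nucleus equivalent radius in pixels.
#' @slot mnRadiusRatio micronucleus radius as a fraction of the nucleus
#'   radius, in (0, 1/3].
#' @slot blurSigmaPx Gaussian point-spread proxy (pixels).
#' @slot noisePoissonScale photon-count scaling for Poisson shot noise
#'   (expected counts per intensity unit; 0 disables).
#' @slot noiseGaussianSd read-noise standard deviation as a fraction of the
#'   dynamic range.
#'
#' @seealso [presetTable()], [generateField()], [generateTileSet()]
#' @export
setClass("ConditionPreset",
  representation(
    name             = "character",
    nCellsTarget     = "integer",
    survivalFraction = "numeric",
    classFractions   = "numeric",
    mnProbBi         = "numeric",
    mnCountDist      = "numeric",
    nucleusRadiusPx  = "numeric",
    mnRadiusRatio    = "numeric",
    blurSigmaPx      = "numeric",
    noisePoissonScale = "numeric",
    noiseGaussianSd  = "numeric"
  )
)

setValidity("ConditionPreset", function(object) {
  msg <- character()
  f <- object@classFractions
  if (length(f) != 3L || is.null(names(f)) ||
      !identical(names(f), c("mono", "bi", "poly")))
    msg <- c(msg, "classFractions must be named c(mono=, bi=, poly=)")
  else {
    if (abs(sum(f) - 1) > 1e-9)
      msg <- c(msg, "classFractions must sum to 1 (within 1e-9)")
    if (any(f < 0 | f > 1)) msg <- c(msg, "classFractions must lie in [0,1]")
  }
  if (object@mnProbBi < 0 || object@mnProbBi > 1)
    msg <- c(msg, "mnProbBi must lie in [0,1]")
  if (object@mnRadiusRatio <= 0 || object@mnRadiusRatio > 1 / 3)
    msg <- c(msg, "mnRadiusRatio must lie in (0, 1/3]")
  if (object@survivalFraction <= 0 || object@survivalFraction > 1)
    msg <- c(msg, "survivalFraction must lie in (0,1]")
  if (length(object@mnCountDist) != 3L || abs(sum(object@mnCountDist) - 1) > 1e-9 ||
      any(object@mnCountDist < 0))
    msg <- c(msg, "mnCountDist must be 3 non-negative probabilities summing to 1")
  if (length(object@nucleusRadiusPx) != 2L || object@nucleusRadiusPx[1] <= 0)
    msg <- c(msg, "nucleusRadiusPx must be c(mean, sd) with positive mean")
  if (object@nCellsTarget < 1L) msg <- c(msg, "nCellsTarget must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn ConditionPreset compact display
#' @param object a `ConditionPreset`.
#' @export
setMethod("show", "ConditionPreset", function(object) {
  f <- object@classFractions
  cat("ConditionPreset '", object@name, "'\n", sep = "")
  cat(sprintf("  cells/field target: %d  (survival fraction %.4f)\n",
              object@nCellsTarget, object@survivalFraction))
  cat(sprintf("  class fractions: mono %.4f | bi %.4f | poly %.4f\n",
              f["mono"], f["bi"], f["poly"]))
  cat(sprintf("  P(MN | binucleated): %.4f ; MN count dist (1,2,3): %s\n",
              object@mnProbBi, paste(object@mnCountDist, collapse = "/")))
  cat(sprintf("  nucleus radius %.1f +/- %.1f px ; MN radius ratio %.2f\n",
              object@nucleusRadiusPx[1], object@nucleusRadiusPx[2],
              object@mnRadiusRatio))
  cat(sprintf("  blur sigma %.1f px ; Poisson scale %.3g ; Gaussian sd %.3f\n",
              object@blurSigmaPx, object@noisePoissonScale,
              object@noiseGaussianSd))
})

#' Accessors for ConditionPreset
#'
#' @param x a [ConditionPreset-class] object.
#' @return `presetName` the condition label; `classFractions` the named
#'   mono/bi/poly mixture; `mnProbBi` the per-binucleate micronucleus
#'   probability; `survivalFraction` the treated/untreated yield ratio.
#' @name preset-accessors
#' @export
presetName <- function(x) x@name

#' @rdname preset-accessors
#' @export
classFractions <- function(x) x@classFractions

#' @rdname preset-accessors
#' @export
mnProbBi <- function(x) x@mnProbBi

#' @rdname preset-accessors
#' @export
survivalFraction <- function(x) x@survivalFraction

# ---------------------------------------------------------------------------
# LabeledObjects
# ---------------------------------------------------------------------------

#' LabeledObjects: segmented objects with per-object measurements
#'
#' Result of nuclei segmentation: an integer label map (0 = background,
#' objects labelled 1..n consecutively) together with one measurement row per
#' object. Compactness is perimeter^2 / (4 pi area) (>= 1, 1 for a perfect
#' circle, clamped below at 1 to absorb discretisation of small perimeters);
#' eccentricity comes from second central moments and lies in [0, 1).
#' Coordinates are 0-based (row, col) with origin at the top-left.
#'
#' @slot labels integer matrix label map.
#' @slot measurements `data.frame` with columns `label`, `area_px`,
#'   `perimeter_px`, `compactness`, `eccentricity`, `centroid_row`,
#'   `centroid_col`, `mean_intensity`.
#' @export
setClass("LabeledObjects",
  representation(labels = "matrix", measurements = "data.frame"))

setValidity("LabeledObjects", function(object) {
  msg <- character()
  m <- object@measurements
  need <- c("label", "area_px", "perimeter_px", "compactness", "eccentricity",
            "centroid_row", "centroid_col", "mean_intensity")
  if (!all(need %in% names(m)))
    msg <- c(msg, paste("measurements must contain:", paste(need, collapse = ", ")))
  else {
    mx <- max(0L, max(object@labels))
    cnt <- if (mx > 0) tabulate(object@labels, mx) else integer()
    if (any(cnt == 0))
      msg <- c(msg, "labels must be consecutive positive integers")
    if (!identical(sort(as.integer(m$label)), seq_len(mx)))
      msg <- c(msg, "every label must have exactly one measurement row")
    if (nrow(m) && any(m$compactness < 1 - 1e-6))
      msg <- c(msg, "compactness must be >= 1 - 1e-6")
    if (nrow(m) && any(m$eccentricity < 0 | m$eccentricity >= 1 + 1e-9))
      msg <- c(msg, "eccentricity must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn LabeledObjects compact display
#' @param object a `LabeledObjects`.
#' @export
setMethod("show", "LabeledObjects", function(object) {
  cat("LabeledObjects:", nrow(object@measurements), "objects on a",
      paste(dim(object@labels), collapse = " x "), "grid\n")
  if (nrow(object@measurements)) {
    cat("  area_px:", paste(round(range(object@measurements$area_px)),
                            collapse = " - "), "\n")
  }
})

#' Accessors for LabeledObjects
#' @param x a [LabeledObjects-class] object.
#' @return `labelMap` the integer label matrix; `objectTable` the per-object
#'   measurement `data.frame`; `nObjects` the object count.
#' @name labeled-accessors
#' @export
labelMap <- function(x) x@labels

#' @rdname labeled-accessors
#' @export
objectTable <- function(x) x@measurements

#' @rdname labeled-accessors
#' @export
nObjects <- function(x) nrow(x@measurements)

# ---------------------------------------------------------------------------
# CellGroupSet
# ---------------------------------------------------------------------------

#' CellGroupSet: nuclei grouped into cells
#'
#' Result of grouping segmented nuclei into cells by fixed-distance expansion.
#' Each non-rejected group carries a nucleation class (`mono`, `bi`, `poly`);
#' the cell region is the union of the member nuclei's expanded regions and
#' the cytoplasm is that region minus the nuclei (a doughnut-shaped annulus).
#'
#' @slot groups `data.frame` with columns `cell_id`, `class`, `n_nuclei`,
#'   `centroid_row`, `centroid_col`.
#' @slot membership `data.frame` mapping nucleus `label` to `cell_id`.
#' @slot cellMap integer matrix: pixels of each cell region labelled by
#'   `cell_id` (0 elsewhere); rejected groups keep their id so their extent is
#'   known, but they are excluded from all counts.
#' @slot nucleusMap integer matrix of the nuclei as segmented.
#' @export
setClass("CellGroupSet",
  representation(groups = "data.frame", membership = "data.frame",
                 cellMap = "matrix", nucleusMap = "matrix"))

setValidity("CellGroupSet", function(object) {
  g <- object@groups
  msg <- character()
  if (!all(c("cell_id", "class", "n_nuclei") %in% names(g)))
    msg <- c(msg, "groups must have cell_id, class, n_nuclei")
  else if (nrow(g)) {
    ok <- (g$class == "mono" & g$n_nuclei == 1) |
      (g$class == "bi" & g$n_nuclei == 2) |
      (g$class == "poly" & g$n_nuclei >= 3) |
      g$class == "rejected"
    if (!all(ok))
      msg <- c(msg, "class must match member count (mono=1, bi=2, poly>=3) or be 'rejected'")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CellGroupSet compact display
#' @param object a `CellGroupSet`.
#' @export
setMethod("show", "CellGroupSet", function(object) {
  tab <- table(factor(object@groups$class,
                      levels = c("mono", "bi", "poly", "rejected")))
  cat("CellGroupSet:", nrow(object@groups), "cell groups (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
})

#' Accessors for CellGroupSet
#' @param x a [CellGroupSet-class] object.
#' @return `cellGroups` the per-cell `data.frame`; `cellMap` the labelled cell
#'   region matrix; `cytoplasmMask` the logical cytoplasm (cell-minus-nuclei)
#'   mask.
#' @name group-accessors
#' @export
cellGroups <- function(x) x@groups

#' @rdname group-accessors
#' @export
cellMap <- function(x) x@cellMap

#' @rdname group-accessors
#' @export
cytoplasmMask <- function(x) x@cellMap > 0 & x@nucleusMap == 0

# ---------------------------------------------------------------------------
# MaskSet
# ---------------------------------------------------------------------------

#' MaskSet: boolean morphological masks for one single-cell tile
#'
#' Named boolean grids produced by [buildMasks()], mirroring the mask algebra
#' of imaging-flow-cytometry software: a DNA threshold mask, its dilation, a
#' top-hat spot mask, an area-filtered range mask, the refined nuclear mask,
#' and the micronucleus mask composed as `range AND NOT dilate(nuclear)` so it
#' can never intersect the nuclear mask.
#'
#' @slot masks named list of logical matrices, all the tile's shape:
#'   `threshold`, `dilate`, `spot`, `range`, `levelset`, `nuclear`,
#'   `micronuclei`.
#' @export
setClass("MaskSet", representation(masks = "list"))

setValidity("MaskSet", function(object) {
  need <- c("threshold", "dilate", "spot", "range", "levelset", "nuclear",
            "micronuclei")
  msg <- character()
  if (!all(need %in% names(object@masks)))
    msg <- c(msg, paste("masks must contain:", paste(need, collapse = ", ")))
  else {
    dims <- lapply(object@masks, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
      msg <- c(msg, "all masks must share one shape")
    if (any(object@masks$micronuclei & object@masks$nuclear))
      msg <- c(msg, "micronuclei mask must be disjoint from the nuclear mask")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MaskSet compact display
#' @param object a `MaskSet`.
#' @export
setMethod("show", "MaskSet", function(object) {
  px <- vapply(object@masks, sum, 0)
  cat("MaskSet (", paste(dim(object@masks[[1]]), collapse = " x "), "):\n")
  for (n in names(px)) cat(sprintf("  %-12s %d px\n", n, px[[n]]))
})

#' Extract one mask from a MaskSet
#' @param x a [MaskSet-class].
#' @param name one of `"threshold"`, `"dilate"`, `"spot"`, `"range"`,
#'   `"levelset"`, `"nuclear"`, `"micronuclei"`.
#' @export
getMask <- function(x, name) {
  if (!name %in% names(x@masks)) stop("unknown mask: ", name)
  x@masks[[name]]
}

# ---------------------------------------------------------------------------
# GateConfig
# ---------------------------------------------------------------------------

#' GateConfig: thresholds of the sequential BNC gate chain
#'
#' The threshold set defining the flow-style gate sequence: focus (gradient
#' RMS), lobe count, single-cell aspect ratio, DNA area window, texture
#' (homogeneity and width), and the final aspect-ratio-intensity /
#' compactness box that defines the accepted binucleated-cell (BNC)
#' population.
#'
#' Aspect-ratio thresholds are unitless (minor/major, in (0,1]); areas and
#' widths are in pixels; homogeneity is the co-occurrence inverse difference
#' moment in (0,1]. The classical instrument-software thresholds (aspect
#' ratio 0.5, homogeneity 10, width 15) are expressed in that software's
#' units; defaults here are in this package's units and can be re-fitted with
#' [calibrateGates()].
#'
#' @slot focusMin minimum gradient RMS (focus) to keep an event.
#' @slot lobeCountRequired required DNA lobe count (2 selects binucleated).
#' @slot bfAspectRatioMin minimum brightfield aspect ratio (singlets).
#' @slot dnaAreaRange `c(min, max)` DNA mask area (px) for the BNC window.
#' @slot homogeneityMin minimum DNA homogeneity (uniform chromatin stain).
#' @slot widthMin minimum DNA width (px).
#' @slot compactnessMax maximum DNA compactness.
#' @slot aspectRatioIntensityRange `c(min, max)` intensity-weighted DNA
#'   aspect ratio window.
#' @export
setClass("GateConfig",
  representation(
    focusMin = "numeric", lobeCountRequired = "integer",
    bfAspectRatioMin = "numeric", dnaAreaRange = "numeric",
    homogeneityMin = "numeric", widthMin = "numeric",
    compactnessMax = "numeric", aspectRatioIntensityRange = "numeric"
  )
)

setValidity("GateConfig", function(object) {
  msg <- character()
  num <- c(object@focusMin, object@bfAspectRatioMin, object@dnaAreaRange,
           object@homogeneityMin, object@widthMin, object@compactnessMax,
           object@aspectRatioIntensityRange)
  if (any(!is.finite(num))) msg <- c(msg, "all thresholds must be finite")
  if (length(object@dnaAreaRange) != 2L ||
      diff(object@dnaAreaRange) <= 0)
    msg <- c(msg, "dnaAreaRange must be a non-empty c(min, max)")
  if (length(object@aspectRatioIntensityRange) != 2L ||
      diff(object@aspectRatioIntensityRange) <= 0)
    msg <- c(msg, "aspectRatioIntensityRange must be a non-empty c(min, max)")
  if (length(msg)) msg else TRUE
})

#' @describeIn GateConfig compact display
#' @param object a `GateConfig`.
#' @export
setMethod("show", "GateConfig", function(object) {
  cat("GateConfig:\n")
  cat(sprintf("  focus (gradient RMS) >= %.3g\n", object@focusMin))
  cat(sprintf("  lobe count == %d\n", object@lobeCountRequired))
  cat(sprintf("  BF aspect ratio > %.2f\n", object@bfAspectRatioMin))
  cat(sprintf("  DNA area in [%g, %g] px\n", object@dnaAreaRange[1],
              object@dnaAreaRange[2]))
  cat(sprintf("  homogeneity > %.3g and width > %.3g px\n",
              object@homogeneityMin, object@widthMin))
  cat(sprintf("  AR-intensity in [%.2f, %.2f], compactness <= %.2f\n",
              object@aspectRatioIntensityRange[1],
              object@aspectRatioIntensityRange[2], object@compactnessMax))
})

#' Construct a GateConfig
#'
#' Defaults reproduce the published gating logic on this package's feature
#' scales: aspect-ratio cut 0.5 as printed; area window sized for binucleated
#' DNA content at the default nucleus radius; homogeneity/width cuts mapped
#' onto the package's inverse-difference-moment and pixel units.
#'
#' @param focusMin minimum gradient RMS.
#' @param lobeCountRequired required lobe count (default 2 = binucleated).
#' @param bfAspectRatioMin brightfield singlet cut (default 0.5).
#' @param dnaAreaRange DNA area window in px.
#' @param homogeneityMin homogeneity cut.
#' @param widthMin DNA width cut in px.
#' @param compactnessMax DNA compactness cut.
#' @param aspectRatioIntensityRange intensity-weighted aspect-ratio window.
#' @return a [GateConfig-class] object.
#' @export
gateConfig <- function(focusMin = 0.105, lobeCountRequired = 2L,
                       bfAspectRatioMin = 0.5,
                       dnaAreaRange = c(900, 3600),
                       homogeneityMin = 0.35, widthMin = 15,
                       compactnessMax = 2.6,
                       aspectRatioIntensityRange = c(0.25, 1)) {
  new("GateConfig", focusMin = focusMin,
      lobeCountRequired = as.integer(lobeCountRequired),
      bfAspectRatioMin = bfAspectRatioMin, dnaAreaRange = dnaAreaRange,
      homogeneityMin = homogeneityMin, widthMin = widthMin,
      compactnessMax = compactnessMax,
      aspectRatioIntensityRange = aspectRatioIntensityRange)
}
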