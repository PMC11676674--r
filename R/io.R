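# Plain-format I/O: TIFF/PNG images, CSV object tables, JSON summaries.

#' Write / read a field or tile image
#'
#' Images are written as TIFF (one page per channel, 16-bit) via EBImage;
#' `writeFieldPreview` writes a PNG preview scaled to the data range.
#'
#' @param image numeric matrix (or `list(bf=, dna=)` for a two-channel tile).
#' @param path output path (`.tif`/`.tiff` or `.png`).
#' @return the path, invisibly (`readFieldImage` returns a matrix or a
#'   two-channel list).
#' @export
writeFieldImage <- function(image, path) {
  if (is.list(image)) {
    arr <- EBImage::combine(EBImage::Image(image$bf / .DYNAMIC_RANGE),
                            EBImage::Image(image$dna / .DYNAMIC_RANGE))
  } else {
    arr <- EBImage::Image(image / .DYNAMIC_RANGE)
  }
  EBImage::writeImage(arr, path, type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeFieldImage
#' @export
readFieldImage <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3 && d[3] == 2) {
    list(bf = matrix(as.numeric(img[, , 1]), d[1], d[2]) * .DYNAMIC_RANGE,
         dna = matrix(as.numeric(img[, , 2]), d[1], d[2]) * .DYNAMIC_RANGE)
  } else {
    matrix(as.numeric(img), d[1], d[2]) * .DYNAMIC_RANGE
  }
}

#' @rdname writeFieldImage
#' @export
writeFieldPreview <- function(image, path) {
  x <- image / max(image, 1)
  EBImage::writeImage(EBImage::Image(x), path, type = "png")
  invisible(path)
}

#' Write ground truth to CSV (per object) and JSON (per-field totals)
#'
#' @param truth a `FieldGroundTruth` from [generateField()].
#' @param csvPath per-object CSV path (one row per nucleus / micronucleus).
#' @param jsonPath per-field totals JSON path.
#' @return invisibly, the paths.
#' @export
writeGroundTruth <- function(truth, csvPath, jsonPath = NULL) {
  nuc <- truth$nuclei
  nuc$object <- "nucleus"
  mn <- truth$micronuclei
  if (nrow(mn)) {
    mn$object <- "micronucleus"
    mn$nucleus <- NA_integer_
    cols <- c("cell_id", "object", "nucleus", "centroid_row", "centroid_col",
              "area_px")
    obj <- rbind(nuc[, cols], mn[, cols])
  } else {
    obj <- nuc[, c("cell_id", "object", "nucleus", "centroid_row",
                   "centroid_col", "area_px")]
  }
  cls <- truth$cells$class[match(obj$cell_id, truth$cells$cell_id)]
  obj <- cbind(obj, class = cls)
  utils::write.csv(obj, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(truth$totals, jsonPath, auto_unbox = TRUE,
                         digits = NA)
  invisible(c(csvPath, jsonPath))
}

#' Read a CSV count table for the statistics layer
#'
#' Expected columns: `condition`, `replicate`, `N1`, `N2`, `N3`,
#' `n_bi_with_mn` and optionally `total_cells`.
#'
#' @param path CSV path.
#' @return validated `data.frame`.
#' @export
readCountsCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "replicate", "N1", "N2", "N3", "n_bi_with_mn")
  if (!all(need %in% names(d)))
    stop("count table needs columns: ", paste(need, collapse = ", "))
  for (col in c("N1", "N2", "N3", "n_bi_with_mn")) {
    if (any(d[[col]] < 0) || any(d[[col]] != round(d[[col]])))
      stop("column ", col, " must hold non-negative integers")
  }
  if (any(d$n_bi_with_mn > d$N2))
    stop("n_bi_with_mn cannot exceed N2")
  d
}

#' Read a CSV concentration-viability table
#'
#' Expected columns: `concentration`, `viability` (and optionally
#' `replicate`).
#'
#' @param path CSV path.
#' @return validated `data.frame`.
#' @export
readViabilityCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("concentration", "viability") %in% names(d)))
    stop("viability table needs columns concentration and viability")
  if (any(d$concentration <= 0)) stop("concentrations must be positive")
  d
}
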