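# Single-cell tile generator for the imaging-flow-cytometry-style route.
#
# Each tile carries two aligned channels: a brightfield proxy (BF) and a DNA
# stain channel. Controlled spoiler categories (out-of-focus, doublet,
# debris) are mixed in at configurable fractions so every gate of the chain
# has something to reject.

.TILE_BF_BG <- 20000
.TILE_BF_CELL <- 27000

# Render one cell's DNA content (nuclei + MN) around a centre point.
.renderTileCell <- function(dna, centre, preset, class, withMN, rMean, mnR) {
  shape <- dim(dna)
  nn <- switch(class, mono = 1L, bi = 2L, poly = 3L)
  r0 <- clamp(stats::rnorm(1, rMean, preset@nucleusRadiusPx[2]),
              rMean - 2.5, rMean + 2.5)
  rs <- r0 * stats::runif(nn, 0.95, 1.05)
  if (nn == 1L) {
    ctr <- matrix(centre, 1)
  } else if (nn == 2L) {
    sep <- stats::runif(1, 1.6, 2.1) * mean(rs)
    th <- stats::runif(1, 0, pi)
    u <- c(cos(th), sin(th))
    ctr <- rbind(centre + u * sep / 2, centre - u * sep / 2)
  } else {
    th0 <- stats::runif(1, 0, 2 * pi)
    ths <- th0 + c(0, 2 * pi / 3, 4 * pi / 3) + stats::runif(3, -0.2, 0.2)
    d0 <- stats::runif(1, 1.2, 1.35) * mean(rs)
    ctr <- cbind(centre[1] + d0 * cos(ths), centre[2] + d0 * sin(ths))
  }
  ax <- stats::runif(nn, 1.0, 1.3)
  aAx <- rs * sqrt(ax)
  intensity <- stats::runif(1, 12000, 20000)
  for (i in seq_len(nn)) {
    idx <- .ellipseIdx(ctr[i, 1], ctr[i, 2], aAx[i], rs[i] / sqrt(ax[i]),
                       stats::runif(1, 0, pi), shape)
    dna[idx] <- intensity
  }
  mnCount <- 0L
  if (withMN) {
    k <- sample(1:3, 1, prob = preset@mnCountDist)
    for (m in seq_len(k)) {
      host <- sample(seq_len(nn), 1)
      for (try in 1:60) {
        dist <- stats::runif(1, 1.5, 1.9) * rMean
        thm <- stats::runif(1, 0, 2 * pi)
        pm <- c(ctr[host, 1] + dist * cos(thm), ctr[host, 2] + dist * sin(thm))
        dAll <- sqrt((pm[1] - ctr[, 1])^2 + (pm[2] - ctr[, 2])^2)
        inFrame <- all(pm > 8) && all(pm < shape - 8)
        if (all(dAll >= aAx + mnR + 4) && inFrame) {
          idx <- .ellipseIdx(pm[1], pm[2], mnR * stats::runif(1, 0.85, 1.15),
                             mnR, 0, shape)
          dna[idx] <- stats::runif(1, 18000, 20000)
          mnCount <- mnCount + 1L
          break
        }
      }
    }
  }
  list(dna = dna, centres = ctr, radius = mean(rs), mn_count = mnCount)
}

#' Generate a labelled set of single-cell tiles
#'
#' Emulates single-cell acquisition on an imaging flow cytometer: each tile
#' is a two-channel (brightfield proxy + DNA) image of one event, labelled
#' with its true category. Class balance follows the preset's nucleation
#' mixture and micronucleus rate; spoiler tiles (out-of-focus, doublet,
#' debris) are mixed in at the requested fractions so that each gate of the
#' analysis chain rejects something.
#'
#' @param preset a [ConditionPreset-class].
#' @param nTiles number of tiles (>= 1).
#' @param seed integer seed.
#' @param spoilers named fractions `c(oof=, doublet=, debris=)`.
#' @param shape tile shape in px (default 128 x 128).
#' @param noiseFree skip Poisson/Gaussian noise (blur still applied).
#' @return list with `tiles` (list of `list(bf=, dna=)` matrices) and
#'   `labels` (`data.frame`: `tile`, `category`, `class`, `mn_count`,
#'   `in_focus`, `n_cells`, `is_bnc`). `category` is one of `mono`, `bi`,
#'   `poly`, `bi_mn`, `oof`, `doublet`, `debris`; `is_bnc` marks the tiles a
#'   perfect binucleated-cell gate should accept (in-focus single
#'   binucleated, with or without micronuclei).
#' @export
generateTileSet <- function(preset, nTiles, seed,
                            spoilers = c(oof = 0.05, doublet = 0.05,
                                         debris = 0.05),
                            shape = c(128L, 128L), noiseFree = FALSE) {
  stopIfNot(is(preset, "ConditionPreset"), "preset must be a ConditionPreset")
  stopIfNot(nTiles >= 1, "nTiles must be >= 1")
  shape <- as.integer(shape)
  rMean <- preset@nucleusRadiusPx[1]
  mnR <- preset@mnRadiusRatio * rMean
  spo <- c(oof = 0, doublet = 0, debris = 0)
  spo[names(spoilers)] <- spoilers
  withLocalSeed(seed, {
    tiles <- vector("list", nTiles)
    labs <- vector("list", nTiles)
    centre <- (shape - 1) / 2
    for (t in seq_len(nTiles)) {
      u <- stats::runif(1)
      kind <- if (u < spo["oof"]) "oof"
      else if (u < spo["oof"] + spo["doublet"]) "doublet"
      else if (u < sum(spo)) "debris"
      else "cell"
      dna <- matrix(300, shape[1], shape[2])
      bf <- matrix(.TILE_BF_BG, shape[1], shape[2])
      cls <- NA_character_
      mnCount <- 0L
      nCells <- 1L
      inFocus <- kind != "oof"
      if (kind == "debris") {
        nspeck <- sample(2:5, 1)
        for (s in seq_len(nspeck)) {
          ps <- stats::runif(2, 20, shape - 20)
          rr <- stats::runif(1, 2, 5)
          dna[.ellipseIdx(ps[1], ps[2], rr, rr * 0.6, stats::runif(1, 0, pi),
                          shape)] <- stats::runif(1, 2500, 6000)
        }
        bf[.ellipseIdx(centre[1], centre[2], 12, 8, 0, shape)] <- 22000
        nCells <- 0L
      } else if (kind == "doublet") {
        th <- stats::runif(1, 0, pi)
        u2 <- c(cos(th), sin(th))
        off <- stats::runif(1, 22, 27)
        cls <- "doublet"
        for (s in c(-1, 1)) {
          c1 <- centre + s * off * u2
          cellCls <- sample(c("mono", "bi"), 1,
                            prob = preset@classFractions[c("mono", "bi")])
          res <- .renderTileCell(dna, c1, preset, cellCls, FALSE, rMean * 0.85,
                                 mnR)
          dna <- res$dna
          bf[.ellipseIdx(c1[1], c1[2], 2.1 * rMean * 0.85, 2.1 * rMean * 0.85,
                         0, shape)] <- .TILE_BF_CELL
        }
        nCells <- 2L
      } else {
        cls <- sample(c("mono", "bi", "poly"), 1, prob = preset@classFractions)
        withMN <- cls == "bi" && stats::runif(1) < preset@mnProbBi
        res <- .renderTileCell(dna, centre, preset, cls, withMN, rMean, mnR)
        dna <- res$dna
        mnCount <- res$mn_count
        bf[.ellipseIdx(centre[1], centre[2],
                       stats::runif(1, 2.2, 2.5) * rMean,
                       stats::runif(1, 2.0, 2.3) * rMean,
                       stats::runif(1, 0, pi), shape)] <- .TILE_BF_CELL
      }
      blur <- if (kind == "oof") 9 else preset@blurSigmaPx
      pScale <- if (noiseFree) 0 else preset@noisePoissonScale
      gSd <- if (noiseFree) 0 else preset@noiseGaussianSd
      dna <- .degradeImage(dna, blur, pScale, gSd)
      bf <- .degradeImage(bf, blur, pScale, gSd * 0.5)
      category <- if (kind == "cell") {
        if (!is.na(cls) && cls == "bi" && mnCount > 0) "bi_mn" else cls
      } else kind
      tiles[[t]] <- list(bf = bf, dna = dna)
      labs[[t]] <- data.frame(
        tile = t, category = category, class = cls, mn_count = mnCount,
        in_focus = inFocus, n_cells = nCells,
        is_bnc = kind == "cell" && !is.na(cls) && cls == "bi")
    }
    list(tiles = tiles, labels = do.call(rbind, labs))
  })
}
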