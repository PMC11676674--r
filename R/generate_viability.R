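# Synthetic MTT viability tables from a known 4PL dose-response.

#' Generate a synthetic concentration-viability table
#'
#' Viability (percent of control, T/C x 100 convention) is drawn from a
#' four-parameter logistic
#' `bottom + (top - bottom) / (1 + (c / ic50)^hill)` with Gaussian replicate
#' noise, clipped at 0. Deterministic given the seed.
#'
#' @param ic50 the midpoint concentration (same units as `concentrations`,
#'   conventionally microgram/mL).
#' @param hill Hill slope (> 0).
#' @param top,bottom upper/lower plateaus in percent.
#' @param concentrations positive concentrations (e.g. the classical
#'   two-fold 9.4-600 microgram/mL MTT series).
#' @param replicates replicates per concentration.
#' @param noiseSd Gaussian noise sd in percentage points (0 = noiseless).
#' @param seed integer seed.
#' @return `data.frame` with columns `concentration`, `replicate`,
#'   `viability`.
#' @examples
#' tab <- generateViabilityTable(228, 1.5, 100, 0,
#'                               concentrations = 9.375 * 2^(0:6),
#'                               replicates = 3, noiseSd = 0, seed = 1)
#' @export
generateViabilityTable <- function(ic50, hill, top, bottom, concentrations,
                                   replicates = 3, noiseSd = 5, seed) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  stopIfNot(ic50 > 0, "ic50 must be positive")
  withLocalSeed(seed, {
    grid <- expand.grid(replicate = seq_len(replicates),
                        concentration = concentrations)
    mu <- bottom + (top - bottom) / (1 + (grid$concentration / ic50)^hill)
    v <- mu + if (noiseSd > 0)
      stats::rnorm(nrow(grid), 0, noiseSd) else 0
    data.frame(concentration = grid$concentration,
               replicate = grid$replicate,
               viability = pmax(v, 0))
  })
}
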