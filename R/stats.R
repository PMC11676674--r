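# CBMN endpoints: cytotoxicity (cell-number and CBPI methods), micronucleus
# frequency under both denominator conventions, relative effects (fold change
# and percent reduction), 4-parameter-logistic IC50 fitting, and one-way
# ANOVA with Tukey multiple comparisons.

#' Percent cytotoxicity by the cell-number method
#'
#' `100 * (n_untreated - n_treated) / n_untreated`. May be negative (growth
#' stimulation); returned as-is.
#'
#' @param nUntreated untreated cell count (> 0).
#' @param nTreated treated cell count.
#' @return percent cytotoxicity.
#' @examples
#' cytotoxicityCN(400, 343)  # 14.25
#' @export
cytotoxicityCN <- function(nUntreated, nTreated) {
  if (any(nUntreated <= 0)) stop("untreated cell count must be positive")
  100 * (nUntreated - nTreated) / nUntreated
}

.asCounts <- function(counts) {
  if (is.data.frame(counts)) {
    stopIfNot(all(c("N1", "N2", "N3") %in% names(counts)),
              "counts need columns N1, N2, N3")
    counts <- c(sum(counts$N1), sum(counts$N2), sum(counts$N3))
  }
  stopIfNot(length(counts) == 3 && all(counts >= 0) &&
              all(counts == round(counts)),
            "counts must be three non-negative integers (N1, N2, N3)")
  as.numeric(counts)
}

#' Cytokinesis-block proliferation index
#'
#' `CBPI = (N1 + 2 N2 + 3 N3) / (N1 + N2 + N3)`: the average number of cell
#' cycles completed under cytochalasin-B block, between 1 (no division) and
#' 3. (A published form of this formula carries a stray 100x prefactor that
#' is dimensionally inconsistent with the cytostasis equation and with a
#' 1-3-cycle index; the plain ratio is used.)
#'
#' @param counts either `c(N1, N2, N3)` or a score table with columns
#'   `N1`, `N2`, `N3` (summed over rows).
#' @return the CBPI, in `[1, 3]`.
#' @examples
#' cbpi(c(59, 41, 0))  # 1.41
#' @export
cbpi <- function(counts) {
  counts <- .asCounts(counts)
  total <- sum(counts)
  if (total == 0) stop("CBPI undefined for zero total cells")
  sum(counts * c(1, 2, 3)) / total
}

#' Percent cytotoxicity by the CBPI method (cytostasis)
#'
#' `100 - 100 * (CBPI_treated - 1) / (CBPI_control - 1)`.
#'
#' @param treated,control counts as in [cbpi()].
#' @return percent cytostasis (0 for `treated == control`, 100 when the
#'   treated population did not divide at all).
#' @export
cytotoxicityCBPI <- function(treated, control) {
  cbpiT <- cbpi(treated)
  cbpiC <- cbpi(control)
  if (cbpiC <= 1)
    stop("control CBPI equals 1: cytostasis undefined (no divisions)")
  100 - 100 * (cbpiT - 1) / (cbpiC - 1)
}

#' Micronucleus frequency
#'
#' Pools field scores and computes the percentage of binucleated cells
#' carrying at least one micronucleus. Two denominator conventions are in
#' common use: per binucleated cell (the default, consistent with OECD
#' TG 487 scoring) and per total cells.
#'
#' @param scores `data.frame` of field scores with columns `N2` and
#'   `n_bi_with_mn` (plus `N1`, `N3` or `total_cells` for the per-total
#'   convention).
#' @param convention `"per_binucleated"` or `"per_total_cells"`.
#' @return object of class `MNFrequencyResult`: list with `freq_pct`,
#'   `denominator_convention`, `n_bi_with_mn`, `denominator`.
#' @examples
#' s <- data.frame(N1 = 0, N2 = 1000, N3 = 0, n_bi_with_mn = 56)
#' mnFrequency(s)$freq_pct  # 5.6
#' @export
mnFrequency <- function(scores, convention = c("per_binucleated",
                                               "per_total_cells")) {
  convention <- match.arg(convention)
  stopIfNot(all(c("N2", "n_bi_with_mn") %in% names(scores)),
            "scores need columns N2 and n_bi_with_mn")
  num <- sum(scores$n_bi_with_mn)
  den <- if (convention == "per_binucleated") {
    sum(scores$N2)
  } else if ("total_cells" %in% names(scores)) {
    sum(scores$total_cells)
  } else {
    stopIfNot(all(c("N1", "N3") %in% names(scores)),
              "per-total convention needs N1 and N3 (or total_cells)")
    sum(scores$N1) + sum(scores$N2) + sum(scores$N3)
  }
  if (den <= 0) stop("zero denominator in micronucleus frequency")
  res <- list(freq_pct = 100 * num / den, denominator_convention = convention,
              n_bi_with_mn = num, denominator = den)
  class(res) <- "MNFrequencyResult"
  res
}

#' @export
print.MNFrequencyResult <- function(x, ...) {
  cat(sprintf("MN frequency: %.3f%% (%d / %d, %s)\n", x$freq_pct,
              x$n_bi_with_mn, x$denominator, x$denominator_convention))
  invisible(x)
}

#' Fold change and percent reduction relative to the study controls
#'
#' `fold_vs_NC = freq / freq_NC`; `pct_reduction_vs_MMC = 100 * (freq_MMC -
#' freq) / freq_MMC` — the antigenotoxicity readouts (fold induction of the
#' positive control over the negative control; percent protection of a
#' combination treatment relative to the clastogen alone).
#'
#' @param summary `data.frame` with columns `condition` and `freq_pct`.
#' @param nc name of the negative-control row (default `"NC"`).
#' @param mmc name of the positive-control row (default `"MMC-0.025"`;
#'   `NULL` skips the reduction column).
#' @return the summary with `fold_vs_NC` and `pct_reduction_vs_MMC` added.
#' @export
relativeEffects <- function(summary, nc = "NC", mmc = "MMC-0.025") {
  stopIfNot(all(c("condition", "freq_pct") %in% names(summary)),
            "summary needs columns condition and freq_pct")
  if (!nc %in% summary$condition) stop("missing reference row: ", nc)
  fNC <- summary$freq_pct[summary$condition == nc][1]
  if (fNC <= 0) stop("reference frequencies must be positive")
  summary$fold_vs_NC <- summary$freq_pct / fNC
  if (!is.null(mmc)) {
    if (!mmc %in% summary$condition) stop("missing reference row: ", mmc)
    fMMC <- summary$freq_pct[summary$condition == mmc][1]
    if (fMMC <= 0) stop("reference frequencies must be positive")
    summary$pct_reduction_vs_MMC <- 100 * (fMMC - summary$freq_pct) / fMMC
  }
  summary
}

#' Fit a four-parameter logistic dose-response and extract the IC50
#'
#' Least-squares 4PL fit on log10 concentration:
#' `v = bottom + (top - bottom) / (1 + 10^(hill * (log10 c - log10 ic50rel)))`.
#' The fit is multi-started from three fixed initialisations (best SSE wins)
#' and is deterministic given the data. Two IC50 readings are reported: the
#' absolute crossing of 50% viability (`ic50`, the usual MTT convention) and
#' the 4PL relative midpoint (`ic50_rel`).
#'
#' @param viability `data.frame` with columns `concentration` and
#'   `viability` (percent of control); replicate rows welcome.
#' @return object of class `DoseResponseFit`: list with `ic50`, `ic50_rel`,
#'   `hill`, `top`, `bottom`, `residual_sd`, `fitted`
#'   (per-concentration fitted values).
#' @export
fitIC50 <- function(viability) {
  stopIfNot(all(c("concentration", "viability") %in% names(viability)),
            "viability table needs columns concentration and viability")
  v <- viability[viability$concentration > 0, ]
  if (length(unique(v$concentration)) < 4)
    stop("need >= 4 distinct positive concentrations")
  means <- tapply(v$viability, v$concentration, mean)
  if (diff(range(means)) < 10)
    stop("no dose response: viability span < 10 percentage points")
  lc <- log10(v$concentration)
  dat <- data.frame(lc = lc, y = v$viability)
  starts <- list(
    c(top = max(means), bottom = min(means), l50 = stats::median(lc), hill = 1),
    c(top = max(means), bottom = 0, l50 = unname(stats::quantile(lc, 0.25)),
      hill = 2),
    c(top = 100, bottom = 0, l50 = unname(stats::quantile(lc, 0.75)),
      hill = 0.7))
  best <- NULL
  bestSse <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - l50))),
        data = dat, start = as.list(st),
        lower = c(top = 10, bottom = -50, l50 = min(lc) - 2, hill = 0.1),
        upper = c(top = 200, bottom = 90, l50 = max(lc) + 2, hill = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (sse < bestSse) {
        bestSse <- sse
        best <- fit
      }
    }
  }
  if (is.null(best)) stop("4PL fit failed from all starts")
  p <- as.list(stats::coef(best))
  ic50rel <- 10^p$l50
  ic50abs <- if (p$bottom < 50 && p$top > 50) {
    10^(p$l50 + log10((p$top - p$bottom) / (50 - p$bottom) - 1) / p$hill)
  } else NA_real_
  fitted <- data.frame(
    concentration = sort(unique(v$concentration)))
  fitted$fitted_viability <- p$bottom + (p$top - p$bottom) /
    (1 + 10^(p$hill * (log10(fitted$concentration) - p$l50)))
  res <- list(ic50 = ic50abs, ic50_rel = ic50rel, hill = p$hill, top = p$top,
              bottom = p$bottom,
              residual_sd = sqrt(bestSse / max(1, nrow(dat) - 4)),
              fitted = fitted)
  class(res) <- "DoseResponseFit"
  res
}

#' @export
print.DoseResponseFit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: IC50 (absolute 50%%) = %.1f ; midpoint = %.1f ; hill = %.2f\n",
    x$ic50, x$ic50_rel, x$hill))
  cat(sprintf("  top = %.1f ; bottom = %.1f ; residual sd = %.2f\n",
              x$top, x$bottom, x$residual_sd))
  invisible(x)
}

#' One-way ANOVA with Tukey multiple comparisons against a control
#'
#' Standard one-way ANOVA over all groups followed by Tukey's HSD; reports
#' the family-adjusted p-value of each group against the named control
#' (homoscedastic normal model, as the use of Tukey's test implies).
#'
#' @param values `data.frame` with columns `condition` and `value`, or a
#'   named list of numeric vectors.
#' @param control name of the reference condition.
#' @return object of class `GroupComparison`: list with `F`, `p`, and
#'   `tukey` (`data.frame`: condition, diff, p_adj vs control).
#' @export
compareGroups <- function(values, control) {
  if (is.list(values) && !is.data.frame(values))
    values <- data.frame(
      condition = rep(names(values), lengths(values)),
      value = unlist(values, use.names = FALSE))
  stopIfNot(all(c("condition", "value") %in% names(values)),
            "values need columns condition and value")
  stopIfNot(control %in% values$condition, "control group not present")
  n <- table(values$condition)
  if (length(n) < 2) stop("need >= 2 groups")
  if (any(n < 2)) stop("every group needs >= 2 replicates")
  values$condition <- stats::relevel(factor(values$condition), ref = control)
  fit <- stats::aov(value ~ condition, data = values)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$condition
  vs <- grep(paste0("-", control, "$"), rownames(tk))
  tukey <- data.frame(
    condition = sub(paste0("-", control, "$"), "", rownames(tk)[vs]),
    diff = tk[vs, "diff"], p_adj = tk[vs, "p adj"], row.names = NULL)
  res <- list(F = an["condition", "F value"], p = an["condition", "Pr(>F)"],
              tukey = tukey)
  class(res) <- "GroupComparison"
  res
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.3g\n", x$F, x$p))
  print(x$tukey)
  invisible(x)
}
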