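# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG state
#'
#' Seeds the generator, evaluates, and restores the caller's RNG state, so
#' generator functions are deterministic given their `seed` argument and never
#' perturb the session stream.
#' @noRd
withLocalSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and a context
#'
#' Deterministic 32-bit-safe hash of the master seed and any number of
#' string/numeric context labels, so per-condition / per-replicate random
#' streams are independent of each other and of ordering.
#'
#' @param master master seed (integer).
#' @param ... context labels (condition names, replicate indices, ...).
#' @return an integer seed in [1, 2^31).
#' @export
childSeed <- function(master, ...) {
  key <- paste(c(as.character(master), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483563
  as.integer(h + 1L)
}

#' @noRd
.otsuThreshold <- function(x, levels = 256L) {
  # x in [0, 1]; returns the between-class-variance-maximising threshold
  b <- pmin(pmax(as.integer(x * levels) + 1L, 1L), levels)
  h <- as.numeric(tabulate(b, levels))
  n <- sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  w1 <- cumsum(h)
  m1 <- cumsum(h * mids)
  w2 <- n - w1
  mTot <- m1[levels]
  mu1 <- m1 / pmax(w1, 1)
  mu2 <- (mTot - m1) / pmax(w2, 1)
  between <- w1 * w2 * (mu1 - mu2)^2
  between[w1 == 0 | w2 == 0] <- -1
  which.max(between) / levels
}

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Intensity scale of the synthetic images (16-bit-like)
#' @noRd
.DYNAMIC_RANGE <- 65535
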