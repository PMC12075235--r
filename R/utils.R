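# Internal numerical helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generator calls do not
#' perturb the caller's RNG stream. A `NULL` seed leaves the stream alone.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Returns the complex analytic signal `x + i H(x)`: the FFT's positive
#' frequencies are doubled, negative frequencies zeroed, DC and Nyquist kept.
#' @param x numeric vector.
#' @return complex vector of `length(x)`.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("analytic_signal: need at least 2 samples")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' FFT band-pass filter with optional raised-cosine edges
#'
#' Zero gain outside `[lo, hi]` Hz (two-sided, symmetric); with
#' `taper_frac > 0` the band edges roll off over a raised-cosine
#' transition of that fraction of the bandwidth instead of a brick wall,
#' which makes the impulse response decay fast (a hard edge decays only
#' like 1/t and leaks spurious long-range correlation into amplitude
#' envelopes).
#' @noRd
fft_bandpass <- function(x, fs, lo, hi, taper_frac = 0) {
  n <- length(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  X <- stats::fft(x)
  if (taper_frac <= 0) {
    g <- as.numeric(f >= lo & f <= hi)
  } else {
    tw <- taper_frac * (hi - lo)
    g <- numeric(n)
    g[f >= lo & f <= hi] <- 1
    rise <- f >= lo - tw & f < lo
    g[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / tw))
    fall <- f > hi & f <= hi + tw
    g[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / tw))
  }
  Re(stats::fft(X * g, inverse = TRUE) / n)
}

#' Logarithmically spaced integer window sizes
#' @noRd
log_spaced_scales <- function(lo, hi, n) {
  s <- unique(round(exp(seq(log(lo), log(hi), length.out = n))))
  s[s >= 4L]
}

#' Half-open band membership on a frequency grid
#'
#' `lo <= f < hi` with a small tolerance so band edges that land exactly on
#' FFT bins (the 0.2 Hz design grid) are classified deterministically.
#' @noRd
band_index <- function(freqs, lo, hi) {
  eps <- 1e-9 * max(1, hi)
  freqs >= lo - eps & freqs < hi - eps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic 1-D two-means split
#'
#' Lloyd iteration on a scalar sample starting from the range midpoint;
#' returns the sorted cluster centers and the midpoint threshold.
#' @noRd
two_means <- function(v) {
  thr <- mean(range(v))
  for (i in 1:100) {
    lo <- v[v <= thr]; hi <- v[v > thr]
    if (!length(lo) || !length(hi)) break
    new_thr <- (mean(lo) + mean(hi)) / 2
    if (isTRUE(all.equal(new_thr, thr))) break
    thr <- new_thr
  }
  lo <- v[v <= thr]; hi <- v[v > thr]
  centers <- c(if (length(lo)) mean(lo) else min(v),
               if (length(hi)) mean(hi) else max(v))
  list(centers = centers, threshold = thr)
}
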