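# Time-averaged wavelet coherence between two channels.

# Analytic Morlet CWT (omega0 = 6) via FFT; returns time x scale matrix.
morlet_cwt <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  dt <- 1 / fs
  # Fourier factor relating Morlet scale to Fourier frequency
  ff <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  scales <- ff / (freqs * dt)
  omega <- 2 * pi * (seq_len(n) - 1L) / n
  omega[omega > pi] <- omega[omega > pi] - 2 * pi
  X <- stats::fft(x - mean(x))
  W <- matrix(0i, nrow = n, ncol = length(scales))
  for (k in seq_along(scales)) {
    s <- scales[k]                       # scale in samples; omega in rad/sample
    psi <- pi^(-1 / 4) * sqrt(2 * pi * s) *
      exp(-((s * omega) - omega0)^2 / 2) * (omega > 0)
    W[, k] <- stats::fft(X * psi, inverse = TRUE) / n
  }
  list(W = W, scales = scales)
}

# Smooth in time (Gaussian of width ~ scale) and across scales (boxcar
# spanning 0.6 octave), the standard smoothing for wavelet coherence.
# stats::filter drops imaginary parts, so complex matrices are smoothed
# component-wise.
smooth_wavelet <- function(M, scales, dt, voices) {
  if (is.complex(M))
    return(smooth_wavelet(Re(M), scales, dt, voices) +
             1i * smooth_wavelet(Im(M), scales, dt, voices))
  n <- nrow(M)
  out <- M
  for (k in seq_along(scales)) {
    s <- scales[k]
    half <- max(1L, ceiling(3 * s))
    t <- (-half):half
    g <- exp(-(t * dt)^2 / (2 * (s * dt)^2))
    g <- g / sum(g)
    padded <- c(rep(M[1L, k], half), M[, k], rep(M[n, k], half))
    out[, k] <- stats::filter(padded, g, sides = 2)[(half + 1L):(half + n)]
  }
  # scale smoothing: boxcar over ~0.6 octave
  wk <- max(1L, round(0.6 * voices))
  if (wk > 1L && length(scales) > wk) {
    box <- rep(1 / wk, wk)
    for (i in seq_len(n)) {
      row <- out[i, ]
      padded <- c(rep(row[1L], wk), row, rep(row[length(row)], wk))
      out[i, ] <- stats::filter(padded, box,
                                sides = 2)[(wk + 1L):(wk + length(row))]
    }
  }
  out
}

#' Time-averaged wavelet coherence profile of two signals
#'
#' Magnitude-squared wavelet coherence (analytic Morlet, `voices` scales
#' per octave) on a logarithmic 0.5-70 Hz grid, smoothed over time and
#' scale, then averaged over the time dimension; the peak frequency and
#' value are extracted from the resulting profile. Coherence is bounded
#' in [0, 1]; identical inputs give coherence 1 at every frequency.
#'
#' @param x,y numeric signals of equal length (>= 10 s).
#' @param fs sampling rate, Hz.
#' @param freq_range frequency range, Hz (default 0.5-70).
#' @param voices scales per octave (default 12).
#' @return list of class `"coherence_profile"`: `freqs`, `coherence`,
#'   `peak_freq`, `peak_value`.
#' @export
coherence_profile <- function(x, y, fs, freq_range = c(0.5, 70),
                              voices = 12) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (length(x) / fs < 10) stop("need at least 10 s of signal")
  hi <- min(freq_range[2], 0.98 * fs / 2)
  n_f <- ceiling(log2(hi / freq_range[1]) * voices) + 1L
  freqs <- freq_range[1] * 2^(seq(0, log2(hi / freq_range[1]),
                                  length.out = n_f))
  dt <- 1 / fs
  Wx <- morlet_cwt(x, fs, freqs)
  Wy <- morlet_cwt(y, fs, freqs)
  scales <- Wx$scales
  inv_s <- matrix(1 / scales, nrow = length(x), ncol = length(scales),
                  byrow = TRUE)
  Sxy <- smooth_wavelet(Wx$W * Conj(Wy$W) * inv_s, scales, dt, voices)
  Sxx <- Re(smooth_wavelet(Mod(Wx$W)^2 * inv_s, scales, dt, voices))
  Syy <- Re(smooth_wavelet(Mod(Wy$W)^2 * inv_s, scales, dt, voices))
  C <- Mod(Sxy)^2 / (Sxx * Syy)
  C[!is.finite(C)] <- 0
  C <- pmin(pmax(C, 0), 1)
  # trim the cone-of-influence edges before time-averaging
  prof <- vapply(seq_along(freqs), function(k) {
    e <- min(length(x) %/% 4L, max(1L, ceiling(2 * scales[k])))
    mean(C[(e + 1L):(length(x) - e), k])
  }, numeric(1))
  pk <- which.max(prof)
  structure(list(freqs = freqs, coherence = prof,
                 peak_freq = freqs[pk], peak_value = prof[pk]),
            class = "coherence_profile")
}
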