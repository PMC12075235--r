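# Detrended fluctuation analysis (long-range temporal correlations) and
# the functional excitation-inhibition ratio derived from it.

#' Detrended fluctuation analysis
#'
#' Integrates the mean-removed series, splits the profile into
#' non-overlapping windows at each scale, removes a least-squares linear
#' trend per window, and pools the residual RMS into the fluctuation
#' function F(s). The alpha exponent is the slope of log F versus log s
#' over 20 logarithmically spaced scales spanning 1-20% of the series
#' (interpretation: alpha = 0.5 white noise, alpha ~ 1 pink noise /
#' long-range memory, alpha < 0.5 anti-correlated).
#'
#' @param x numeric series (constant input is an error: F = 0 everywhere).
#' @param scales integer window sizes; default 20 log-spaced sizes from 1%
#'   to 20% of `length(x)`.
#' @param n_scales number of scales when `scales` is NULL.
#' @return list of class `"dfa_result"`: `scales`, `fluctuation`, `alpha`.
#' @examples
#' dfa_alpha(colored_noise(0, 10000, seed = 1))$alpha   # about 0.5
#' @export
dfa_alpha <- function(x, scales = NULL, n_scales = 20) {
  n <- length(x)
  if (stats::sd(x) == 0)
    stop("DFA undefined for a constant series (zero fluctuation)")
  scales <- scales %||%
    log_spaced_scales(max(4, round(0.01 * n)), round(0.20 * n), n_scales)
  if (length(scales) < 2) stop("need at least 2 usable scales")
  if (max(scales) * 2 > n) stop("series too short for the largest scale")
  y <- cumsum(x - mean(x))
  fl <- vapply(scales, function(s) {
    n_win <- floor(n / s)
    m <- matrix(y[seq_len(n_win * s)], nrow = s)
    t <- seq_len(s)
    qx <- qr(cbind(1, t))
    res <- qr.resid(qx, m)
    sqrt(mean(res^2))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(scales)), log(fl))
  structure(list(scales = scales, fluctuation = fl,
                 alpha = unname(fit$coefficients[2])),
            class = "dfa_result")
}

#' Per-frequency DFA of narrowband amplitude envelopes
#'
#' For each center frequency: narrowband filter at +/- 20% relative
#' bandwidth, amplitude envelope via the analytic signal, then
#' [dfa_alpha()] on the envelope. Bands reaching above Nyquist are
#' skipped with a message.
#'
#' @param x numeric signal (>= 60 s recommended per state).
#' @param fs sampling rate, Hz.
#' @param center_freqs center frequencies, Hz (default 14 log-spaced
#'   points over 0.5-70 Hz).
#' @param rel_bw relative half-bandwidth (default 0.2).
#' @return data.frame `center_freq`, `alpha`.
#' @export
banded_dfa <- function(x, fs, center_freqs = NULL, rel_bw = 0.2) {
  center_freqs <- center_freqs %||%
    exp(seq(log(0.5), log(70), length.out = 14))
  n <- length(x)
  out <- lapply(center_freqs, function(fc) {
    if (fc * (1 + rel_bw) >= fs / 2) {
      message(sprintf("band at %.3g Hz above Nyquist: skipped", fc))
      return(NULL)
    }
    env <- band_envelope(x, fs, fc, rel_bw)
    # the envelope of a band of width 2*rel_bw*fc decorrelates over about
    # 1/(2*rel_bw*fc) s; scales below ~5 correlation times only measure
    # the filter, so the smallest scale is floored there
    s_min <- max(round(0.01 * n), ceiling(5 * fs / (2 * rel_bw * fc)))
    s_max <- round(0.20 * n)
    if (s_min * 4 > s_max) {
      message(sprintf("band at %.3g Hz: too little data for DFA, skipped",
                      fc))
      return(NULL)
    }
    scales <- log_spaced_scales(s_min, s_max, 20)
    data.frame(center_freq = fc, alpha = dfa_alpha(env, scales)$alpha)
  })
  do.call(rbind, out)
}

band_envelope <- function(x, fs, center_freq, rel_bw = 0.2) {
  lo <- center_freq * (1 - rel_bw)
  hi <- center_freq * (1 + rel_bw)
  Mod(analytic_signal(fft_bandpass(x, fs, lo, hi, taper_frac = 0.25)))
}

#' Functional excitation-inhibition ratio (fE/I)
#'
#' On the narrowband amplitude envelope at `center_freq`: the signal
#' profile (integrated demeaned envelope) is cut into non-overlapping
#' windows; each window's detrended fluctuation is normalized by the
#' window's mean amplitude, and fE/I = 1 - Pearson r between the
#' normalized fluctuation and the amplitude across windows. Values above
#' 1 indicate excitation dominance, below 1 inhibition dominance. The
#' measure is only interpretable when the band shows long-range temporal
#' correlations, so when the envelope's DFA alpha is below 0.6 the result
#' is flagged invalid and carries no number.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param center_freq band center, Hz (+/- 20% bandwidth).
#' @param window_len window length, s (default 5; >= 10 windows required).
#' @param shuffle_amplitude surrogate mode: the amplitude series is
#'   permuted across windows (destroying the amplitude-fluctuation
#'   pairing) and the statistic is averaged over `n_shuffles` draws, so
#'   the surrogate fE/I converges to 1.
#' @param n_shuffles permutation draws for the surrogate (default 200).
#' @param seed seed for the surrogate shuffles.
#' @return list of class `"fei_result"`: `center_freq`, `fei` (NA when
#'   invalid), `valid`, `alpha`, and the per-window `amplitude` /
#'   `fluctuation` vectors.
#' @export
fei <- function(x, fs, center_freq, window_len = 5,
                shuffle_amplitude = FALSE, n_shuffles = 200, seed = NULL) {
  env <- band_envelope(x, fs, center_freq)
  alpha <- dfa_alpha(env)$alpha
  w <- round(window_len * fs)
  n_win <- floor(length(env) / w)
  if (n_win < 10) stop("need at least 10 windows for fE/I")
  prof <- cumsum(env - mean(env))
  amp <- numeric(n_win); fl <- numeric(n_win)
  t <- seq_len(w); qx <- qr(cbind(1, t))
  for (k in seq_len(n_win)) {
    idx <- (k - 1L) * w + seq_len(w)
    amp[k] <- mean(env[idx])
    res <- qr.resid(qx, prof[idx] / amp[k])
    fl[k] <- sqrt(mean(res^2))
  }
  valid <- alpha >= 0.6
  val <- if (!valid) NA_real_
  else if (shuffle_amplitude) {
    with_seed(seed, mean(vapply(seq_len(n_shuffles), function(i)
      fei_from_windows(fl, sample(amp)), numeric(1))))
  } else fei_from_windows(fl, amp)
  structure(list(center_freq = center_freq, fei = val,
                 valid = valid, alpha = alpha,
                 amplitude = amp, fluctuation = fl),
            class = "fei_result")
}

#' fE/I from precomputed per-window fluctuation and amplitude
#'
#' `1 - cor(fluctuation, amplitude)`; exposed so surrogate constructions
#' can be tested directly.
#' @param fluctuation,amplitude numeric vectors of equal length.
#' @export
fei_from_windows <- function(fluctuation, amplitude) {
  1 - stats::cor(fluctuation, amplitude)
}
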