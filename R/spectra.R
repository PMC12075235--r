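# Epoch segmentation and spectral estimation.
#
# The scorer's sole per-epoch input is the magnitude-squared FFT of the
# mean-removed epoch. Epochs are zero-padded to a 5 s equivalent so the
# frequency resolution is 0.2 Hz regardless of epoch length (0.5/1/5 s),
# which puts every rule-band edge (0.2, 3, 3.2, 6, 6.2, 10, 12, 20, 24 Hz)
# exactly on an FFT bin.

#' Cut a recording into contiguous scoring epochs
#'
#' Epochs are contiguous and non-overlapping from sample 1; a trailing
#' partial epoch is discarded (with a message).
#'
#' @param rec a [recording()] or a total sample count.
#' @param epoch_len epoch length in seconds.
#' @param fs sampling rate, required when `rec` is a sample count.
#' @return list of class `"epoch_grid"`: `epoch_len`, `n_epochs`,
#'   `samples_per_epoch`, `starts` (1-based sample offsets), `fs`.
#' @export
segment_epochs <- function(rec, epoch_len, fs = NULL) {
  if (inherits(rec, "recording")) {
    n <- ncol(rec$signal); fs <- rec$fs
  } else {
    n <- rec
    if (is.null(fs)) stop("fs required when rec is a sample count")
  }
  spe <- round(epoch_len * fs)
  if (spe < 2) stop("epoch_len x fs must be at least 2 samples")
  n_ep <- floor(n / spe)
  if (n_ep < 1) stop("recording shorter than one epoch: empty grid")
  if (n_ep * spe < n)
    message(sprintf("dropping trailing partial epoch (%d samples)",
                    n - n_ep * spe))
  structure(list(epoch_len = epoch_len, n_epochs = n_ep,
                 samples_per_epoch = spe,
                 starts = (seq_len(n_ep) - 1L) * spe + 1L, fs = fs),
            class = "epoch_grid")
}

#' Per-epoch FFT power spectrum
#'
#' Mean-removed, zero-padded to at least `fs / resolution` samples
#' (default resolution 0.2 Hz), no taper; power is the one-sided
#' magnitude-squared FFT.
#'
#' @param x numeric vector (one epoch of signal).
#' @param fs sampling rate, Hz.
#' @param resolution target frequency resolution, Hz (<= 0.2 by default).
#' @return list of class `"epoch_spectrum"` with `freqs` (Hz, strictly
#'   increasing) and `power` (same length, >= 0, arbitrary units).
#' @export
epoch_power_spectrum <- function(x, fs, resolution = 0.2) {
  if (!all(is.finite(x)))
    stop("epoch contains non-finite samples: spectrum undefined")
  n <- length(x)
  nfft <- max(n, ceiling(fs / resolution))
  xp <- c(x - mean(x), numeric(nfft - n))
  X <- stats::fft(xp)
  half <- seq_len(floor(nfft / 2) + 1L)
  structure(list(freqs = (half - 1L) * fs / nfft,
                 power = Mod(X[half])^2),
            class = "epoch_spectrum")
}

#' Summed power over a half-open frequency band
#'
#' Band membership is half-open, `lo <= f < hi`, so adjacent rule bands
#' never double-count a bin.
#'
#' @param sp an `"epoch_spectrum"`.
#' @param lo,hi band edges in Hz (`lo < hi`).
#' @return list of class `"band_power"`: `lo`, `hi`, `value` (a.u., >= 0).
#' @export
band_power <- function(sp, lo, hi) {
  stopifnot(lo < hi)
  idx <- band_index(sp$freqs, lo, hi)
  if (!any(idx)) stop(sprintf("no spectral bins in [%g, %g) Hz", lo, hi))
  structure(list(lo = lo, hi = hi, value = sum(sp$power[idx])),
            class = "band_power")
}

# Bare-number convenience used throughout the scorer.
bp <- function(sp, lo, hi) band_power(sp, lo, hi)$value

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-tapered segments with 50% overlap,
#' scaled to one-sided power per Hz (white noise of variance 1 gives a
#' flat density of 2/fs).
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param seg_len segment length in seconds (default 2).
#' @return an `"epoch_spectrum"` whose `power` is density (a.u.^2 / Hz).
#' @export
welch_psd <- function(x, fs, seg_len = 2) {
  nper <- round(seg_len * fs)
  n <- length(x)
  if (n < 2 * nper)
    stop("signal too short for Welch segmentation (need >= 2 segments)")
  step <- floor(nper / 2)
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nper) - 1L) / (nper - 1L))
  u <- sum(w^2)
  half <- seq_len(floor(nper / 2) + 1L)
  acc <- numeric(length(half))
  for (s in starts) {
    seg <- x[s + seq_len(nper) - 1L]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg)[half])^2 / (u * fs)
    acc <- acc + P
  }
  P <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- rep(2, length(half)); dbl[1] <- 1
  if (nper %% 2 == 0) dbl[length(half)] <- 1
  structure(list(freqs = (half - 1L) * fs / nper, power = P * dbl),
            class = "epoch_spectrum")
}

#' Export a spectrum as a two-column CSV (freq, power)
#' @param sp an `"epoch_spectrum"`.
#' @param path output file.
#' @export
write_spectrum_csv <- function(sp, path) {
  utils::write.csv(data.frame(freq = sp$freqs, power = sp$power),
                   path, row.names = FALSE)
  invisible(path)
}
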