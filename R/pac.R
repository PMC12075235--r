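# Phase-amplitude coupling with permutation normalization (PACz).

#' Permutation-normalized phase-amplitude coupling (PACz)
#'
#' For each (phase frequency, amplitude frequency) pair: the phase series
#' comes from the analytic signal of the narrowband-filtered low
#' frequency, the amplitude series from the envelope at the high
#' frequency; the raw coupling is the mean-vector modulation index
#' `|mean(A * exp(i * phi))|`. The null distribution is built from
#' `n_perm` circular time shifts of the phase series (shift drawn
#' uniformly away from the edges, seeded), which preserves both marginal
#' distributions, and PACz is the z-score of the observed value against
#' that null.
#'
#' @param x numeric signal, a single-state segment of >= 10 s.
#' @param fs sampling rate, Hz.
#' @param phase_freqs low-frequency grid, Hz (default 1-15 in 1 Hz steps).
#' @param amp_freqs high-frequency grid, Hz (default 30,35,40,45,50).
#' @param n_perm number of circular-shift permutations (default 100).
#' @param seed integer seed; fixed seed gives bit-reproducible output.
#' @param phase_bw half-bandwidth of the phase filter, Hz (default 1).
#' @param amp_bw half-bandwidth of the amplitude filter, Hz (default 8,
#'   wide enough to pass modulation sidebands of all phase frequencies).
#' @return list of class `"pacz_result"`: `phase_freqs`, `amp_freqs`,
#'   `pacz` (matrix, phase x amplitude), `pac` (raw), `n_perm`,
#'   `max_phase_freq`, `max_value`.
#' @examples
#' x <- pac_signal(4, 40, depth = 0.8, n = 20 * 250, fs = 250, seed = 2)
#' z <- pacz(x, 250, phase_freqs = c(2, 4, 6), amp_freqs = 40, seed = 2)
#' z$max_phase_freq
#' @export
pacz <- function(x, fs, phase_freqs = 1:15,
                 amp_freqs = c(30, 35, 40, 45, 50),
                 n_perm = 100, seed = 1, phase_bw = 1, amp_bw = 8) {
  n <- length(x)
  if (n / fs < 5 / min(phase_freqs))
    stop("segment too short: need >= 5 cycles of the lowest phase frequency")
  margin <- round(fs)
  if (n <= 2 * margin) stop("segment too short for circular-shift null")
  shifts <- with_seed(seed,
                      sample.int(n - 2L * margin, n_perm, replace = TRUE) +
                        margin)
  amps <- lapply(amp_freqs, function(fa)
    Mod(analytic_signal(fft_bandpass(x, fs, fa - amp_bw, fa + amp_bw))))
  z <- matrix(NA_real_, length(phase_freqs), length(amp_freqs),
              dimnames = list(phase_freqs, amp_freqs))
  raw <- z
  for (i in seq_along(phase_freqs)) {
    fp <- phase_freqs[i]
    lo <- max(0.1, fp - phase_bw)
    ph <- Arg(analytic_signal(fft_bandpass(x, fs, lo, fp + phase_bw)))
    E <- exp(1i * ph)
    for (j in seq_along(amps)) {
      A <- amps[[j]]
      obs <- Mod(mean(A * E))
      null <- vapply(shifts, function(s)
        Mod(mean(A * E[c((s + 1L):n, 1:s)])), numeric(1))
      raw[i, j] <- obs
      z[i, j] <- (obs - mean(null)) / stats::sd(null)
    }
  }
  peak <- which(z == max(z), arr.ind = TRUE)[1L, ]
  structure(list(phase_freqs = phase_freqs, amp_freqs = amp_freqs,
                 pacz = z, pac = raw, n_perm = n_perm,
                 max_phase_freq = phase_freqs[peak[1L]],
                 max_value = max(z)),
            class = "pacz_result")
}
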