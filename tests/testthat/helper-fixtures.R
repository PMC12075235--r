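# Shared fixtures: hand-built spectra and an independent transcription of
# the printed state-definition rules used as a brute-force oracle.

# A spectrum on a 0.2 Hz grid with power mass placed by hand.
make_spectrum <- function(freqs, power) {
  structure(list(freqs = freqs, power = power), class = "epoch_spectrum")
}

# Spectrum whose half-open band sums equal the requested values: all mass
# of each band is put on its first bin.
spectrum_with_bands <- function(delta = 0, theta = 0, alpha = 0,
                                rem_hi = 0, hf = 0, extra_freq = NULL,
                                extra_power = 0) {
  freqs <- seq(0.2, 69.8, by = 0.2)
  power <- numeric(length(freqs))
  put <- function(f, v) {
    i <- which.min(abs(freqs - f))
    power[i] <<- power[i] + v
  }
  if (delta > 0) put(0.6, delta)     # inside [0.2, 3)
  if (theta > 0) put(3.2, theta)     # inside [3.2, 6)
  if (alpha > 0) put(10.4, alpha)    # inside [6.2, 12) but outside [6, 10)
  if (rem_hi > 0) put(6.4, rem_hi)   # inside [6, 10) and [6.2, 12)
  if (hf > 0) put(20.2, hf)          # inside [20, 24)
  if (!is.null(extra_freq)) put(extra_freq, extra_power)
  make_spectrum(freqs, power)
}

# Independent brute-force evaluation of the printed per-epoch rules,
# written directly from the state-definition table (no package band
# helpers): noise bounds on total 0.5-70 Hz power; awake argmax over
# 0.2-3 / 3.2-6 / 6.2-12 (ties to the higher band); REM when 6-10 power
# exceeds 0.2-6; otherwise the 0.2-12 over 20-24 ratio ladder at 20 / 10.
oracle_score <- function(freqs, power, macro, noise_low, noise_high) {
  s <- function(lo, hi) sum(power[freqs >= lo - 1e-9 & freqs < hi - 1e-9])
  if (any(!is.finite(power))) return("N")
  tot <- s(0.5, 70)
  if (tot < noise_low || tot > noise_high) return("N")
  if (macro == "tense") {
    v <- c(a = s(0.2, 3), b = s(3.2, 6), c = s(6.2, 12))
    return(names(v)[max(which(v == max(v)))])
  }
  if (s(6, 10) > s(0.2, 6)) return("l")
  den <- s(20, 24)
  r <- if (den == 0) Inf else s(0.2, 12) / den
  if (r > 20) "m" else if (r > 10) "n" else "o"
}

# Random rule-engine configuration used by the oracle-equivalence checks.
random_rule_case <- function() {
  freqs <- seq(0.2, 69.8, by = 0.2)
  power <- stats::rexp(length(freqs)) *
    stats::rbinom(length(freqs), 1, 0.3) * 10^stats::runif(1, -2, 2)
  macro <- sample(c("tense", "relaxed"), 1)
  tot <- sum(power[freqs >= 0.5 - 1e-9 & freqs < 70 - 1e-9])
  # bounds sometimes triggered, sometimes not
  noise_low <- if (stats::runif(1) < 0.2) tot * stats::runif(1, 0.5, 2) else 0
  noise_high <- if (stats::runif(1) < 0.2) tot * stats::runif(1, 0.5, 2) else Inf
  if (noise_low >= noise_high) noise_low <- 0
  list(freqs = freqs, power = power, macro = macro,
       noise_low = noise_low, noise_high = noise_high)
}
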