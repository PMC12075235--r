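# DFA -----------------------------------------------------------------------

test_that("DFA separates white, pink, and anti-correlated noise", {
  alphas <- sapply(1:3, function(s) c(
    white = dfa_alpha(colored_noise(0, 2e4, seed = s))$alpha,
    pink = dfa_alpha(colored_noise(1, 2e4, seed = s))$alpha,
    anti = dfa_alpha(diff(colored_noise(0, 2e4 + 1, seed = s)))$alpha))
  m <- rowMeans(alphas)
  expect_equal(unname(m["white"]), 0.5, tolerance = 0.12)
  expect_equal(unname(m["pink"]), 1.0, tolerance = 0.12)
  expect_lt(m["anti"], 0.5)
  expect_error(dfa_alpha(rep(1, 1000)), "constant")
})

test_that("DFA alpha is monotone in the spectral exponent", {
  betas <- c(0, 0.5, 1, 1.5)
  a <- sapply(betas, function(b)
    mean(sapply(1:3, function(s)
      dfa_alpha(colored_noise(b, 2e4, seed = 10 * s + b * 100))$alpha)))
  expect_true(all(diff(a) > 0))
})

test_that("banded DFA sees no long-range correlation in white noise", {
  x <- colored_noise(0, 200 * 128, 128, seed = 5)
  ba <- banded_dfa(x, 128, center_freqs = c(5, 10, 30))
  expect_equal(ba$alpha, rep(0.5, 3), tolerance = 0.12)
  expect_error(dfa_alpha(rnorm(50), scales = c(100, 500)), "too short")
})

test_that("banded DFA recovers an imposed envelope exponent at its band", {
  fs <- 128
  t <- (0:(200 * fs - 1)) / fs
  menv <- colored_noise(0.6, length(t), fs, seed = 7)   # H = 0.8 envelope
  env0 <- 1 + 0.8 * (menv - min(menv)) / (max(menv) - min(menv))
  x <- env0 * sin(2 * pi * 10 * t) + 0.1 * rnorm(length(t))
  ba <- banded_dfa(x, fs, center_freqs = 10)
  expect_equal(ba$alpha, 0.8, tolerance = 0.15)
})

test_that("bands above Nyquist are skipped with a message", {
  x <- colored_noise(0, 100 * 64, 64, seed = 1)
  expect_message(ba <- banded_dfa(x, 64, center_freqs = c(10, 50)),
                 "Nyquist")
  expect_equal(nrow(ba), 1)
})

# fE/I -----------------------------------------------------------------------

fei_fixture <- function(seed = 9, dur = 300, fs = 128) {
  t <- (0:(dur * fs - 1)) / fs
  menv <- colored_noise(0.6, length(t), fs, seed = seed)
  env0 <- 1 + 0.8 * (menv - min(menv)) / (max(menv) - min(menv))
  env0 * sin(2 * pi * 10 * t) + 0.05 * rnorm(length(t))
}

test_that("fE/I is 1 - r and shuffling amplitude pushes it to 1", {
  expect_equal(fei_from_windows(c(1, 2, 3, 4), c(4, 3, 2, 1)), 2)
  set.seed(4)
  fl <- rnorm(100)
  am <- 0.3 * fl + sqrt(1 - 0.09) * rnorm(100)
  expect_equal(fei_from_windows(fl, am), 1 - cor(fl, am))

  set.seed(2)
  x <- fei_fixture()
  fr <- fei(x, 128, 10)
  expect_true(fr$valid)
  frs <- fei(x, 128, 10, shuffle_amplitude = TRUE, seed = 1)
  expect_equal(frs$fei, 1, tolerance = 0.05)
})

test_that("fE/I is invalid (no number) when alpha is below 0.6", {
  x <- colored_noise(0, 120 * 128, 128, seed = 21)
  fr <- fei(x, 128, 20)                     # white noise envelope: alpha ~ 0.5
  expect_lt(fr$alpha, 0.6)
  expect_false(fr$valid)
  expect_true(is.na(fr$fei))
})

# PACz -----------------------------------------------------------------------

test_that("PACz localizes constructed coupling and is seed-reproducible", {
  x <- pac_signal(4, 40, depth = 0.8, n = 30 * 256, fs = 256, seed = 5)
  z <- pacz(x, 256, phase_freqs = 1:8, amp_freqs = c(35, 40), seed = 5)
  expect_lt(abs(z$max_phase_freq - 4), 1.1)
  expect_gt(z$max_value, 3)
  z2 <- pacz(x, 256, phase_freqs = 1:8, amp_freqs = c(35, 40), seed = 5)
  expect_identical(z$pacz, z2$pacz)
})

test_that("constant amplitude with uniform phase cancels the PAC vector", {
  fs <- 128
  t <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * 40 * t) + sin(2 * pi * 4 * t)
  ph <- Arg(vigiscore:::analytic_signal(sin(2 * pi * 4 * t)))
  A <- rep(1, length(t))
  expect_lt(Mod(mean(A * exp(1i * ph))), 0.02)
})

test_that("PACz rejects segments too short for the phase band", {
  expect_error(pacz(rnorm(256), 256, phase_freqs = 1), "too short")
})

# Aperiodic ------------------------------------------------------------------

test_that("the aperiodic fit is exact on pure power laws", {
  f <- seq(0.5, 65, by = 0.5)
  expect_equal(aperiodic_exponent(
    make_spectrum(f, 10 / f^2))$exponent, 2, tolerance = 1e-10)
  expect_equal(aperiodic_exponent(
    make_spectrum(f, rep(3, length(f))))$exponent, 0, tolerance = 1e-10)
  expect_error(aperiodic_exponent(make_spectrum(f, c(-1, 10 / f[-1]))),
               "nonpositive")
})

test_that("an additive Gaussian peak does not bias the aperiodic fit", {
  f <- seq(0.5, 65, by = 0.5)
  for (b in c(0, 1, 1.5, 2)) {
    bg <- 10 / f^b
    peak <- 5 * (10 / 10^b) * exp(-(f - 10)^2 / (2 * 1.5^2))
    fit <- aperiodic_exponent(make_spectrum(f, bg + peak))
    expect_equal(fit$exponent, b, tolerance = 0.1)
  }
})

# Spindles -------------------------------------------------------------------

test_that("spindle detection recalls injected bursts and honors durations", {
  fs <- 128
  bg <- 0.5 * colored_noise(0, 600 * fs, fs, seed = 3)
  times <- c(10, 50, 100, 200, 400)
  ev <- detect_spindles(inject_spindles(bg, fs, times, dur = 1, amp = 3), fs)
  mids <- times + 0.5
  hits <- vapply(mids, function(m)
    any(ev$start <= m & ev$end >= m), logical(1))
  expect_true(all(hits))
  expect_true(all(ev$duration >= 0.5 & ev$duration <= 2))
  expect_true(all(ev$peak_z > 3.5))

  short <- detect_spindles(
    inject_spindles(bg, fs, 100, dur = 0.2, amp = 3), fs)
  expect_false(any(short$start <= 100.2 & short$end >= 100))
  long <- detect_spindles(inject_spindles(bg, fs, 100, dur = 3, amp = 3), fs)
  expect_false(any(long$start <= 103 & long$end >= 100))
})

test_that("the background false-positive rate stays within its bound", {
  fs <- 128
  fp <- sapply(1:3, function(s)
    nrow(detect_spindles(colored_noise(0, 600 * fs, fs, seed = s), fs)))
  expect_lte(max(fp), 2)              # <= 0.2 events/min on 10-min noise
  expect_warning(ev0 <- detect_spindles(numeric(40 * fs), fs), "flat")
  expect_equal(nrow(ev0), 0)
})

# Per-state PSD --------------------------------------------------------------

test_that("state-average PSD matches whole-signal Welch when uniform", {
  fs <- 128
  x <- colored_noise(1, 120 * fs, fs, seed = 6)
  L <- label_sequence(rep("m", 120), 1)
  ps <- state_average_psd(x, L, "m", fs)
  pw <- welch_psd(x, fs)
  keep <- pw$freqs >= 9 & pw$freqs <= 16
  expect_equal(ps$power, pw$power[keep])
  expect_error(state_average_psd(x, L, "o", fs), "no epochs")
})

test_that("spindle-rich sleep lifts the 10-12 Hz band over spindle-free", {
  sim <- synth_recording(
    state_schedule(c("nREM1", "nREM3"), c(120, 120)), fs = 128, seed = 13)
  x <- sim$recording$signal[1, ]
  p1 <- state_average_psd(x, sim$labels, "m", 128)
  p3 <- state_average_psd(x, sim$labels, "o", 128)
  band <- p1$freqs >= 10 & p1$freqs <= 12
  expect_gt(mean(p3$power[band]), mean(p1$power[band]))
})

# Coherence ------------------------------------------------------------------

test_that("wavelet coherence is bounded, unit on self, low on independents", {
  fs <- 128
  set.seed(1)
  x <- rnorm(20 * fs); y <- rnorm(20 * fs)
  cs <- coherence_profile(x, x, fs)
  expect_true(all(cs$coherence > 0.99))
  cn <- coherence_profile(x, y, fs)
  expect_true(all(cn$coherence >= 0 & cn$coherence <= 1))
  expect_lt(mean(cn$coherence), 0.5)
  expect_error(coherence_profile(x, y[-1], fs), "equal length")
})

test_that("a shared 8 Hz component puts the coherence peak at 8 Hz", {
  fs <- 128
  n <- 20 * fs
  sh <- sin(2 * pi * 8 * (0:(n - 1)) / fs)
  set.seed(2)
  cp <- coherence_profile(rnorm(n) + sh, rnorm(n) + sh, fs)
  expect_lt(abs(cp$peak_freq - 8), 0.5)
  expect_equal(cp$peak_value, max(cp$coherence))
})
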