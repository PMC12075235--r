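th0 <- rule_thresholds(noise_low = 0, noise_high = Inf)

test_that("the noise test brackets total power and catches bad spectra", {
  f <- seq(0.2, 69.8, by = 0.2)
  zero <- make_spectrum(f, numeric(length(f)))
  expect_true(is_noise(zero, rule_thresholds(1e-6, Inf)))
  mid <- make_spectrum(f, rep(1, length(f)))
  expect_false(is_noise(mid, rule_thresholds(1, 1e6)))
  expect_true(is_noise(make_spectrum(f, rep(1e6, length(f))),
                       rule_thresholds(1, 1e6)))
  bad <- make_spectrum(f, c(NaN, rep(1, length(f) - 1)))
  expect_true(is_noise(bad, rule_thresholds(0, Inf)))
})

test_that("awake substates follow the band-sum argmax with high-band ties", {
  expect_equal(classify_awake(spectrum_with_bands(5, 1, 2), th0), "a")
  expect_equal(classify_awake(spectrum_with_bands(1, 4, 2), th0), "b")
  expect_equal(classify_awake(spectrum_with_bands(2, 1, 2), th0), "c")
  expect_equal(classify_awake(spectrum_with_bands(3, 3, 1), th0), "b")
})

test_that("sleep substates follow the REM test then the ratio ladder", {
  # REM: power 6-10 exceeds 0.2-6
  expect_equal(classify_sleep(spectrum_with_bands(delta = 3, rem_hi = 5),
                              th0), "l")
  # ratio r = 50/2 = 25 > 20
  expect_equal(classify_sleep(spectrum_with_bands(delta = 50, hf = 2),
                              th0), "m")
  # r = 15 and r = 8
  expect_equal(classify_sleep(spectrum_with_bands(delta = 30, hf = 2),
                              th0), "n")
  expect_equal(classify_sleep(spectrum_with_bands(delta = 16, hf = 2),
                              th0), "o")
  # exact boundaries: closed at 20 (deeper label), open at 10
  expect_equal(classify_sleep(spectrum_with_bands(delta = 40, hf = 2),
                              th0), "n")
  expect_equal(classify_sleep(spectrum_with_bands(delta = 20, hf = 2),
                              th0), "o")
  # zero denominator: ratio infinite, slow-wave sleep
  expect_equal(classify_sleep(spectrum_with_bands(delta = 5), th0), "m")
})

test_that("noise precedes the macro gate and 'U' is never emitted", {
  f <- seq(0.2, 69.8, by = 0.2)
  loud <- make_spectrum(f, rep(1e9, length(f)))
  expect_equal(score_epoch(loud, "tense", rule_thresholds(1, 1e6)), "N")
  expect_equal(score_epoch(spectrum_with_bands(1, 1, 5), "tense", th0), "c")
  expect_equal(score_epoch(spectrum_with_bands(delta = 2, rem_hi = 4),
                           "relaxed", th0), "l")
})

test_that("sub-labels are invariant under positive rescaling", {
  set.seed(5)
  for (i in 1:200) {
    cs <- random_rule_case()
    sp <- make_spectrum(cs$freqs, cs$power)
    sc <- make_spectrum(cs$freqs, cs$power * runif(1, 0.01, 100))
    expect_identical(score_epoch(sp, cs$macro, th0),
                     score_epoch(sc, cs$macro, th0))
  }
})

test_that("the rule engine matches an independent brute-force oracle", {
  set.seed(99)
  for (i in 1:2000) {
    cs <- random_rule_case()
    th <- rule_thresholds(cs$noise_low, cs$noise_high)
    got <- score_epoch(make_spectrum(cs$freqs, cs$power), cs$macro, th)
    want <- oracle_score(cs$freqs, cs$power, cs$macro,
                         cs$noise_low, cs$noise_high)
    expect_identical(got, want)
  }
})

test_that("a zero recording scores all noise and never drops an epoch", {
  rec <- recording(matrix(0, nrow = 2, ncol = 128 * 20), fs = 128,
                   channels = data.frame(name = c("e", "m"),
                                         role = c("EEG", "EMG")))
  lab <- suppressMessages(score_recording(rec, scoring_config(target_fs = 128)))
  expect_equal(lab$n_epochs, 20)
  expect_true(all(lab$labels == "N"))
})

test_that("awake labels stay in tense segments and sleep labels in relaxed", {
  sim <- synth_recording(seed = 21)
  lab <- suppressMessages(score_recording(
    sim$recording, scoring_config(target_fs = 256), diagnostics = TRUE))
  d <- attr(lab, "diagnostics")
  expect_true(all(d$label[d$macro == "tense"] %in% c("a", "b", "c", "N")))
  expect_true(all(d$label[d$macro == "relaxed"] %in%
                  c("l", "m", "n", "o", "N")))
})
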