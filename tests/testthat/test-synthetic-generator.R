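test_that("colored noise is seeded, standardized, and slope-faithful", {
  expect_identical(colored_noise(1, 1024, 128, seed = 4),
                   colored_noise(1, 1024, 128, seed = 4))
  expect_error(colored_noise(0, 8), ">= 16")
  expect_error(colored_noise(5, 1024), "beta")

  w <- colored_noise(0, 2e4, seed = 1)
  expect_lt(abs(cor(w[-1], w[-length(w)])), 0.03)   # lag-1 autocorrelation

  br <- colored_noise(2, 2^15, 1, seed = 2)
  pg <- welch_psd(br, 1, seg_len = 4096)
  sel <- pg$freqs > 0.01 & pg$freqs < 0.4
  slope <- unname(coef(lm(log(pg$power[sel]) ~ log(pg$freqs[sel])))[2])
  expect_equal(slope, -2, tolerance = 0.25)
})

test_that("every default recipe satisfies its own scoring rule", {
  for (st in names(default_recipes())) {
    expect_gte(recipe_self_check(st, fs = 256, n_draws = 100, seed = 2),
               0.95)
  }
})

test_that("schedules validate durations and round-trip as CSV", {
  expect_error(state_schedule("a1", -5), "durations > 0")
  expect_error(state_schedule("dozing", 10), "unknown state")
  sched <- default_schedule()
  expect_equal(sum(sched$duration_s), 600)
  p <- file.path(withr::local_tempdir(), "sched.csv")
  write_schedule(sched, p)
  expect_equal(read_schedule(p)$state, sched$state)
})

test_that("synthetic recordings are deterministic with ground truth attached", {
  sched <- state_schedule(c("a1", "nREM1"), c(20, 20))
  s1 <- synth_recording(sched, fs = 128, seed = 7)
  s2 <- synth_recording(sched, fs = 128, seed = 7)
  expect_identical(s1$recording$signal, s2$recording$signal)
  expect_equal(s1$labels$n_epochs, 40)
  expect_equal(s1$labels$labels, rep(c("a", "m"), each = 20))
  expect_equal(nrow(s1$recording$signal), 3)       # 2 EEG + 1 EMG
})

test_that("an all-sleep schedule yields one relaxed macro-segment", {
  sim <- synth_recording(state_schedule("nREM1", 60), fs = 128, seed = 9)
  emg <- sim$recording$signal[3, ]
  env <- emg_summary(emg, 128)
  seg <- detect_tone_changepoints(env)
  expect_equal(nrow(seg$segments), 1)
  expect_equal(seg$segments$state, "relaxed")
})

test_that("spindle injection is exact, bounded, and refuses overlap", {
  x <- numeric(128 * 60)
  expect_identical(inject_spindles(x, 128, times = 10, amp = 0), x)
  y <- inject_spindles(x, 128, times = c(5, 20), dur = 1, amp = 2)
  expect_equal(max(abs(y)), 2, tolerance = 0.01)    # Hann peak
  expect_true(all(y[1:(128 * 4)] == 0))             # untouched outside bursts
  expect_error(inject_spindles(x, 128, times = c(5, 5.5)), "overlap")
  expect_error(inject_spindles(x, 128, times = 59.9), "bounds")
})

test_that("pac_signal validates its frequencies and depth", {
  expect_error(pac_signal(40, 4, 0.5, 1000, 128), "f_phase < f_amp")
  expect_error(pac_signal(4, 100, 0.5, 1000, 128), "f_phase < f_amp")
  expect_error(pac_signal(4, 40, 2, 1000, 128), "depth")
  expect_identical(pac_signal(4, 40, 0.5, 2048, 128, seed = 3),
                   pac_signal(4, 40, 0.5, 2048, 128, seed = 3))
})

test_that("deeper modulation raises PACz monotonically on average", {
  fs <- 200
  z <- sapply(c(0.2, 0.8), function(dep)
    mean(sapply(1:3, function(s) {
      x <- pac_signal(4, 40, dep, n = 25 * fs, fs = fs, seed = 40 + s)
      pacz(x, fs, phase_freqs = 4, amp_freqs = 40, seed = 50 + s)$pacz[1, 1]
    })))
  expect_gt(z[2], z[1])
})
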