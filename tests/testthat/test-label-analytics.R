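lab <- function(s, epoch_len = 1)
  label_sequence(strsplit(s, "")[[1]], epoch_len)

test_that("state proportions count epochs and sum to one", {
  p <- state_proportions(lab("aaam"))
  expect_equal(unname(p["a"]), 0.75)
  expect_equal(unname(p["m"]), 0.25)
  expect_equal(sum(p), 1)
  pn <- state_proportions(lab("NNNN"))
  expect_equal(unname(pn["N"]), 1)
})

test_that("transition pairs conserve n-1 and support noise exclusion", {
  m <- transition_pair_counts(lab("aab"))
  expect_equal(m["a", "a"], 1L)
  expect_equal(m["a", "b"], 1L)
  expect_equal(sum(m), 2L)
  expect_equal(attr(m, "total"), 2L)
  expect_equal(length(m), 64L)                  # 8 labels -> 64 ordered pairs

  mx <- transition_pair_counts(lab("aNa"), exclude_noise = TRUE)
  expect_equal(sum(mx), 0L)
  expect_equal(attr(mx, "total"), 2L)           # total counted before exclusion
})

test_that("hourly bins are wall-clock aligned with light/dark phases", {
  t0 <- as.POSIXct("2024-01-01 09:00:00", tz = "UTC")
  hd <- hourly_distribution(lab(strrep("a", 7200)), t0)
  expect_equal(nrow(hd), 2)
  expect_equal(hd$a, c(3600, 3600))
  expect_equal(hd$total, c(3600, 3600))

  hd2 <- hourly_distribution(lab(strrep("a", 7200)),
                             as.POSIXct("2024-01-01 09:30:00", tz = "UTC"))
  expect_equal(hd2$total[1], 1800)              # partial first hour

  hd3 <- hourly_distribution(lab(strrep("m", 3600)),
                             as.POSIXct("2024-01-01 15:00:00", tz = "UTC"))
  expect_equal(hd3$phase, "dark")               # lights off at 14:00
})

test_that("cumulative curves are monotone and conserve totals", {
  L <- lab(paste0(strrep("a", 3600), strrep("m", 3600), strrep("a", 1800)))
  cc <- cumulative_state_curve(L, "a",
                               as.POSIXct("2024-01-01 00:00:00", tz = "UTC"))
  expect_true(all(diff(cc$cumulative) >= 0))
  expect_equal(cc$cumulative[nrow(cc)],
               unname(state_proportions(L)["a"]) * L$n_epochs)
  none <- cumulative_state_curve(L, "o",
                                 as.POSIXct("2024-01-01", tz = "UTC"))
  expect_true(all(none$cumulative == 0))
})

test_that("CV is sd over mean, scale-invariant, undefined at zero mean", {
  expect_equal(coefficient_of_variance(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variance(c(1, 3)), sqrt(2) / 2)
  x <- rexp(50) + 1
  expect_equal(coefficient_of_variance(x), coefficient_of_variance(7 * x))
  expect_error(coefficient_of_variance(c(-1, 1)), "zero")
})

test_that("subdividing a heterogeneous pool lowers the per-band CV", {
  # two awake substates with different spectral levels: the pooled CV
  # exceeds the within-substate CVs
  set.seed(3)
  a1 <- rnorm(200, 10, 1)
  a3 <- rnorm(200, 30, 1)
  expect_lt(coefficient_of_variance(a1),
            coefficient_of_variance(c(a1, a3)))
  expect_lt(coefficient_of_variance(a3),
            coefficient_of_variance(c(a1, a3)))
})

test_that("the correlogram flags complements, masks null and constants", {
  set.seed(8)
  x <- runif(30, 0.2, 0.5)
  tab <- cbind(s1 = x, s2 = 0.8 - x, cst = rep(0.1, 30))
  cg <- state_correlogram(tab)
  expect_equal(cg$r["s1", "s2"], -1)
  expect_true(cg$significant["s1", "s2"])
  expect_false(cg$significant["s1", "cst"])     # constant column masked
  expect_true(is.na(cg$r["s1", "cst"]))

  set.seed(9)
  null_tab <- matrix(rnorm(50 * 4), ncol = 4)
  cg0 <- state_correlogram(null_tab)
  expect_false(any(cg0$significant))
  expect_error(state_correlogram(tab[1:2, ]), "3 subjects")
})

test_that("a synthetic genotype covariate shows up in the correlogram", {
  set.seed(10)
  geno <- rep(0:2, each = 8)
  nrem1 <- 0.35 - 0.08 * geno + rnorm(24, 0, 0.02)
  other <- runif(24, 0.1, 0.3)
  cg <- state_correlogram(cbind(genotype = geno, nREM1 = nrem1,
                                other = other))
  expect_lt(cg$r["genotype", "nREM1"], -0.6)
  expect_true(cg$significant["genotype", "nREM1"])
})

test_that("the difference-wave test flags only real offsets", {
  set.seed(12)
  a <- matrix(rnorm(10 * 65), nrow = 10)
  expect_false(any(difference_wave_test(a, a)$significant))

  b <- a + 10                                    # 10 sigma at every frequency
  expect_true(all(difference_wave_test(b, a)$significant))

  expect_error(difference_wave_test(a[1, , drop = FALSE], a), "single subject")
  expect_error(difference_wave_test(a, a[, 1:10]), "frequency grid")
})
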