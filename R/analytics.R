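# Label analytics: proportions, transition pairs, hourly and cumulative
# distributions, coefficient of variance, correlogram with Bonferroni
# thresholding, and the Bonferroni difference-wave test on curves.

#' Proportion of epochs in each state
#'
#' @param L a [label_sequence()].
#' @return named numeric vector over the 8 scoring labels (no 'U'),
#'   summing to 1, with attribute `n_epochs`.
#' @export
state_proportions <- function(L) {
  stopifnot(inherits(L, "label_sequence"), L$n_epochs > 0)
  tab <- table(factor(L$labels, levels = scoring_labels()))
  p <- as.numeric(tab) / L$n_epochs
  names(p) <- names(tab)
  attr(p, "n_epochs") <- L$n_epochs
  p
}

#' Ordered consecutive-pair (transition) counts
#'
#' Counts every ordered pair of consecutive epoch labels over the 8-label
#' scoring alphabet (64 possible pairs). Same-label pairs are within-state
#' persistence; different-label pairs are transitions. With
#' `exclude_noise = TRUE` any pair containing 'N' is zeroed for display.
#'
#' @param L a [label_sequence()] of length >= 2.
#' @param exclude_noise zero out pairs containing the noise label.
#' @return 8 x 8 integer matrix (from-state rows, to-state columns) with
#'   attribute `total` = `n_epochs - 1` (before exclusion).
#' @export
transition_pair_counts <- function(L, exclude_noise = FALSE) {
  stopifnot(inherits(L, "label_sequence"), L$n_epochs >= 2)
  lv <- scoring_labels()
  from <- factor(L$labels[-L$n_epochs], levels = lv)
  to <- factor(L$labels[-1L], levels = lv)
  m <- table(from, to)
  m <- matrix(as.integer(m), nrow = length(lv), dimnames = dimnames(m))
  total <- L$n_epochs - 1L
  if (exclude_noise) {
    m["N", ] <- 0L
    m[, "N"] <- 0L
  }
  attr(m, "total") <- total
  m
}

#' Hourly distribution of state labels
#'
#' Bins epochs into wall-clock hours from `start_time` and counts labels
#' per hour; each hour is annotated as light or dark phase (lights off at
#' `lights_off`, on at `lights_on`, 24-h clock).
#'
#' @param L a [label_sequence()].
#' @param start_time `POSIXct` wall-clock time of the first epoch.
#' @param lights_off,lights_on hour of day for the dark-phase bounds
#'   (defaults 14 and 2, a 12 h/12 h cycle with lights off at 14:00).
#' @return data.frame: `hour` (index from start), `clock_hour` (0-23),
#'   `phase` ("light"/"dark"), one count column per scoring label, and
#'   `total` (epochs in that hour).
#' @export
hourly_distribution <- function(L, start_time,
                                lights_off = 14, lights_on = 2) {
  stopifnot(inherits(L, "label_sequence"))
  start_time <- as.POSIXct(start_time)
  t0 <- as.numeric(start_time)
  tt <- t0 + (seq_len(L$n_epochs) - 1L) * L$epoch_len
  hour_abs <- floor(tt / 3600)
  hours <- sort(unique(hour_abs))
  lv <- scoring_labels()
  rows <- lapply(seq_along(hours), function(i) {
    sel <- hour_abs == hours[i]
    counts <- table(factor(L$labels[sel], levels = lv))
    ch <- as.integer(format(
      as.POSIXct(hours[i] * 3600, origin = "1970-01-01", tz = "UTC"), "%H"))
    dark <- if (lights_off < lights_on)
      ch >= lights_off & ch < lights_on
    else ch >= lights_off | ch < lights_on
    c(hour = i - 1L, clock_hour = ch, dark = as.integer(dark),
      as.integer(counts), total = sum(sel))
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("hour", "clock_hour", "dark", lv, "total")
  df$phase <- ifelse(df$dark == 1, "dark", "light")
  df$dark <- NULL
  df[, c("hour", "clock_hour", "phase", lv, "total")]
}

#' Cumulative per-hour epoch count of one state
#'
#' Nondecreasing step curve, one step per hour; the final value equals the
#' total number of epochs of that state.
#'
#' @param L a [label_sequence()].
#' @param state one scoring label character.
#' @param start_time wall-clock time of the first epoch.
#' @return data.frame `hour`, `cumulative`.
#' @export
cumulative_state_curve <- function(L, state,
                                   start_time = as.POSIXct("2024-01-01",
                                                           tz = "UTC")) {
  stopifnot(state %in% scoring_labels())
  hd <- hourly_distribution(L, start_time)
  data.frame(hour = hd$hour, cumulative = cumsum(hd[[state]]))
}

#' Coefficient of variance
#'
#' Sample standard deviation (n-1 denominator) divided by the mean; a
#' dimensionless spread comparable across data types.
#'
#' @param x numeric sample vector with nonzero mean.
#' @return the CV.
#' @examples
#' coefficient_of_variance(c(1, 3))   # sqrt(2)/2
#' @export
coefficient_of_variance <- function(x) {
  m <- mean(x)
  if (m == 0) stop("CV undefined: mean is zero")
  stats::sd(x) / m
}

#' State-proportion correlogram with Bonferroni thresholding
#'
#' Pairwise Pearson correlations between the columns of a per-subject
#' proportion (or covariate) table, with a significance mask at adjusted
#' p < `alpha`; the adjustment is Bonferroni over the unique off-diagonal
#' cells. Pairs involving a constant column have undefined r and are
#' masked.
#'
#' @param tab numeric matrix or data.frame, subjects x variables (>= 3
#'   subjects).
#' @param alpha family-wise level (default 0.05).
#' @return list: `r` (correlation matrix), `p_adj` (Bonferroni-adjusted
#'   p-values), `significant` (logical mask), `n_tests`.
#' @export
state_correlogram <- function(tab, alpha = 0.05) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 3) stop("need at least 3 subjects")
  k <- ncol(tab)
  n_tests <- k * (k - 1) / 2
  r <- matrix(NA_real_, k, k, dimnames = list(colnames(tab), colnames(tab)))
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  diag(r) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (stats::sd(tab[, i]) == 0 || stats::sd(tab[, j]) == 0) next
    ct <- stats::cor.test(tab[, i], tab[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- min(1, ct$p.value * n_tests)
  }
  sig <- !is.na(p) & p < alpha
  list(r = r, p_adj = p, significant = sig, n_tests = n_tests)
}

#' Bonferroni difference-wave test between two groups of curves
#'
#' Per frequency, a t confidence interval on the difference of group
#' means (Welch degrees of freedom), with the level Bonferroni-corrected
#' across the number of evaluated frequencies; a frequency is flagged when
#' the corrected interval excludes zero.
#'
#' @param curves_a,curves_b numeric matrices, subjects x frequencies, on
#'   the same frequency grid; >= 2 subjects per group.
#' @param level base confidence level (default 0.95).
#' @return data.frame: `freq_index`, `diff` (mean A - mean B), `lo`, `hi`
#'   (corrected CI bounds), `significant`.
#' @export
difference_wave_test <- function(curves_a, curves_b, level = 0.95) {
  curves_a <- as.matrix(curves_a); curves_b <- as.matrix(curves_b)
  if (ncol(curves_a) != ncol(curves_b))
    stop("curves must share the frequency grid")
  na <- nrow(curves_a); nb <- nrow(curves_b)
  if (na < 2 || nb < 2) stop("CI undefined with a single subject in a group")
  nf <- ncol(curves_a)
  alpha <- (1 - level) / nf                     # Bonferroni across frequencies
  ma <- colMeans(curves_a); mb <- colMeans(curves_b)
  va <- apply(curves_a, 2, stats::var); vb <- apply(curves_b, 2, stats::var)
  se <- sqrt(va / na + vb / nb)
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  df[!is.finite(df)] <- na + nb - 2
  tc <- stats::qt(1 - alpha / 2, df)
  d <- ma - mb
  lo <- d - tc * se; hi <- d + tc * se
  data.frame(freq_index = seq_len(nf), diff = d, lo = lo, hi = hi,
             significant = lo > 0 | hi < 0)
}
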