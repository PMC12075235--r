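# The fixed frequency-profile rule engine: per-epoch assignment of one of
# seven vigilance states or noise from the epoch's FFT band sums and the
# tense/relaxed macro-state.
#
# Rule precedence: noise test first; then the macro gate picks the awake
# argmax rules (tense) or the REM test followed by the nREM ratio ladder
# (relaxed). REM is tested before the ladder because a REM epoch can also
# satisfy a ladder inequality.

#' Fixed rule thresholds
#'
#' The frequency bands are fixed and half-open: awake argmax bands
#' `[0.2,3)`, `[3.2,6)`, `[6.2,12)` Hz; REM compares `[6,10)` against
#' `[0.2,6)`; the nREM ladder uses `[0.2,12)` over `[20,24)` with cutoffs
#' 20 (nREM1) and 10 (nREM2/nREM3). Only the noise bounds are
#' recording-specific.
#'
#' @param noise_low,noise_high absolute bounds (a.u.) on the epoch's total
#'   power over `[0.5, 70)` Hz outside which the epoch is noise.
#' @param nrem_hi_ratio,nrem_lo_ratio ladder cutoffs (defaults 20 and 10).
#' @return list of class `"rule_thresholds"`.
#' @export
rule_thresholds <- function(noise_low = 0, noise_high = Inf,
                            nrem_hi_ratio = 20, nrem_lo_ratio = 10) {
  if (noise_low >= noise_high) stop("noise_low must be < noise_high")
  if (nrem_lo_ratio >= nrem_hi_ratio)
    stop("nrem_lo_ratio must be < nrem_hi_ratio")
  structure(list(
    awake_bands = list(a = c(0.2, 3), b = c(3.2, 6), c = c(6.2, 12)),
    rem_num = c(6, 10), rem_den = c(0.2, 6),
    nrem_num = c(0.2, 12), nrem_den = c(20, 24),
    total_band = c(0.5, 70),
    nrem_hi_ratio = nrem_hi_ratio, nrem_lo_ratio = nrem_lo_ratio,
    noise_low = noise_low, noise_high = noise_high),
    class = "rule_thresholds")
}

#' Noise test
#'
#' TRUE when the total power over `[0.5, 70)` Hz is below `noise_low`,
#' above `noise_high`, or the spectrum contains non-finite values — power
#' too big or too low to fall into any other category.
#'
#' @param sp an `"epoch_spectrum"`.
#' @param th a [rule_thresholds()].
#' @export
is_noise <- function(sp, th) {
  if (any(!is.finite(sp$power))) return(TRUE)
  tot <- sum(sp$power[band_index(sp$freqs, th$total_band[1],
                                 th$total_band[2])])
  tot < th$noise_low || tot > th$noise_high
}

#' Awake substate by band-sum argmax
#'
#' a1 ('a') when the `[0.2,3)` Hz sum is the maximum, a2 ('b') for
#' `[3.2,6)`, a3 ('c') for `[6.2,12)`. Ties go to the higher-frequency
#' band (a3 > a2 > a1).
#'
#' @inheritParams is_noise
#' @return one of `"a"`, `"b"`, `"c"`.
#' @export
classify_awake <- function(sp, th) {
  sums <- vapply(th$awake_bands, function(b) bp(sp, b[1], b[2]), numeric(1))
  names(sums)[max(which(sums == max(sums)))]   # higher band wins ties
}

#' Sleep substate: REM test then the nREM ratio ladder
#'
#' REM ('l') when power in `[6,10)` exceeds power in `[0.2,6)`. Otherwise
#' the ratio `r` of `[0.2,12)` to `[20,24)` power grades non-REM:
#' `r > 20` nREM1 ('m'), `10 < r <= 20` nREM2 ('n'), `r <= 10` nREM3
#' ('o'); a zero denominator counts as infinite ratio (nREM1).
#'
#' @inheritParams is_noise
#' @return one of `"l"`, `"m"`, `"n"`, `"o"`.
#' @export
classify_sleep <- function(sp, th) {
  if (bp(sp, th$rem_num[1], th$rem_num[2]) >
      bp(sp, th$rem_den[1], th$rem_den[2])) return("l")
  den <- bp(sp, th$nrem_den[1], th$nrem_den[2])
  r <- if (den == 0) Inf else bp(sp, th$nrem_num[1], th$nrem_num[2]) / den
  if (r > th$nrem_hi_ratio) "m"
  else if (r > th$nrem_lo_ratio) "n"
  else "o"
}

#' Score one epoch
#'
#' Total by construction: noise first, then the macro gate dispatches to
#' the awake or sleep rules; never returns 'U'.
#'
#' @inheritParams is_noise
#' @param macro_state `"tense"` (awake) or `"relaxed"` (sleep).
#' @return a single label character.
#' @export
score_epoch <- function(sp, macro_state, th) {
  macro_state <- match.arg(macro_state, c("tense", "relaxed"))
  if (is_noise(sp, th)) return("N")
  if (macro_state == "tense") classify_awake(sp, th)
  else classify_sleep(sp, th)
}

#' Label sequence container
#'
#' @param labels character vector of single-character labels from the
#'   9-character alphabet.
#' @param epoch_len epoch length in seconds.
#' @return list of class `"label_sequence"`: `labels`, `epoch_len`,
#'   `n_epochs`.
#' @export
label_sequence <- function(labels, epoch_len = 1) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), names(label_alphabet))
  if (length(bad))
    stop("labels outside the alphabet: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, epoch_len = epoch_len,
                 n_epochs = length(labels)),
            class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d epochs x %g s\n", x$n_epochs, x$epoch_len))
  print(table(factor(x$labels, levels = names(label_alphabet))))
  invisible(x)
}

#' Score a whole recording
#'
#' Pipeline: downsample to the scoring copy, derive the tense/relaxed
#' macro-segments from the EMG tone envelope (or, without EMG, from
#' per-epoch total power with the wake/sleep ambiguity resolved toward
#' awake), cut into epochs, compute each epoch's FFT power profile, and
#' apply the rules. Epochs whose spectrum cannot be computed become 'N',
#' never 'U'.
#'
#' @param rec a [recording()] with at least one EEG channel.
#' @param cfg a [scoring_config()].
#' @param tone_overrides optional data.frame of manual tone edits
#'   (`start`, `end`, `state`) applied after change-point detection.
#' @param diagnostics if TRUE, attach a per-epoch data.frame (band sums,
#'   nREM ratio, macro-state, label) as attribute `"diagnostics"`.
#' @return a [label_sequence()].
#' @examples
#' sim <- synth_recording(state_schedule(c("a1", "nREM1"), c(30, 30)),
#'                        fs = 128, seed = 5)
#' lab <- score_recording(sim$recording, scoring_config(target_fs = 128))
#' mean(lab$labels == sim$labels$labels)
#' @export
score_recording <- function(rec, cfg = scoring_config(),
                            tone_overrides = NULL, diagnostics = FALSE) {
  stopifnot(inherits(rec, "recording"))
  if (cfg$target_fs < rec$fs) rec <- resample_recording(rec, cfg$target_fs)
  grid <- segment_epochs(rec, cfg$epoch_len)
  eeg <- rec$signal[channels_with_role(rec, "EEG")[1L], ]

  spectra <- lapply(seq_len(grid$n_epochs), function(k) {
    idx <- grid$starts[k] + seq_len(grid$samples_per_epoch) - 1L
    tryCatch(epoch_power_spectrum(eeg[idx], rec$fs), error = function(e) NULL)
  })

  # noise bounds: manual values if configured, else relative to the
  # recording's own median per-epoch total power (reported for audit)
  totals <- vapply(spectra, function(sp) {
    if (is.null(sp)) return(NA_real_)
    sum(sp$power[band_index(sp$freqs, 0.5, min(70, max(sp$freqs)))])
  }, numeric(1))
  med <- stats::median(totals, na.rm = TRUE)
  if (!is.finite(med) || med <= 0) med <- NA
  nl <- cfg$noise_low %||% (if (is.na(med)) .Machine$double.eps else 1e-3 * med)
  nh <- cfg$noise_high %||% (if (is.na(med)) Inf else 1e3 * med)
  message(sprintf("noise bounds in use: [%.4g, %.4g] (median epoch power %.4g)",
                  nl, nh, med))
  th <- rule_thresholds(nl, nh, cfg$nrem_hi_ratio, cfg$nrem_lo_ratio)

  emg_idx <- channels_with_role(rec, "EMG")
  if (cfg$use_emg && length(emg_idx)) {
    env <- emg_summary(rec$signal[emg_idx, , drop = FALSE], rec$fs)
    seg <- detect_tone_changepoints(env)
    if (!is.null(tone_overrides) && nrow(tone_overrides) > 0)
      seg <- apply_manual_overrides(seg, tone_overrides)
    macro <- epoch_macro_states(seg, grid)
  } else {
    macro <- macro_from_power(totals)
  }

  labs <- vapply(seq_len(grid$n_epochs), function(k) {
    if (is.null(spectra[[k]])) return("N")
    score_epoch(spectra[[k]], macro[k], th)
  }, character(1))
  out <- label_sequence(labs, cfg$epoch_len)
  if (diagnostics) {
    d <- t(vapply(seq_len(grid$n_epochs), function(k) {
      sp <- spectra[[k]]
      if (is.null(sp)) return(rep(NA_real_, 6))
      den <- bp(sp, 20, 24)
      c(bp(sp, 0.2, 3), bp(sp, 3.2, 6), bp(sp, 6.2, 12),
        bp(sp, 0.2, 12), den,
        if (den == 0) Inf else bp(sp, 0.2, 12) / den)
    }, numeric(6)))
    attr(out, "diagnostics") <- data.frame(
      epoch = seq_len(grid$n_epochs),
      delta = d[, 1], theta = d[, 2], alpha = d[, 3],
      nrem_num = d[, 4], nrem_den = d[, 5], nrem_ratio = d[, 6],
      macro = macro, label = labs)
  }
  out
}

# EMG-free fallback: sleep carries more spectral power than wake, so split
# per-epoch log total power into two clusters; the high cluster is relaxed
# (sleep). Indistinct clusters resolve toward awake (documented limitation:
# without muscle tone, REM and theta-awake are not separable).
macro_from_power <- function(totals) {
  lt <- log(pmax(totals, .Machine$double.xmin))
  lt[!is.finite(lt)] <- stats::median(lt[is.finite(lt)])
  if (max(lt) - min(lt) < log(2)) return(rep("tense", length(lt)))
  tm <- two_means(lt)
  if (diff(tm$centers) < log(2)) return(rep("tense", length(lt)))
  ifelse(lt > tm$threshold, "relaxed", "tense")
}

#' Per-epoch diagnostic CSV for audit
#'
#' Writes the band sums, nREM ratio, macro-state and label of each epoch.
#' Requires `score_recording(..., diagnostics = TRUE)` output.
#' @param labels a scored [label_sequence()] carrying diagnostics.
#' @param path output CSV path.
#' @export
write_diagnostics_csv <- function(labels, path) {
  d <- attr(labels, "diagnostics")
  if (is.null(d)) stop("no diagnostics attached; score with diagnostics=TRUE")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
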