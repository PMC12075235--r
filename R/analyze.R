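# Per-state metric battery driver: distribute the scored signal into
# states and run the requested analyses, returning tidy long-format rows.

#' Run the per-state metric battery
#'
#' Concatenates the epochs of each state present in `labels` and computes
#' the requested metrics on each state's signal, returning one tidy row
#' per (state, metric, frequency).
#'
#' @param rec a [recording()] (the filtered, not downsampled signal).
#' @param labels a [label_sequence()] aligned to the recording.
#' @param metrics character subset of
#'   `c("dfa", "fei", "pacz", "coherence", "aperiodic", "spindles")`.
#' @param min_state_dur minimum seconds of data required per state
#'   (default 30; shorter states are skipped with a message).
#' @param seed integer seed for stochastic steps (PACz permutations).
#' @return data.frame with columns `state`, `metric`, `frequency`, `value`.
#' @export
analyze_states <- function(rec, labels,
                           metrics = c("dfa", "aperiodic"),
                           min_state_dur = 30, seed = 1) {
  stopifnot(inherits(rec, "recording"), inherits(labels, "label_sequence"))
  metrics <- match.arg(metrics,
                       c("dfa", "fei", "pacz", "coherence", "aperiodic",
                         "spindles"),
                       several.ok = TRUE)
  fs <- rec$fs
  eeg_idx <- channels_with_role(rec, "EEG")
  eeg <- rec$signal[eeg_idx[1L], ]
  eeg2 <- if (length(eeg_idx) > 1L) rec$signal[eeg_idx[2L], ] else NULL
  spe <- round(labels$epoch_len * fs)
  rows <- list()
  add <- function(state, metric, frequency, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      state = state, metric = metric, frequency = frequency, value = value)
  for (st in setdiff(unique(labels$labels), "N")) {
    sel <- which(labels$labels == st)
    idx <- unlist(lapply(sel, function(k) (k - 1L) * spe + seq_len(spe)))
    idx <- idx[idx <= length(eeg)]
    if (length(idx) / fs < min_state_dur) {
      message("state '", st, "' shorter than ", min_state_dur, " s: skipped")
      next
    }
    x <- eeg[idx]
    if ("dfa" %in% metrics) {
      bd <- banded_dfa(x, fs)
      for (r in seq_len(nrow(bd)))
        add(st, "dfa_alpha", bd$center_freq[r], bd$alpha[r])
    }
    if ("fei" %in% metrics) {
      for (fc in c(2, 5, 10, 20)) {
        if (fc * 1.2 >= fs / 2) next
        fr <- tryCatch(fei(x, fs, fc), error = function(e) NULL)
        if (!is.null(fr))
          add(st, "fei", fc, if (fr$valid) fr$fei else NA_real_)
      }
    }
    if ("pacz" %in% metrics) {
      pz <- tryCatch(pacz(x, fs, seed = seed), error = function(e) NULL)
      if (!is.null(pz)) {
        add(st, "pacz_max", pz$max_phase_freq, pz$max_value)
      }
    }
    if ("coherence" %in% metrics && !is.null(eeg2)) {
      cp <- tryCatch(coherence_profile(x, eeg2[idx], fs),
                     error = function(e) NULL)
      if (!is.null(cp)) {
        for (r in seq_along(cp$freqs))
          add(st, "coherence", cp$freqs[r], cp$coherence[r])
        add(st, "coherence_peak", cp$peak_freq, cp$peak_value)
      }
    }
    if ("aperiodic" %in% metrics) {
      ps <- tryCatch(welch_psd(x, fs), error = function(e) NULL)
      if (!is.null(ps)) {
        ap <- tryCatch(
          aperiodic_exponent(ps, c(0.5, min(65, 0.95 * fs / 2))),
          error = function(e) NULL)
        if (!is.null(ap)) add(st, "aperiodic_exponent", NA_real_, ap$exponent)
      }
    }
    if ("spindles" %in% metrics && length(idx) / fs >= 30) {
      ev <- detect_spindles(x, fs)
      add(st, "spindle_rate_per_min", NA_real_,
          nrow(ev) / (length(idx) / fs / 60))
    }
  }
  if (!length(rows))
    return(data.frame(state = character(0), metric = character(0),
                      frequency = numeric(0), value = numeric(0)))
  do.call(rbind, rows)
}
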