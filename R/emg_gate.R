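# EMG muscle-tone gate: summary envelope, penalized change-point
# segmentation into tense (awake) and relaxed (sleep) macro-states, and
# manual override hooks for the visual transition check.

#' Muscle-tone envelope from EMG channels
#'
#' High-pass filters each EMG channel (muscle activity lives above the EEG
#' band), squares, sums across channels, and integrates over consecutive
#' windows — a "sum plot" of muscle tone over time.
#'
#' @param emg numeric vector or channels x samples matrix of EMG.
#' @param fs sampling rate, Hz.
#' @param window_len window length in seconds (>= 0.5; default 1).
#' @param hp_cutoff high-pass cutoff, Hz (default 20).
#' @return list of class `"tone_envelope"`: `times` (window centers, s),
#'   `values` (summed squared EMG per window, >= 0), `window_len`.
#' @export
emg_summary <- function(emg, fs, window_len = 1, hp_cutoff = 20) {
  if (is.vector(emg)) emg <- matrix(emg, nrow = 1L)
  if (window_len < 0.5) stop("window_len must be >= 0.5 s")
  n <- ncol(emg)
  pow <- numeric(n)
  for (ch in seq_len(nrow(emg))) {
    x <- emg[ch, ]
    if (any(x != 0) && hp_cutoff > 0 && hp_cutoff < fs / 2) {
      bf <- signal::butter(4, hp_cutoff / (fs / 2), type = "high")
      x <- signal::filtfilt(bf, x)
    }
    pow <- pow + x^2
  }
  spw <- round(window_len * fs)
  n_win <- floor(n / spw)
  if (n_win < 1) stop("EMG shorter than one window")
  vals <- vapply(seq_len(n_win), function(k)
    sum(pow[((k - 1L) * spw + 1L):(k * spw)]), numeric(1))
  structure(list(times = (seq_len(n_win) - 0.5) * window_len,
                 values = vals, window_len = window_len),
            class = "tone_envelope")
}

# Exact penalized least-squares segmentation with a minimum segment length:
# dynamic program over window indices minimizing sum of within-segment SSE
# plus penalty per change point. O(n^2), exact.
segment_mean_shift <- function(y, penalty, min_len = 1L) {
  n <- length(y)
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  fcost <- rep(Inf, n + 1L); fcost[1L] <- -penalty
  prev <- integer(n + 1L)
  for (j in seq_len(n)) {
    if (j < min_len) next
    i <- 0:(j - min_len)                      # last index of previous segment
    i <- i[i == 0L | i >= min_len]
    s <- cs[j + 1L] - cs[i + 1L]
    seg_sse <- cs2[j + 1L] - cs2[i + 1L] - s^2 / (j - i)
    v <- fcost[i + 1L] + penalty + seg_sse
    k <- which.min(v)
    fcost[j + 1L] <- v[k]; prev[j + 1L] <- i[k]
  }
  ends <- integer(0); j <- n
  while (j > 0L) { ends <- c(j, ends); j <- prev[j + 1L] }
  ends
}

#' Segment the tone envelope into tense / relaxed macro-states
#'
#' Mean-shift change points by exact penalized least-squares segmentation
#' (L2 cost); detected segments shorter than `min_seg_dur` are merged into
#' the neighbor with the closer mean (the envelope is sensitive to noise).
#' Segment means are then split into two clusters; a segment is tense when
#' its mean exceeds the midpoint of the two cluster means. When the two
#' clusters are indistinguishable (mean ratio below `two_state_gap`) the
#' whole recording is a single macro-state, assigned by comparing the
#' grand mean to `tense_floor`: without within-recording contrast the
#' envelope carries no absolute tone scale, so the default (`Inf`) assigns
#' relaxed unless a calibrated floor is supplied.
#'
#' Detection is invariant under positive rescaling of the envelope: both
#' the penalty (proportional to the envelope variance) and the cluster
#' split are relative.
#'
#' @param env a [emg_summary()] envelope (>= 4 windows).
#' @param penalty change-point penalty; default `3 * log(n) * var(values)`.
#' @param min_seg_dur minimum macro-segment duration, s (default 10).
#' @param two_state_gap minimal tense/relaxed cluster mean ratio (default 2).
#' @param tense_floor absolute envelope level above which a single-state
#'   recording counts as tense (default `Inf` = relaxed).
#' @return list of class `"tone_segments"`: data.frame `segments`
#'   (`start`, `end` in seconds, `state` in tense/relaxed) tiling the
#'   recording, plus `provenance = "auto"`.
#' @export
detect_tone_changepoints <- function(env, penalty = NULL,
                                     min_seg_dur = 10,
                                     two_state_gap = 2,
                                     tense_floor = Inf) {
  y <- env$values
  n <- length(y)
  if (n < 4) stop("envelope too short: need >= 4 windows")
  penalty <- penalty %||% (3 * log(n) * stats::var(y))
  min_len <- max(1L, ceiling(min_seg_dur / env$window_len))
  ends <- if (stats::var(y) == 0) n else
    segment_mean_shift(y, penalty, min_len = 1L)
  # merge short segments into the neighbor with the closer mean
  bounds <- c(0L, ends)
  repeat {
    lens <- diff(bounds)
    means <- vapply(seq_along(lens), function(k)
      mean(y[(bounds[k] + 1L):bounds[k + 1L]]), numeric(1))
    short <- which(lens < min_len)
    if (!length(short) || length(lens) == 1L) break
    k <- short[which.min(lens[short])]
    if (k == 1L) drop <- 2L
    else if (k == length(lens)) drop <- k
    else drop <- if (abs(means[k] - means[k - 1L]) <=
                     abs(means[k] - means[k + 1L])) k else k + 1L
    bounds <- bounds[-drop]
  }
  lens <- diff(bounds)
  means <- vapply(seq_along(lens), function(k)
    mean(y[(bounds[k] + 1L):bounds[k + 1L]]), numeric(1))
  # two-class threshold: midpoint of the two segment-mean clusters
  if (length(unique(means)) == 1L ||
      max(means) < two_state_gap * max(min(means), .Machine$double.eps)) {
    states <- rep(if (mean(y) > tense_floor) "tense" else "relaxed",
                  length(lens))
  } else {
    thr <- mean(two_means(means)$centers)
    states <- ifelse(means > thr, "tense", "relaxed")
  }
  seg <- data.frame(start = bounds[-length(bounds)] * env$window_len,
                    end = bounds[-1L] * env$window_len,
                    state = states, stringsAsFactors = FALSE)
  # collapse adjacent same-state segments so states alternate
  keep <- c(TRUE, seg$state[-1L] != seg$state[-nrow(seg)])
  starts <- seg$start[keep]
  ends_s <- c(seg$start[keep][-1L], seg$end[nrow(seg)])
  structure(list(segments = data.frame(start = starts, end = ends_s,
                                       state = seg$state[keep],
                                       stringsAsFactors = FALSE),
                 provenance = "auto"),
            class = "tone_segments")
}

#' Apply manual overrides to tone segments
#'
#' Each edit forces `state` over the interval `[start, end)`; this covers
#' both boundary shifts (an edit abutting an existing boundary) and the
#' insertion of a new interval inside a segment. The tiling invariant is
#' preserved and adjacent same-state segments are merged.
#'
#' @param seg a `"tone_segments"` object.
#' @param edits data.frame with columns `start`, `end`, `state`; an empty
#'   edit list is the identity.
#' @return edited `"tone_segments"` with `provenance = "manual"`.
#' @export
apply_manual_overrides <- function(seg, edits) {
  s <- seg$segments
  if (is.null(edits) || nrow(edits) == 0L) return(seg)
  total <- max(s$end)
  if (any(edits$start >= edits$end))
    stop("override would create a zero-length segment")
  if (any(edits$start < 0) || any(edits$end > total))
    stop("override outside recording bounds")
  # rebuild on a breakpoint grid
  brk <- sort(unique(c(s$start, s$end, edits$start, edits$end)))
  st <- character(length(brk) - 1L)
  for (k in seq_along(st)) {
    mid <- (brk[k] + brk[k + 1L]) / 2
    st[k] <- s$state[which(s$start <= mid & s$end > mid)[1L]]
  }
  for (e in seq_len(nrow(edits))) {
    hit <- brk[-length(brk)] >= edits$start[e] & brk[-1L] <= edits$end[e]
    st[hit] <- edits$state[e]
  }
  keep <- c(TRUE, st[-1L] != st[-length(st)])
  starts <- brk[-length(brk)][keep]
  ends <- c(starts[-1L], total)
  message(sprintf("applied %d manual tone override(s)", nrow(edits)))
  structure(list(segments = data.frame(start = starts, end = ends,
                                       state = st[keep],
                                       stringsAsFactors = FALSE),
                 provenance = "manual"),
            class = "tone_segments")
}

#' Macro-state of each epoch under a tone segmentation
#' @noRd
epoch_macro_states <- function(seg, grid) {
  mids <- (grid$starts - 1L) / grid$fs + grid$epoch_len / 2
  s <- seg$segments
  vapply(mids, function(m) {
    k <- which(s$start <= m & s$end > m)
    if (!length(k)) s$state[nrow(s)] else s$state[k[1L]]
  }, character(1))
}
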