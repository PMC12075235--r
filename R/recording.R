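# Core containers: Recording, channel metadata, scoring configuration,
# and the fixed 9-character label alphabet.

#' Vigilance-state label alphabet
#'
#' One ASCII character per state: `a` = a1 (delta-dominated awake),
#' `b` = a2 (theta-dominated awake), `c` = a3 (alpha-dominated awake /
#' resting state), `l` = REM, `m` = nREM1 (slow-wave sleep), `n` = nREM2,
#' `o` = nREM3, `N` = noise, `U` = unscored (development only; must not
#' appear in a final label sequence).
#'
#' @format A named character vector mapping code to state meaning.
#' @export
label_alphabet <- c(
  a = "a1", b = "a2", c = "a3", l = "REM",
  m = "nREM1", n = "nREM2", o = "nREM3", N = "noise", U = "unscored"
)

#' Scoring labels excluding the development-only 'U'
#' @keywords internal
scoring_labels <- function() setdiff(names(label_alphabet), "U")

#' Construct a multi-channel Recording
#'
#' @param signal numeric matrix, channels x samples (nominal microvolts).
#' @param fs sampling rate in Hz (> 0).
#' @param channels data.frame with columns `name`, `role` (one of
#'   `"EEG"`, `"EMG"`, `"REF"`) and optional `site` (free-text anatomical
#'   tag); one row per signal row.
#' @param start_time wall-clock time of the first sample (`POSIXct`);
#'   defaults to midnight of the current day so hour binning is aligned.
#' @return An object of class `"recording"`: a list with elements
#'   `signal`, `fs`, `channels`, `start_time`.
#' @examples
#' sig <- matrix(rnorm(2 * 500), nrow = 2)
#' rec <- recording(sig, fs = 250,
#'                  channels = data.frame(name = c("fr", "emg"),
#'                                        role = c("EEG", "EMG")))
#' rec
#' @export
recording <- function(signal, fs, channels,
                      start_time = as.POSIXct(format(Sys.Date()), tz = "UTC")) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  stopifnot(is.matrix(signal), is.numeric(signal))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  if (!all(c("name", "role") %in% names(channels)))
    stop("channels needs columns 'name' and 'role'")
  if (is.null(channels$site)) channels$site <- ""
  if (nrow(channels) != nrow(signal))
    stop("one channel metadata row per signal row required")
  bad <- setdiff(channels$role, c("EEG", "EMG", "REF"))
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  if (!any(channels$role == "EEG"))
    stop("a recording needs at least one EEG-role channel")
  structure(
    list(signal = signal, fs = fs, channels = channels,
         start_time = as.POSIXct(start_time)),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  dur <- ncol(x$signal) / x$fs
  cat(sprintf("<recording> %d channel(s), %.6g Hz, %.1f s\n",
              nrow(x$signal), x$fs, dur))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s[%s]", x$channels$name, x$channels$role),
                    collapse = " ")))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [recording()].
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$fs

#' Indices of channels with a given role
#' @noRd
channels_with_role <- function(rec, role) which(rec$channels$role == role)

#' Scoring configuration
#'
#' Bundles the tunable parameters of the scorer. Frequency-profile rules
#' are fixed; the noise bounds are the one deliberately adjustable pair
#' (recordings differ in gain), so they default to `NULL` and, when left
#' unset, are derived per recording as `c(1e-3, 1e3)` times the median
#' per-epoch total power — any value actually used is reported via message
#' so manual adjustments stay auditable.
#'
#' @param epoch_len epoch length in seconds (default 1).
#' @param target_fs sampling rate (Hz) of the downsampled scoring copy.
#' @param noise_low,noise_high absolute total-power bounds (a.u.) outside
#'   which an epoch is labeled noise; `NULL` = derive from the recording.
#' @param nrem_hi_ratio,nrem_lo_ratio low/high band power ratio cutoffs for
#'   the nREM ladder (defaults 20 and 10).
#' @param seed integer seed for any stochastic step.
#' @param use_emg use the EMG change-point gate when EMG channels exist.
#' @return A list of class `"scoring_config"`.
#' @export
scoring_config <- function(epoch_len = 1, target_fs = 256,
                           noise_low = NULL, noise_high = NULL,
                           nrem_hi_ratio = 20, nrem_lo_ratio = 10,
                           seed = 1L, use_emg = TRUE) {
  if (epoch_len <= 0) stop("epoch_len must be > 0")
  if (!is.null(noise_low) && !is.null(noise_high) && noise_low >= noise_high)
    stop("noise_low must be < noise_high")
  if (nrem_lo_ratio >= nrem_hi_ratio)
    stop("nrem_lo_ratio must be < nrem_hi_ratio")
  structure(list(epoch_len = epoch_len, target_fs = target_fs,
                 noise_low = noise_low, noise_high = noise_high,
                 nrem_hi_ratio = nrem_hi_ratio, nrem_lo_ratio = nrem_lo_ratio,
                 seed = seed, use_emg = use_emg),
            class = "scoring_config")
}

#' Read a scoring configuration from a YAML file
#'
#' Any field of [scoring_config()] may appear in the file; missing fields
#' take their defaults. Requires the `yaml` package.
#' @param path YAML file.
#' @export
read_scoring_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is needed to read config files")
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(scoring_config)))
  do.call(scoring_config, vals[keep])
}
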