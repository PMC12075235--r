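# Aperiodic (1/f) component of a power spectral density.

#' Aperiodic exponent of a PSD
#'
#' Robust linear fit of log10 power against log10 frequency with
#' iterative exclusion of points lying above the fit (oscillatory peaks
#' ride on top of the 1/f background, so only upward outliers are
#' removed). The exponent is the negative slope: a PSD proportional to
#' `1/f^b` yields exponent `b` exactly, and the peak exclusion keeps the
#' estimate within about 0.1 of the generating exponent in the presence
#' of an additive Gaussian peak.
#'
#' @param psd an `"epoch_spectrum"` (e.g. from [welch_psd()]), strictly
#'   positive over the fit range.
#' @param fit_range frequency range, Hz (default 0.5-65).
#' @param max_iter maximum exclusion iterations (default 10).
#' @return list of class `"aperiodic_fit"`: `exponent`, `offset`
#'   (log10 power at 1 Hz), `fit_range`, `n_points` (used in final fit).
#' @examples
#' sp <- structure(list(freqs = 1:64, power = 10 / (1:64)^2),
#'                 class = "epoch_spectrum")
#' aperiodic_exponent(sp)$exponent   # 2
#' @export
aperiodic_exponent <- function(psd, fit_range = c(0.5, 65), max_iter = 10) {
  sel <- psd$freqs >= fit_range[1] & psd$freqs <= fit_range[2] &
    psd$freqs > 0
  f <- psd$freqs[sel]; p <- psd$power[sel]
  if (length(f) < 10) stop("need at least 10 PSD points in the fit range")
  if (any(p <= 0)) stop("nonpositive PSD values in the fit range")
  lx <- log10(f); ly <- log10(p)
  keep <- rep(TRUE, length(f))
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.fit(cbind(1, lx[keep]), ly[keep])
    res_all <- ly - (fit$coefficients[1] + fit$coefficients[2] * lx)
    neg <- res_all[keep & res_all <= 0]
    spread <- if (length(neg) >= 3) stats::sd(c(neg, -neg)) else
      stats::sd(res_all[keep])
    new_keep <- res_all <= 2.5 * max(spread, 1e-12)
    if (sum(new_keep) < 10 || identical(new_keep, keep)) break
    keep <- new_keep
  }
  fit <- stats::lm.fit(cbind(1, lx[keep]), ly[keep])
  structure(list(exponent = -unname(fit$coefficients[2]),
                 offset = unname(fit$coefficients[1]),
                 fit_range = fit_range, n_points = sum(keep)),
            class = "aperiodic_fit")
}
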