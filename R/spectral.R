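#' Welch power spectral density
#'
#' Averaged periodogram over Hann-tapered, overlapping segments with
#' one-sided density scaling, so that `sum(power) * df` approximates the
#' signal variance (Parseval-consistent).
#'
#' @param signal A `multichannel_signal` (list with `data`, `fs`) or a
#'   channels x samples matrix (then `fs` is required).
#' @param window_s Segment length in seconds (default 2 s).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param fs Sampling frequency, if `signal` is a bare matrix.
#' @return A `power_spectrum`: list with `freqs` (Hz) and `power`
#'   (channels x frequencies matrix).
#' @export
welch_psd <- function(signal, window_s = 2, overlap = 0.5, fs = NULL) {
  if (inherits(signal, "multichannel_signal")) {
    x <- signal$data
    fs <- signal$fs
  } else {
    x <- rbind(signal)
    if (is.null(fs)) abort("`fs` is required for matrix input.")
  }
  nseg <- round(window_s * fs)
  n <- ncol(x)
  if (nseg > n) abort("window longer than signal.")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nseg %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1L) * fs / nseg
  pow <- matrix(0, nrow = nrow(x), ncol = nfreq)
  for (s in starts) {
    seg <- x[, s:(s + nseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    tap <- sweep(seg, 2L, w, `*`)
    ft <- t(apply(tap, 1L, fft))
    if (nrow(x) == 1L) ft <- matrix(ft, nrow = 1L)
    p <- Mod(ft[, seq_len(nfreq), drop = FALSE])^2 * scale
    # one-sided: double everything except DC (and Nyquist for even nseg)
    dbl <- rep(2, nfreq)
    dbl[1L] <- 1
    if (nseg %% 2L == 0L) dbl[nfreq] <- 1
    pow <- pow + sweep(p, 2L, dbl, `*`)
  }
  structure(list(freqs = freqs, power = pow / length(starts)),
            class = "power_spectrum")
}

#' Construct a power spectrum object
#'
#' @param freqs Strictly increasing frequency vector (Hz).
#' @param power Channels x frequencies non-negative power matrix (a vector
#'   is treated as one channel).
#' @return A `power_spectrum`.
#' @export
power_spectrum <- function(freqs, power) {
  power <- rbind(power)
  if (length(freqs) != ncol(power)) abort("freqs and power shapes differ.")
  if (any(diff(freqs) <= 0)) abort("freqs must be strictly increasing.")
  if (any(power < 0)) abort("power must be non-negative.")
  structure(list(freqs = freqs, power = power), class = "power_spectrum")
}

#' Alpha-band peak frequency
#'
#' Removes the 1/f trend by fitting a high-degree polynomial (default
#' degree 15) to log10 power against frequency over the full estimated
#' range, takes the per-bin maximum of the residual across channels, and
#' returns the frequency of the band-restricted argmax. A flat residual in
#' the band yields an explicit "no peak" flag rather than a silent number;
#' downstream, an undetected peak is treated as a missing feature.
#'
#' @param spectrum A [welch_psd()] result.
#' @param band Search band in Hz (default 6--15).
#' @param detrend_degree Polynomial degree of the 1/f detrend (default 15).
#' @param min_prominence Minimal in-band residual (log10 units) above the
#'   median residual required to call a peak.
#' @return One-row tibble with `peak_hz` (NA when no peak) and `detected`.
#' @export
alpha_peak <- function(spectrum, band = c(6, 15), detrend_degree = 15L,
                       min_prominence = 0.05) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  keep <- spectrum$freqs > 0 &
    apply(spectrum$power > 0, 2L, all)
  freqs <- spectrum$freqs[keep]
  if (!any(freqs >= band[1] & freqs <= band[2])) {
    abort("band not covered by the spectrum support.")
  }
  degree <- min(detrend_degree, length(freqs) - 2L)
  resid <- matrix(0, nrow = nrow(spectrum$power), ncol = length(freqs))
  basis <- stats::poly(freqs, degree = degree)
  for (ch in seq_len(nrow(spectrum$power))) {
    lp <- log10(spectrum$power[ch, keep])
    fit <- lm.fit(cbind(1, basis), lp)
    resid[ch, ] <- fit$residuals
  }
  prof <- apply(resid, 2L, max)  # per-bin max across channels
  in_band <- freqs >= band[1] & freqs <= band[2]
  prominence <- max(prof[in_band]) - median(prof)
  if (!is.finite(prominence) || prominence < min_prominence) {
    return(tibble(peak_hz = NA_real_, detected = FALSE))
  }
  tibble(peak_hz = freqs[in_band][which.max(prof[in_band])],
         detected = TRUE)
}

#' 1/f spectral slope
#'
#' Ordinary-least-squares slope of log power on log frequency over a fit
#' range, one slope per channel (a "1/f topography"). Power of the exact
#' form `c * f^-beta` yields slope `-beta`.
#'
#' @param spectrum A [welch_psd()] result.
#' @param fit_range Frequency range in Hz; must exclude 0 (default
#'   0.1--40 Hz).
#' @return Tibble with `channel` and `slope`.
#' @export
one_over_f_slope <- function(spectrum, fit_range = c(0.1, 40)) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (fit_range[1] <= 0) abort("`fit_range` must exclude 0 Hz.")
  sel <- spectrum$freqs >= fit_range[1] & spectrum$freqs <= fit_range[2]
  slopes <- vapply(seq_len(nrow(spectrum$power)), function(ch) {
    p <- spectrum$power[ch, sel]
    f <- spectrum$freqs[sel]
    ok <- p > 0
    if (sum(ok) < 3L) abort(sprintf(
      "channel %d: fewer than 3 positive-power bins in the fit range.", ch))
    unname(coef(lm.fit(cbind(1, log10(f[ok])), log10(p[ok])))[2L])
  }, numeric(1))
  tibble(channel = seq_len(nrow(spectrum$power)), slope = slopes)
}

#' Peak evoked-response latency
#'
#' Computes the root-mean-square across channels and looks up the time of
#' its maximum within a search window.
#'
#' @param evoked List with `times` (seconds, strictly increasing) and
#'   `data` (channels x times amplitude matrix).
#' @param search_window Two-element window in seconds.
#' @return One-row tibble with `latency_s` (NA when the RMS trace is
#'   constant) and `detected`.
#' @export
evoked_latency <- function(evoked, search_window = range(evoked$times)) {
  stopifnot(all(diff(evoked$times) > 0))
  sel <- evoked$times >= search_window[1] & evoked$times <= search_window[2]
  if (!any(sel)) abort("search window outside the epoch.")
  rms <- sqrt(colMeans(rbind(evoked$data)^2))[sel]
  if (diff(range(rms)) < 1e-12) {
    return(tibble(latency_s = NA_real_, detected = FALSE))
  }
  tibble(latency_s = evoked$times[sel][which.max(rms)], detected = TRUE)
}

#' Amplitude envelope via the Hilbert transform
#'
#' Per-channel magnitude of the analytic signal, computed with the FFT
#' one-sided spectrum method.
#'
#' @param signal A `multichannel_signal` or channels x samples matrix.
#' @param fs Sampling frequency for matrix input (carried through).
#' @return A `multichannel_signal` holding the envelopes.
#' @export
hilbert_envelope <- function(signal, fs = NULL) {
  if (inherits(signal, "multichannel_signal")) {
    x <- signal$data
    fs <- signal$fs
  } else {
    x <- rbind(signal)
  }
  n <- ncol(x)
  h <- rep(0, n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) %/% 2L)] <- 2
  }
  env <- t(apply(x, 1L, function(row) {
    Mod(fft(fft(row) * h, inverse = TRUE) / n)
  }))
  if (nrow(x) == 1L) env <- matrix(env, nrow = 1L)
  structure(list(data = env, fs = fs), class = "multichannel_signal")
}

#' @describeIn welch_psd Log-log spectrum plot, one line per channel.
#' @param object,... Plot method arguments.
#' @export
autoplot.power_spectrum <- function(object, ...) {
  df <- as_tibble(expand.grid(channel = seq_len(nrow(object$power)),
                              idx = seq_along(object$freqs)))
  df$freq <- object$freqs[df$idx]
  df$power <- object$power[cbind(df$channel, df$idx)]
  df <- df[df$freq > 0 & df$power > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$power,
                                   group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power density")
}
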