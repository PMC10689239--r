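# Synthetic two-channel fiber-photometry traces with planted event responses.

#' Create a photometry trace
#'
#' @param time Sample times in seconds (uniformly spaced).
#' @param signal_465 Calcium-sensitive signal channel (a.u.).
#' @param control_405 Isosbestic control channel (a.u.).
#' @param rate Sampling rate in Hz.
#' @return A `photometry_trace` object.
#' @export
photometry_trace <- function(time, signal_465, control_405, rate) {
  if (length(time) != length(signal_465) ||
      length(time) != length(control_405))
    stopf("time, signal_465 and control_405 must have equal length")
  if (rate <= 0) stopf("sampling rate must be positive")
  structure(list(time = time, signal_465 = signal_465,
                 control_405 = control_405, rate = rate),
            class = "photometry_trace")
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("photometry_trace: %.1f s at %g Hz\n",
              length(x$time) / x$rate, x$rate))
  invisible(x)
}

#' Generate a synthetic photometry recording
#'
#' Both channels share a slow exponential bleaching trend and a smooth
#' motion artifact; only the signal channel carries planted post-event
#' transients and each channel has independent white noise. The transient is
#' a 5-s plateau whose amplitude is scaled so that, after control-channel
#' detrending and event-aligned z-scoring ([detrend_photometry()],
#' [event_zscore()]), the expected post-event z equals `response_amp`.
#'
#' @param n_events Number of planted events (30 s apart).
#' @param response_amp Planted response amplitude in z units.
#' @param noise_sd White-noise sd on the signal channel (a.u.).
#' @param bleach_rate Exponential bleaching rate (1/s).
#' @param seed Integer seed.
#' @param rate Sampling rate in Hz.
#' @return A list with `trace` (a [photometry_trace()]) and `events`
#'   (`data.frame` with `time`, `label`).
#' @export
generate_photometry <- function(n_events = 20, response_amp = 3,
                                noise_sd = 1, bleach_rate = 1e-3,
                                seed = 0, rate = 20) {
  if (rate <= 0) stopf("sampling rate must be positive")
  with_seed(seed, {
    duration <- 30 + n_events * 30 + 15
    time <- seq(0, duration, by = 1 / rate)
    n <- length(time)
    events <- 30 + (seq_len(n_events) - 1L) * 30

    # shared slow structure: bleaching x smooth motion artifact
    k <- round(rate * 5)
    slow <- stats::filter(stats::rnorm(n), rep(1 / k, k), sides = 2)
    slow[is.na(slow)] <- 0
    slow <- as.numeric(slow) / max(stats::sd(slow), 1e-12)
    common <- exp(-bleach_rate * time) * (1 + 0.05 * slow)

    # plateau amplitude calibrated so binned z ~ response_amp (0.5 s bins)
    amp <- response_amp * noise_sd / sqrt(rate * 0.5)
    transient <- numeric(n)
    for (ev in events) {
      idx <- which(time > ev & time <= ev + 5)
      transient[idx] <- transient[idx] + amp
    }

    signal <- 300 * common + transient + stats::rnorm(n, 0, noise_sd)
    control <- 200 * common + stats::rnorm(n, 0, 0.1 * noise_sd)
    list(trace = photometry_trace(time, signal, control, rate),
         events = data.frame(time = events, label = "event"))
  })
}
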