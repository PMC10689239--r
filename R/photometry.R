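# Fiber-photometry processing: control-channel detrending and event-aligned
# z-scoring.

#' Detrend a photometry trace with the isosbestic control channel
#'
#' Fits the control (405 nm) channel onto the signal (465 nm) channel by
#' least squares (`f = a * control + b`) and returns
#' `dFF = (signal - f) / f`, which removes bleaching and movement artifacts
#' shared by the two channels. Samples where the fit is nonpositive are
#' masked (`NA`). A constant control channel falls back to an
#' intercept-only fit with a warning.
#'
#' @param trace A [photometry_trace()] with at least 10 s of data.
#' @param mode `"dff"` (default, `(signal - fit) / fit`) or `"residual"`
#'   (`signal - fit`).
#' @return List with `dff` (the detrended series), `fit` (fitted values)
#'   and `coef` (`a`, `b`).
#' @export
detrend_photometry <- function(trace, mode = c("dff", "residual")) {
  stopifnot(inherits(trace, "photometry_trace"))
  mode <- match.arg(mode)
  if (length(trace$time) < 10 * trace$rate)
    stopf("need at least 10 s of data")
  ctrl <- trace$control_405
  sig <- trace$signal_465
  if (stats::sd(ctrl) == 0) {
    warnf("constant control channel; fitting intercept only")
    coef <- c(a = 0, b = mean(sig))
  } else {
    fit <- stats::lm.fit(cbind(ctrl, 1), sig)
    coef <- c(a = unname(fit$coefficients[1]), b = unname(fit$coefficients[2]))
  }
  f <- coef[["a"]] * ctrl + coef[["b"]]
  dff <- switch(mode,
                dff = ifelse(f > 0, (sig - f) / f, NA_real_),
                residual = sig - f)
  list(dff = dff, fit = f, coef = coef)
}

#' Event-aligned z-scored responses
#'
#' Aligns the detrended trace to each event, averages it into fixed-width
#' bins over a pre/post window, and z-scores each event against its own
#' pre-event baseline bins (mean 0, sd 1 by construction). Events whose
#' window overlaps the trace edge are dropped with a warning; events with a
#' zero-variance baseline are marked invalid.
#'
#' @param dff Detrended series (from [detrend_photometry()]).
#' @param time Sample times (seconds), same length as `dff`.
#' @param events Event onset times in seconds (or a `data.frame` with a
#'   `time` column).
#' @param pre,post Window extent before/after the event (seconds).
#' @param bin Bin width (seconds).
#' @return An `aligned_response`: list with `z` (events x bins matrix,
#'   baseline bins first), `bin_centers` (seconds relative to event),
#'   `valid` (logical per event).
#' @export
event_zscore <- function(dff, time, events, pre = 5, post = 5, bin = 0.5) {
  if (is.data.frame(events)) events <- events$time
  if (length(dff) != length(time)) stopf("dff and time lengths differ")
  n_pre <- round(pre / bin)
  n_post <- round(post / bin)
  edges <- seq(-pre, post, by = bin)
  centers <- utils::head(edges, -1) + bin / 2
  keep <- events - pre >= time[1] & events + post <= time[length(time)]
  if (any(!keep))
    warnf("dropping %d event(s) overlapping the trace edge", sum(!keep))
  events <- events[keep]
  if (length(events) == 0L) stopf("no events with a full window")
  z <- matrix(NA_real_, length(events), length(centers),
              dimnames = list(NULL, sprintf("%+.2fs", centers)))
  valid <- logical(length(events))
  for (i in seq_along(events)) {
    rel <- time - events[i]
    in_win <- rel >= -pre & rel < post
    bins <- cut(rel[in_win], breaks = edges, right = FALSE,
                include.lowest = TRUE)
    bm <- tapply(dff[in_win], bins, mean, na.rm = TRUE)
    base <- bm[seq_len(n_pre)]
    mu <- mean(base, na.rm = TRUE)
    sdv <- stats::sd(base, na.rm = TRUE)
    if (is.na(sdv) || sdv == 0) next  # invalid event
    z[i, ] <- (bm - mu) / sdv
    valid[i] <- TRUE
  }
  structure(list(z = z, bin_centers = centers, valid = valid,
                 n_pre = n_pre, n_post = n_post),
            class = "aligned_response")
}

#' @export
print.aligned_response <- function(x, ...) {
  post <- x$z[x$valid, x$bin_centers > 0, drop = FALSE]
  cat(sprintf("aligned_response: %d/%d valid events; mean post-event z %.2f\n",
              sum(x$valid), length(x$valid), mean(post)))
  invisible(x)
}

#' Mean post-event z score
#'
#' @param ar An `aligned_response`.
#' @return Mean z over the post-event bins of all valid events.
#' @export
mean_post_z <- function(ar) {
  stopifnot(inherits(ar, "aligned_response"))
  mean(ar$z[ar$valid, ar$bin_centers > 0, drop = FALSE])
}
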