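#' Stimulation protocol for evoked-response trials
#'
#' Trial structure of the hindpaw-stimulation experiment: each trial is a
#' baseline period, a stimulation period and a recovery period, repeated
#' `n_trials` times while imaging at `frame_rate`. Defaults follow the
#' standard protocol of forty 15-s trials (2 s baseline, 2 s stimulation,
#' 11 s recovery) imaged at 50 fps.
#'
#' Frame `k` (1-based) is assigned time `t = (k - 1)/frame_rate` from trial
#' start. Baseline frames are those with `t < baseline_s`; stimulation
#' frames are those with `baseline_s <= t <= baseline_s + stim_s` (closed
#' interval, so the trapezoidal AUC of a plateau equals amplitude x stim_s).
#'
#' @param baseline_s,stim_s,recovery_s period durations in seconds.
#' @param n_trials number of trials (>= 1).
#' @param frame_rate imaging frame rate in Hz.
#' @param pulse optional stimulus description (e.g. width_us, rate_hz,
#'   current_ma), carried as metadata.
#' @return an object of class `stim_protocol`.
#' @export
stim_protocol <- function(baseline_s = 2, stim_s = 2, recovery_s = 11,
                          n_trials = 40, frame_rate = 50,
                          pulse = list(width_us = 500, rate_hz = 4,
                                       current_ma = 1)) {
  for (nm in c("baseline_s", "stim_s", "recovery_s", "frame_rate"))
    check_scalar_pos(get(nm), nm)
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  structure(list(baseline_s = baseline_s, stim_s = stim_s,
                 recovery_s = recovery_s, n_trials = as.integer(n_trials),
                 frame_rate = frame_rate, pulse = pulse),
            class = "stim_protocol")
}

trial_length_s <- function(p) p$baseline_s + p$stim_s + p$recovery_s
frames_per_trial <- function(p) as.integer(round(trial_length_s(p) * p$frame_rate))
frame_times <- function(p) (seq_len(frames_per_trial(p)) - 1) / p$frame_rate
baseline_idx <- function(p) which(frame_times(p) < p$baseline_s - 1e-9)
stim_idx <- function(p) {
  t <- frame_times(p)
  which(t >= p$baseline_s - 1e-9 & t <= p$baseline_s + p$stim_s + 1e-9)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol: %d trials of %g s (%g + %g + %g), %g fps, %d frames/trial>\n",
    x$n_trials, trial_length_s(x), x$baseline_s, x$stim_s, x$recovery_s,
    x$frame_rate, frames_per_trial(x)))
  invisible(x)
}

#' Downsample CBF frames into non-overlapping square windows
#'
#' Tiles each frame with non-overlapping `window x window` pixel blocks
#' anchored at the image origin and replaces each block by its mean CBF,
#' reducing memory and improving signal-to-noise before trial averaging.
#' Partial blocks at the right/bottom edges are dropped.
#'
#' @param frames a matrix or a height x width x n_frames array.
#' @param window block edge length in pixels (default 15).
#' @return array of window means, `floor(h/window) x floor(w/window) x
#'   n_frames` (a matrix input returns a matrix).
#' @export
downsample_windows <- function(frames, window = 15) {
  if (window < 1) stop("'window' must be >= 1", call. = FALSE)
  window <- as.integer(window)
  was_matrix <- is.matrix(frames)
  if (was_matrix) frames <- array(frames, c(dim(frames), 1L))
  d <- dim(frames)
  ny <- d[1] %/% window; nx <- d[2] %/% window
  if (ny < 1 || nx < 1)
    stop("image smaller than one window", call. = FALSE)
  # block-mean by aggregation matrices: out = t(Py) %*% A %*% Px / window^2
  Py <- matrix(0, d[1], ny); Px <- matrix(0, d[2], nx)
  Py[cbind(seq_len(ny * window), rep(seq_len(ny), each = window))] <- 1
  Px[cbind(seq_len(nx * window), rep(seq_len(nx), each = window))] <- 1
  out <- array(0, c(ny, nx, d[3]))
  for (f in seq_len(d[3]))
    out[, , f] <- crossprod(Py, frames[, , f] %*% Px) / window^2
  if (was_matrix) out[, , 1] else out
}

#' Cut a windowed recording into stimulus-aligned trials
#'
#' Splits a continuous window-downsampled CBF recording into per-trial
#' blocks using stimulus trigger times, so that frame 1 of every trial is
#' the trial start. Trials whose frames extend past the end of the
#' recording are rejected whole (never padded), with a message naming them.
#'
#' @param windowed array `wy x wx x n_total_frames` of windowed CBF values.
#' @param protocol a [stim_protocol()].
#' @param triggers trial start times in seconds (recording starts at 0).
#' @return an object of class `trial_series`: list with `data`
#'   (`wy x wx x frames_per_trial x n_kept`), `protocol`, `window_size`
#'   (if known) and `kept` (indices of retained triggers).
#' @export
segment_trials <- function(windowed, protocol, triggers) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (!is.array(windowed) || length(dim(windowed)) != 3L)
    stop("'windowed' must be a wy x wx x frames array", call. = FALSE)
  d <- dim(windowed)
  fpt <- frames_per_trial(protocol)
  start <- as.integer(round(triggers * protocol$frame_rate)) + 1L
  if (any(start < 1L | start > d[3]))
    stop(sprintf("trigger(s) %s outside the recording",
                 paste(which(start < 1L | start > d[3]), collapse = ", ")),
         call. = FALSE)
  complete <- start + fpt - 1L <= d[3]
  if (!all(complete))
    message(sprintf("rejecting %d incomplete trial(s): %s",
                    sum(!complete),
                    paste(which(!complete), collapse = ", ")))
  if (!any(complete))
    stop("no complete trials in the recording", call. = FALSE)
  keep <- which(complete)
  data <- array(0, c(d[1], d[2], fpt, length(keep)))
  for (i in seq_along(keep))
    data[, , , i] <- windowed[, , start[keep[i]] + seq_len(fpt) - 1L]
  structure(list(data = data, protocol = protocol, kept = keep),
            class = "trial_series")
}

#' @export
print.trial_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_series: %d x %d windows, %d frames/trial, %d trials>\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Baseline-normalized percent-change time course
#'
#' Converts one CBF time course to percent change relative to the mean of
#' its baseline period: `100 (x(t) - b)/b` with `b` the baseline-period
#' mean, so the baseline mean of the output is exactly zero.
#'
#' @param course numeric vector, one trial's CBF course for one window.
#' @param protocol a [stim_protocol()].
#' @return percent-change course of the same length.
#' @export
trial_percent_change <- function(course, protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  bi <- baseline_idx(protocol)
  if (length(course) < max(bi))
    stop("course shorter than the baseline period", call. = FALSE)
  b <- mean(course[bi])
  if (!is.finite(b) || b <= 0)
    stop("baseline mean must be positive for percent normalization",
         call. = FALSE)
  100 * (course - b) / b
}

#' Select the windows with the largest stimulus response in one trial
#'
#' Ranks windows by their baseline-normalized mean CBF increase during the
#' stimulation period, `(mean_stim - mean_base)/mean_base`, and returns the
#' top `ceiling(fraction * n_windows)` windows. Ties are broken by
#' row-major window index, making the selection deterministic.
#'
#' @param trial array `wy x wx x frames_per_trial`, one trial.
#' @param protocol a [stim_protocol()].
#' @param fraction fraction of windows to select, in (0, 1]; default 0.10.
#' @return integer vector of selected window indices (column-major linear
#'   indices into the `wy x wx` grid).
#' @export
select_responders <- function(trial, protocol, fraction = 0.10) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  d <- dim(trial)
  if (length(d) != 3L)
    stop("'trial' must be a wy x wx x frames array", call. = FALSE)
  nw <- d[1] * d[2]
  X <- matrix(trial, nw, d[3])
  mb <- rowMeans(X[, baseline_idx(protocol), drop = FALSE])
  ms <- rowMeans(X[, stim_idx(protocol), drop = FALSE])
  metric <- (ms - mb) / mb
  n_sel <- as.integer(ceiling(fraction * nw))
  # row-major tie-break: window (r, c) ranks by (r - 1) * wx + c
  rc <- arrayInd(seq_len(nw), d[1:2])
  rowmajor <- (rc[, 1] - 1L) * d[2] + rc[, 2]
  ord <- order(-metric, rowmajor)
  sort(ord[seq_len(n_sel)])
}

#' Trial-averaged neurovascular-coupling response
#'
#' The full evoked-response quantification: for each trial, the top
#' `fraction` responder windows (see [select_responders()]) are averaged
#' into one raw CBF course; that course is baseline-normalized to percent
#' change; all trials are then averaged (unweighted) into a single final
#' percent-change time course. The companion absolute course
#' (`delta_cbf_course`, responder-mean CBF minus its baseline mean, no
#' division) is computed the same way. Peak, stimulation-period AUC and
#' time-to-peak come from [nvc_metrics()].
#'
#' @param trials a [segment_trials()] result.
#' @param fraction responder fraction (default 0.10).
#' @return an object of class `nvc_result`: list with `time_s`,
#'   `mean_percent_course`, `per_trial_courses` (frames x trials),
#'   `delta_cbf_course`, `peak_percent`, `auc_stim`, `time_to_peak_s`,
#'   `responder_fraction`, `responders` (per-trial index list), `protocol`.
#' @export
average_response <- function(trials, fraction = 0.10) {
  stopifnot(inherits(trials, "trial_series"))
  p <- trials$protocol
  d <- dim(trials$data)
  if (d[4] < 1L) stop("no valid trials", call. = FALSE)
  nw <- d[1] * d[2]
  pct <- matrix(0, d[3], d[4])
  dlt <- matrix(0, d[3], d[4])
  sel_list <- vector("list", d[4])
  for (tr in seq_len(d[4])) {
    trial <- trials$data[, , , tr, drop = FALSE]
    dim(trial) <- d[1:3]
    sel <- select_responders(trial, p, fraction)
    sel_list[[tr]] <- sel
    X <- matrix(trial, nw, d[3])
    resp <- colMeans(X[sel, , drop = FALSE])
    pct[, tr] <- trial_percent_change(resp, p)
    dlt[, tr] <- resp - mean(resp[baseline_idx(p)])
  }
  mean_pct <- rowMeans(pct)
  mean_dlt <- rowMeans(dlt)
  met <- nvc_metrics(mean_pct, p)
  structure(list(time_s = frame_times(p),
                 mean_percent_course = mean_pct,
                 per_trial_courses = pct,
                 delta_cbf_course = mean_dlt,
                 peak_percent = met$peak_percent,
                 auc_stim = met$auc_stim,
                 time_to_peak_s = met$time_to_peak_s,
                 responder_fraction = fraction,
                 responders = sel_list,
                 protocol = p),
            class = "nvc_result")
}

#' Peak, stimulation AUC and time-to-peak of a percent-change course
#'
#' The peak is the maximum of the course over the whole trial (evoked
#' responses can peak shortly after stimulus offset). The AUC is the
#' trapezoidal integral of the percent-change course over the stimulation
#' period only (closed interval, units percent x seconds). Time-to-peak is
#' measured from stimulus onset.
#'
#' @param course percent-change course covering at least the stimulation
#'   window (one value per frame).
#' @param protocol a [stim_protocol()].
#' @return list with `peak_percent`, `auc_stim`, `time_to_peak_s`.
#' @export
nvc_metrics <- function(course, protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  si <- stim_idx(protocol)
  if (length(course) < max(si))
    stop("course does not cover the stimulation window", call. = FALSE)
  t <- (seq_along(course) - 1) / protocol$frame_rate
  ipk <- which.max(course)
  list(peak_percent = course[ipk],
       auc_stim = trapz(t[si], course[si]),
       time_to_peak_s = t[ipk] - protocol$baseline_s)
}

#' @export
print.nvc_result <- function(x, ...) {
  cat(sprintf(
    paste0("<nvc_result: %d trials, top %.0f%% windows>\n",
           "  peak %% change : %.3g %%\n",
           "  stim AUC       : %.3g %%.s\n",
           "  time to peak   : %.3g s\n"),
    ncol(x$per_trial_courses), 100 * x$responder_fraction,
    x$peak_percent, x$auc_stim, x$time_to_peak_s))
  invisible(x)
}

#' @export
plot.nvc_result <- function(x, ...) {
  p <- x$protocol
  graphics::plot(x$time_s, x$mean_percent_course, type = "l", lwd = 2,
                 xlab = "time from trial start (s)",
                 ylab = "CBF change (%)", ...)
  graphics::rect(p$baseline_s, graphics::par("usr")[3],
                 p$baseline_s + p$stim_s, graphics::par("usr")[4],
                 col = grDevices::adjustcolor("red", 0.12), border = NA)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
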