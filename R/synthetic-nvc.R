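#' Specification of a synthetic evoked-response trial set
#'
#' Describes a window-downsampled CBF recording with a known evoked
#' response: a grid of windows, a subset of "responder" windows whose CBF
#' rises by `amplitude_percent` during stimulation (as a plateau or a
#' gamma-variate transient), additive Gaussian noise, and the stimulation
#' protocol. Defaults emulate the standard forty-trial hindpaw protocol at
#' 50 fps with a 10 x 10 window grid and a 15% response in the top-left
#' 10% of windows.
#'
#' @param protocol a [stim_protocol()].
#' @param grid window grid (rows, cols).
#' @param responders integer vector of responder window indices
#'   (column-major linear indices into the grid); default: the first
#'   `ceiling(0.1 * n_windows)` windows.
#' @param amplitude_percent evoked CBF increase in percent (>= 0). For the
#'   plateau shape the stimulation-period level is
#'   `baseline * (1 + amplitude/100)`; for the gamma shape the transient
#'   peaks at that level.
#' @param shape `"plateau"` or `"gamma"`.
#' @param noise_sigma_percent additive Gaussian noise standard deviation, as
#'   percent of the baseline level.
#' @param baseline_level baseline CBF level (1/s).
#' @param onset_s response onset delay after stimulus start (gamma shape).
#' @param time_to_peak_s time from stimulus start to the gamma-variate peak.
#' @param seed integer seed.
#' @return an object of class `nvc_trial_spec`.
#' @export
nvc_trial_spec <- function(protocol = stim_protocol(), grid = c(10, 10),
                           responders = NULL, amplitude_percent = 15,
                           shape = c("plateau", "gamma"),
                           noise_sigma_percent = 2, baseline_level = 100,
                           onset_s = 0.2, time_to_peak_s = 1.5, seed = 1) {
  stopifnot(inherits(protocol, "stim_protocol"))
  shape <- match.arg(shape)
  if (amplitude_percent < 0)
    stop("'amplitude_percent' must be >= 0", call. = FALSE)
  if (noise_sigma_percent < 0)
    stop("'noise_sigma_percent' must be >= 0", call. = FALSE)
  check_scalar_pos(baseline_level, "baseline_level")
  nw <- prod(grid)
  if (is.null(responders)) responders <- seq_len(ceiling(0.1 * nw))
  responders <- as.integer(responders)
  if (length(responders) && (min(responders) < 1 || max(responders) > nw))
    stop("responder indices outside the window grid", call. = FALSE)
  structure(list(protocol = protocol, grid = as.integer(grid),
                 responders = responders,
                 amplitude_percent = amplitude_percent, shape = shape,
                 noise_sigma_percent = noise_sigma_percent,
                 baseline_level = baseline_level, onset_s = onset_s,
                 time_to_peak_s = time_to_peak_s, seed = as.integer(seed)),
            class = "nvc_trial_spec")
}

# evoked-response template in percent, over trial-relative frame times
response_template <- function(spec) {
  p <- spec$protocol
  t <- frame_times(p)
  amp <- spec$amplitude_percent
  r <- numeric(length(t))
  if (spec$shape == "plateau") {
    r[stim_idx(p)] <- amp
  } else {
    t0 <- p$baseline_s + spec$onset_s
    tp <- spec$time_to_peak_s - spec$onset_s  # time from onset to peak
    alpha <- 3
    u <- (t - t0) / tp
    on <- u > 0
    r[on] <- amp * (u[on]^alpha) * exp(alpha * (1 - u[on]))
  }
  r
}

#' Generate a synthetic windowed recording of evoked-response trials
#'
#' Produces a continuous window-downsampled CBF recording containing
#' `n_trials` back-to-back trials plus the trigger times, suitable for
#' running the full evoked-response pipeline ([segment_trials()] then
#' [average_response()]). Responder windows carry the evoked template of
#' the spec; all windows receive i.i.d. Gaussian noise.
#'
#' @param spec an [nvc_trial_spec()].
#' @return list with `stack` (array `wy x wx x n_total_frames`), `triggers`
#'   (seconds), `protocol` and `truth` (a [phantom_truth()] with the
#'   responder set, amplitude, shape and noise level).
#' @export
generate_nvc_trials <- function(spec) {
  stopifnot(inherits(spec, "nvc_trial_spec"))
  p <- spec$protocol
  fpt <- frames_per_trial(p)
  nw <- prod(spec$grid)
  total <- fpt * p$n_trials
  templ <- response_template(spec)
  base <- spec$baseline_level
  course <- matrix(base, nw, total)
  resp_course <- base * (1 + templ / 100)
  for (tr in seq_len(p$n_trials))
    course[spec$responders, (tr - 1L) * fpt + seq_len(fpt)] <-
      matrix(resp_course, length(spec$responders), fpt, byrow = TRUE)
  sigma <- spec$noise_sigma_percent / 100 * base
  if (sigma > 0)
    course <- course + with_seed(spec$seed,
                                 matrix(rnorm(nw * total, 0, sigma), nw, total))
  stack <- array(course, c(spec$grid[1], spec$grid[2], total))
  truth <- phantom_truth("nvc", list(
    responders = spec$responders, amplitude_percent = spec$amplitude_percent,
    shape = spec$shape, noise_sigma_percent = spec$noise_sigma_percent,
    baseline_level = base))
  list(stack = stack, triggers = (seq_len(p$n_trials) - 1) * trial_length_s(p),
       protocol = p, truth = truth)
}
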