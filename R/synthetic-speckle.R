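#' Closed-form speckle contrast for an exponentially decorrelating field
#'
#' Theoretical squared temporal speckle contrast of fully developed speckle
#' integrated over a finite camera exposure, for an optical field whose
#' temporal autocorrelation decays exponentially with correlation time
#' `tau_c` (the Lorentzian-spectrum model of laser speckle flowmetry):
#' \deqn{K^2 = \beta \frac{e^{-2x} - 1 + 2x}{2x^2}, \quad x = T/\tau_c.}
#' This is the independent oracle against which the dynamic-speckle
#' simulator and the flow pipeline are validated.
#'
#' @param exposure_T camera exposure time in seconds (> 0).
#' @param tau_c field correlation time in seconds (> 0). Inversely related
#'   to scatterer speed; flow index is proportional to `1/tau_c`.
#' @param beta speckle-averaging factor in (0, 1]; bounds `K^2` from above.
#' @return squared speckle contrast, a value in `(0, beta]`.
#' @examples
#' speckle_contrast_theory(0.01, 0.01)        # x = 1: (1 + exp(-2))/2
#' speckle_contrast_theory(0.01, 1e-4)        # x = 100: ~ 1/x
#' @export
speckle_contrast_theory <- function(exposure_T, tau_c, beta = 1) {
  check_scalar_pos(exposure_T, "exposure_T")
  if (!is.numeric(tau_c) || any(tau_c <= 0))
    stop("'tau_c' must be positive", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop("'beta' must be in (0, 1]", call. = FALSE)
  x <- exposure_T / tau_c
  k2 <- ifelse(x < 1e-4,
               # Taylor expansion, avoids cancellation as x -> 0
               1 - (2 / 3) * x + (1 / 3) * x^2,
               (exp(-2 * x) - 1 + 2 * x) / (2 * x^2))
  beta * k2
}

#' Ground-truth record attached to every synthetic dataset
#'
#' @param kind one of `"speckle"`, `"vessel"`, `"nvc"`.
#' @param parameters named list of true parameter values.
#' @return an object of class `phantom_truth`.
#' @export
phantom_truth <- function(kind, parameters) {
  kind <- match.arg(kind, c("speckle", "vessel", "nvc"))
  structure(list(kind = kind, parameters = parameters),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth: %s>\n", x$kind))
  str(x$parameters, max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Specification of a synthetic dynamic-speckle acquisition
#'
#' Parameters of the simulated laser speckle movie: field correlation time,
#' camera exposure and frame timing, image size, target speckle-averaging
#' factor and seed. Defaults mirror the resting-state acquisition the
#' pipelines are designed for (10-ms exposure at 60 fps, 60 frames).
#'
#' @param tau_c field correlation time in seconds.
#' @param exposure_T exposure time in seconds.
#' @param n_frames number of frames (>= 2).
#' @param frame_rate nominal frame rate in Hz (metadata; frame timing is set
#'   by `frame_interval`).
#' @param frame_interval time between frame starts in seconds; must be at
#'   least `exposure_T`. Defaults to `1/frame_rate`. Gaps between the end of
#'   one exposure and the next frame start carry no signal.
#' @param grid image height and width in pixels, length-2 integer.
#' @param beta_target speckle-averaging factor in (0, 1]. Realized by
#'   averaging `m = round(1/beta_target)` independent speckle intensities per
#'   pixel (pixel/speckle size mismatch), so realizable values are `1/m`;
#'   the realized value is recorded in the truth.
#' @param seed integer seed; identical specs give bit-identical stacks.
#' @return an object of class `speckle_spec`.
#' @export
speckle_spec <- function(tau_c, exposure_T = 0.01, n_frames = 60,
                         frame_rate = 60, frame_interval = 1 / frame_rate,
                         grid = c(100, 100), beta_target = 1, seed = 1) {
  check_scalar_pos(tau_c, "tau_c")
  check_scalar_pos(exposure_T, "exposure_T")
  check_scalar_pos(frame_rate, "frame_rate")
  check_scalar_pos(frame_interval, "frame_interval")
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 2)
    stop("'n_frames' must be >= 2", call. = FALSE)
  if (length(grid) != 2L || any(grid < 1))
    stop("'grid' must be two positive integers (height, width)", call. = FALSE)
  if (beta_target <= 0 || beta_target > 1)
    stop("'beta_target' must be in (0, 1]", call. = FALSE)
  if (frame_interval < exposure_T - 1e-12)
    stop("'frame_interval' must be >= 'exposure_T'", call. = FALSE)
  structure(list(tau_c = tau_c, exposure_T = exposure_T,
                 n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 frame_interval = frame_interval, grid = as.integer(grid),
                 beta_target = beta_target, seed = as.integer(seed)),
            class = "speckle_spec")
}

# One exact Ornstein-Uhlenbeck transition of a complex circular-Gaussian
# field: E <- rho E + sqrt(1 - rho^2) xi, xi ~ CN(0, 1), preserving unit
# mean intensity and g1(tau) = exp(-tau/tau_c).
ou_step <- function(E, rho) {
  n <- length(E)
  rho * E + sqrt((1 - rho^2) / 2) * complex(real = rnorm(n),
                                            imaginary = rnorm(n))
}

#' Simulate a dynamic laser speckle stack with known correlation time
#'
#' Per pixel, the intensity of each frame is the exposure-integrated squared
#' magnitude of a complex circular-Gaussian field evolved as an
#' Ornstein-Uhlenbeck process with time constant `tau_c`, so the realized
#' temporal contrast converges to [speckle_contrast_theory()] as the number
#' of frames and pixels grows. Exposure integration uses at least 10
#' sub-steps per frame and at least 10 sub-steps per correlation time.
#'
#' @param spec a [speckle_spec()].
#' @param mean_counts mean detected intensity in camera counts (scale only;
#'   speckle contrast is scale-invariant).
#' @return list with elements `stack` (a [speckle_stack()]) and `truth`
#'   (a [phantom_truth()] recording `tau_c`, the realized beta and the
#'   sub-step count).
#' @examples
#' sim <- simulate_dynamic_speckle(speckle_spec(tau_c = 0.1, grid = c(20, 20)))
#' sim$truth
#' @export
simulate_dynamic_speckle <- function(spec, mean_counts = 1000) {
  stopifnot(inherits(spec, "speckle_spec"))
  m <- max(1L, as.integer(round(1 / spec$beta_target)))
  beta_real <- 1 / m
  npix <- prod(spec$grid)
  nf <- npix * m
  n_sub <- max(10L, min(400L, as.integer(ceiling(10 * spec$exposure_T / spec$tau_c))))
  dt <- spec$exposure_T / n_sub
  rho_sub <- exp(-dt / spec$tau_c)
  gap <- spec$frame_interval - spec$exposure_T
  rho_gap <- exp(-gap / spec$tau_c)
  frames <- with_seed(spec$seed, {
    E <- complex(real = rnorm(nf), imaginary = rnorm(nf)) / sqrt(2)
    out <- array(0, c(spec$grid[1], spec$grid[2], spec$n_frames))
    for (f in seq_len(spec$n_frames)) {
      acc <- numeric(nf)
      for (k in seq_len(n_sub)) {
        acc <- acc + Re(E)^2 + Im(E)^2
        E <- ou_step(E, rho_sub)
      }
      I <- acc / n_sub
      if (m > 1L) I <- rowMeans(matrix(I, npix, m))
      out[, , f] <- I * mean_counts
      if (gap > 0) E <- ou_step(E, rho_gap)
    }
    out
  })
  stack <- speckle_stack(frames, exposure_T = spec$exposure_T,
                         frame_rate = spec$frame_rate,
                         metadata = list(source = "simulate_dynamic_speckle",
                                         frame_interval = spec$frame_interval))
  truth <- phantom_truth("speckle", list(
    tau_c = spec$tau_c, beta = beta_real, n_sub = n_sub,
    k2_theory = speckle_contrast_theory(spec$exposure_T, spec$tau_c, beta_real)))
  list(stack = stack, truth = truth)
}

#' Simulate a static speckle phantom
#'
#' A temporally constant, spatially fully developed speckle pattern, used to
#' calibrate the speckle-averaging factor beta. The spatial contrast squared
#' of the pattern approximates `beta_target`; values below one are realized
#' by averaging `round(1/beta_target)` independent speckle intensities per
#' pixel. All frames are identical, so the temporal contrast is zero.
#'
#' @param grid image height and width in pixels.
#' @param beta_target target spatial contrast squared in (0, 1].
#' @param n_frames number of (identical) frames.
#' @param exposure_T,frame_rate acquisition metadata carried on the stack.
#' @param seed integer seed.
#' @param mean_counts mean intensity in counts.
#' @return list with elements `stack` and `truth` (realized beta).
#' @export
simulate_static_speckle <- function(grid = c(100, 100), beta_target = 1,
                                    n_frames = 10, exposure_T = 0.01,
                                    frame_rate = 60, seed = 1,
                                    mean_counts = 1000) {
  if (beta_target <= 0 || beta_target > 1)
    stop("'beta_target' must be in (0, 1]", call. = FALSE)
  m <- max(1L, as.integer(round(1 / beta_target)))
  npix <- prod(grid)
  I <- with_seed(seed, {
    raw <- (rnorm(npix * m)^2 + rnorm(npix * m)^2) / 2
    if (m > 1L) raw <- rowMeans(matrix(raw, npix, m))
    raw
  })
  frame <- matrix(I * mean_counts, grid[1], grid[2])
  frames <- array(frame, c(grid[1], grid[2], n_frames))
  stack <- speckle_stack(frames, exposure_T = exposure_T,
                         frame_rate = frame_rate,
                         metadata = list(source = "simulate_static_speckle"))
  truth <- phantom_truth("speckle", list(tau_c = Inf, beta = 1 / m))
  list(stack = stack, truth = truth)
}
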