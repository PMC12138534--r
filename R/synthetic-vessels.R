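#' Specification of a synthetic vessel phantom image
#'
#' Describes a grayscale image of drawn vessel segments (emulating a
#' lectin-labeled microvascular MIP) with known centerline geometry: each
#' segment is a straight capsule (line with round caps clipped to the
#' canvas) of given width and intensity, optionally blurred and corrupted
#' with Gaussian noise.
#'
#' @param canvas image height and width in pixels.
#' @param pixel_size_um pixel edge length in micrometers.
#' @param segments data frame with columns `x0, y0, x1, y1` (endpoint pixel
#'   coordinates), `width_um` (> 0) and `intensity`.
#' @param background background intensity level.
#' @param blur_sigma_px Gaussian blur standard deviation in pixels (0 = no
#'   blur).
#' @param noise_sigma additive Gaussian noise standard deviation (intensity
#'   units; 0 = none).
#' @param seed integer seed.
#' @return an object of class `vessel_phantom_spec`.
#' @export
vessel_phantom_spec <- function(canvas = c(256, 256), pixel_size_um = 1,
                                segments = data.frame(), background = 10,
                                blur_sigma_px = 0, noise_sigma = 0,
                                seed = 1) {
  if (length(canvas) != 2L || any(canvas < 1))
    stop("'canvas' must be two positive integers", call. = FALSE)
  check_scalar_pos(pixel_size_um, "pixel_size_um")
  if (nrow(segments)) {
    need <- c("x0", "y0", "x1", "y1", "width_um", "intensity")
    if (!all(need %in% names(segments)))
      stop("'segments' needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(segments$width_um <= 0))
      stop("segment widths must be > 0", call. = FALSE)
  }
  structure(list(canvas = as.integer(canvas), pixel_size_um = pixel_size_um,
                 segments = segments, background = background,
                 blur_sigma_px = blur_sigma_px, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "vessel_phantom_spec")
}

#' Render a vessel phantom with known ground-truth geometry
#'
#' Rasterizes each segment as the set of pixels whose centers lie within
#' half the segment width of the centerline, applies blur and noise per the
#' spec, and returns the image together with a truth table recording each
#' segment's true centerline length (um), width (um) and rasterized pixel
#' area. A segment that covers no canvas pixel is an error.
#'
#' @param spec a [vessel_phantom_spec()].
#' @return list with `image` (matrix), `truth` (a [phantom_truth()] whose
#'   `parameters$segments` is the per-segment truth table) and
#'   `pixel_size_um`.
#' @export
generate_vessel_phantom <- function(spec) {
  stopifnot(inherits(spec, "vessel_phantom_spec"))
  h <- spec$canvas[1]; w <- spec$canvas[2]
  img <- matrix(spec$background, h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)   # pixel-center coords (px)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  segs <- spec$segments
  n <- nrow(segs)
  truth_tab <- data.frame(id = integer(0), length_um = numeric(0),
                          width_um = numeric(0), area_px = integer(0))
  for (i in seq_len(n)) {
    dx <- segs$x1[i] - segs$x0[i]; dy <- segs$y1[i] - segs$y0[i]
    len2 <- dx^2 + dy^2
    if (len2 == 0) {
      dist <- sqrt((xs - segs$x0[i])^2 + (ys - segs$y0[i])^2)
    } else {
      tpar <- pmin(1, pmax(0, ((xs - segs$x0[i]) * dx +
                                 (ys - segs$y0[i]) * dy) / len2))
      dist <- sqrt((xs - (segs$x0[i] + tpar * dx))^2 +
                     (ys - (segs$y0[i] + tpar * dy))^2)
    }
    half_w_px <- segs$width_um[i] / spec$pixel_size_um / 2
    inside <- dist <= half_w_px
    if (!any(inside))
      stop(sprintf("segment %d lies fully outside the canvas", i),
           call. = FALSE)
    img[inside] <- pmax(img[inside], segs$intensity[i])
    truth_tab <- rbind(truth_tab, data.frame(
      id = i, length_um = sqrt(len2) * spec$pixel_size_um,
      width_um = segs$width_um[i], area_px = sum(inside)))
  }
  img <- with_seed(spec$seed, {
    if (spec$blur_sigma_px > 0)
      img <- EBImage::imageData(EBImage::gblur(img, spec$blur_sigma_px))
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
    pmax(img, 0)
  })
  truth <- phantom_truth("vessel", list(
    segments = truth_tab, pixel_size_um = spec$pixel_size_um,
    background = spec$background, blur_sigma_px = spec$blur_sigma_px,
    noise_sigma = spec$noise_sigma))
  list(image = img, truth = truth, pixel_size_um = spec$pixel_size_um)
}
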