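# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the package's own code paths.

# Welch t statistic by the textbook formula
oracle_welch_t <- function(a, b) {
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  (mean(a) - mean(b)) / se
}

# two-sample KS D by enumerating ECDF steps at the pooled points
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(p) mean(a <= p), numeric(1))
  Fb <- vapply(pts, function(p) mean(b <= p), numeric(1))
  max(abs(Fa - Fb))
}

# all ISODATA fixed-point partitions of an intensity sample, by testing
# every integer threshold: candidate g is a fixed point when thresholding
# at the implied midpoint reproduces the partition at g
oracle_isodata_partitions <- function(v) {
  parts <- integer(0)
  for (g in seq(ceiling(min(v)) + 1L, floor(max(v)))) {
    lo <- v[v < g]; hi <- v[v >= g]
    if (!length(lo) || !length(hi)) next
    m <- (mean(lo) + mean(hi)) / 2
    if (sum(v < m) == sum(v < g)) parts <- c(parts, sum(v < g))
  }
  unique(parts)
}

# per-tile mean by explicit loops
oracle_tile_means <- function(A, w) {
  ny <- nrow(A) %/% w; nx <- ncol(A) %/% w
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx))
    out[i, j] <- mean(A[(i - 1) * w + 1:w, (j - 1) * w + 1:w])
  out
}

# horizontal bar mask: rows r0..r0+width-1, cols c0..c0+len-1
bar_mask <- function(h, w, r0, c0, width, len) {
  m <- matrix(FALSE, h, w)
  m[r0:(r0 + width - 1), c0:(c0 + len - 1)] <- TRUE
  m
}

# five parallel full-length vessels of widths 3..11 px on a square canvas
five_bar_phantom <- function(blur = 0, noise = 0, seed = 4) {
  segs <- data.frame(x0 = 10, y0 = c(30, 90, 150, 210, 270), x1 = 310,
                     y1 = c(30, 90, 150, 210, 270),
                     width_um = c(3, 5, 7, 9, 11), intensity = 100)
  generate_vessel_phantom(vessel_phantom_spec(
    canvas = c(320, 320), segments = segs, blur_sigma_px = blur,
    noise_sigma = noise, seed = seed))
}

random_mask <- function(h, w, p = 0.4) matrix(runif(h * w) < p, h, w)

# count of 8-connected components by repeated flood fill (queue-based),
# independent of the package's labelling
oracle_n_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  n <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    n <- n + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r <- (q - 1) %% h + 1; c <- (q - 1) %/% h + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > h || cc < 1 || cc > w) next
        lin <- (cc - 1) * h + rr
        if (mask[lin] && !seen[lin]) { seen[lin] <- TRUE; queue <- c(queue, lin) }
      }
    }
  }
  n
}
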