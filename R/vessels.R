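#' Confocal z-stack container
#'
#' @param volume numeric array `y x x x z` of intensities.
#' @param voxel_um named numeric vector `c(z = , y = , x = )`, voxel size in
#'   micrometers; all entries > 0.
#' @param metadata optional named list (channel, objective, ...).
#' @return an object of class `confocal_stack`.
#' @export
confocal_stack <- function(volume, voxel_um, metadata = list()) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("'volume' must be a y x x x z array", call. = FALSE)
  if (!all(c("z", "y", "x") %in% names(voxel_um)) || any(voxel_um <= 0))
    stop("'voxel_um' must be a positive vector with names z, y, x",
         call. = FALSE)
  structure(list(volume = volume, voxel_um = voxel_um, metadata = metadata),
            class = "confocal_stack")
}

#' @export
print.confocal_stack <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf(
    "<confocal_stack: %d x %d px, %d slices, voxel %g x %g x %g um (z,y,x)>\n",
    d[1], d[2], d[3], x$voxel_um["z"], x$voxel_um["y"], x$voxel_um["x"]))
  invisible(x)
}

#' Reduce a confocal stack to maximum intensity projections
#'
#' Partitions the z-stack into consecutive slabs of
#' `floor(slab_um / z_step)` slices and takes the pixelwise maximum within
#' each slab (~70-um slabs by default). A trailing remainder of fewer than
#' half a slab is discarded; a larger remainder is kept as a final thin
#' MIP. Either way the handling is reported via `message()`.
#'
#' @param stack a [confocal_stack()].
#' @param slab_um slab thickness in micrometers; must be at least one z
#'   step.
#' @return an object of class `mip_series`: list with `mips` (list of
#'   matrices), `slab_um`, and `z_ranges` (slice index range per MIP).
#' @export
make_mips <- function(stack, slab_um = 70) {
  stopifnot(inherits(stack, "confocal_stack"))
  zs <- stack$voxel_um["z"]
  if (slab_um < zs)
    stop("'slab_um' is smaller than one z slice", call. = FALSE)
  per <- as.integer(floor(slab_um / zs))
  nz <- dim(stack$volume)[3]
  n_full <- nz %/% per
  rem <- nz - n_full * per
  blocks <- if (n_full > 0)
    lapply(seq_len(n_full), function(b) ((b - 1L) * per + 1L):(b * per))
  else list()
  if (rem > 0) {
    if (rem >= per / 2) {
      message(sprintf("keeping trailing thin MIP of %d slice(s)", rem))
      blocks <- c(blocks, list((n_full * per + 1L):nz))
    } else {
      message(sprintf("discarding trailing remainder of %d slice(s)", rem))
    }
  }
  if (!length(blocks))
    stop("stack too thin for a single MIP", call. = FALSE)
  mips <- lapply(blocks, function(b) {
    apply(stack$volume[, , b, drop = FALSE], c(1, 2), max)
  })
  structure(list(mips = mips, slab_um = slab_um,
                 z_ranges = lapply(blocks, range)),
            class = "mip_series")
}

#' @export
print.mip_series <- function(x, ...) {
  cat(sprintf("<mip_series: %d MIP(s) of ~%g um>\n", length(x$mips),
              x$slab_um))
  invisible(x)
}

#' Majority-vote consensus of reader-drawn ROI masks
#'
#' A pixel belongs to the consensus when strictly more than half of the
#' readers included it (2-of-3 for three readers). The result always lies
#' between the intersection and the union of the reader masks.
#'
#' @param reader_masks list of >= 2 logical matrices of identical shape.
#' @return an object of class `consensus_roi`: list with `mask`,
#'   `n_readers`, `vote_threshold`.
#' @export
consensus_roi <- function(reader_masks) {
  if (!is.list(reader_masks) || length(reader_masks) < 2L)
    stop("need at least 2 reader masks", call. = FALSE)
  masks <- lapply(reader_masks, check_flag_matrix, name = "reader mask")
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) all(dim(m) == d), logical(1))))
    stop("reader masks differ in shape", call. = FALSE)
  votes <- Reduce(`+`, masks)
  n <- length(masks)
  structure(list(mask = votes > n / 2, n_readers = n,
                 vote_threshold = n / 2),
            class = "consensus_roi")
}

#' Iterative-selection (ISODATA) intensity threshold
#'
#' Starting from the mean intensity inside the ROI, iterates
#' `t <- (mean below t + mean at/above t) / 2` until the induced
#' below/above partition stops changing, at which point the threshold is an
#' exact fixed point of the update map (for a finite sample the midpoint
#' depends only on the partition). This is the classic iterative-selection
#' / Ridler-Calvard binarization.
#'
#' @param image numeric matrix.
#' @param roi optional logical matrix or [consensus_roi()]; statistics are
#'   computed inside the ROI only.
#' @return the converged threshold (scalar). Foreground is `image >=
#'   threshold`.
#' @export
iterative_threshold <- function(image, roi = NULL) {
  if (inherits(roi, "consensus_roi")) roi <- roi$mask
  v <- if (is.null(roi)) as.numeric(image) else {
    roi <- check_flag_matrix(roi, "roi")
    if (!all(dim(roi) == dim(image)))
      stop("ROI shape does not match the image", call. = FALSE)
    as.numeric(image[roi])
  }
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L)
    stop("degenerate histogram: ROI holds fewer than 2 distinct intensities",
         call. = FALSE)
  t <- mean(v)
  for (it in seq_len(1000L)) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (sum(v < t_new) == length(lo)) { t <- t_new; break }
    t <- t_new
  }
  t
}

#' Label 8-connected components of a binary mask
#'
#' Connected-component labelling with 8-connectivity (the convention used
#' throughout the vessel pipeline, appropriate for thin structures).
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 is background, components
#'   are numbered from 1.
#' @export
label_components <- function(mask) {
  mask <- check_flag_matrix(mask, "mask")
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  labels <- matrix(0L, h, w)
  if (!length(idx)) return(labels)
  pos <- integer(h * w)
  pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    dy <- off[1]; dx <- off[2]
    r1 <- max(1L, 1L - dy):min(h, h - dy)
    c1 <- max(1L, 1L - dx):min(w, w - dx)
    both <- mask[r1, c1, drop = FALSE] &
      mask[r1 + dy, c1 + dx, drop = FALSE]
    hit <- which(both)
    if (!length(hit)) next
    rr <- r1[(hit - 1L) %% length(r1) + 1L]
    cc <- c1[(hit - 1L) %/% length(r1) + 1L]
    a <- (cc - 1L) * h + rr
    b <- (cc + dx - 1L) * h + rr + dy
    edges <- c(edges, rbind(pos[a], pos[b]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  labels[idx] <- as.integer(igraph::components(g)$membership)
  labels
}

#' Remove connected components below a physical area threshold
#'
#' Drops 8-connected components whose area (pixel count times pixel area)
#' is strictly smaller than `min_area_um2`; components of exactly the
#' threshold area are kept. The output is a subset of the input and the
#' operation is idempotent.
#'
#' @param mask logical matrix.
#' @param pixel_area_um2 area of one pixel in square micrometers.
#' @param min_area_um2 minimum component area to keep (default 51).
#' @return filtered logical matrix.
#' @export
size_filter <- function(mask, pixel_area_um2, min_area_um2 = 51) {
  check_scalar_pos(pixel_area_um2, "pixel_area_um2")
  labels <- label_components(mask)
  if (max(labels) == 0L) return(labels > 0L)
  sizes <- tabulate(labels[labels > 0L])
  keep <- sizes * pixel_area_um2 >= min_area_um2
  labels > 0L & keep[pmax(labels, 1L)]
}

# neighbour shift of the zero-padded mask: value of the (dy, dx) neighbour
# at each pixel
shift_mask <- function(P, h, w, dy, dx) {
  P[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx), drop = FALSE]
}

#' Topology-preserving skeletonization (thinning) of a binary mask
#'
#' Iterative Zhang-Suen thinning: boundary pixels are peeled in two
#' alternating sub-iterations until no pixel can be removed without
#' breaking 8-connectivity or shortening line ends, leaving one-pixel-wide
#' centerlines. The skeleton is a subset of the mask and preserves the
#' number of connected components.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape, the skeleton.
#' @export
skeletonize_mask <- function(mask) {
  mask <- check_flag_matrix(mask, "mask")
  h <- nrow(mask); w <- ncol(mask)
  M <- mask
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P <- matrix(FALSE, h + 2L, w + 2L)
      P[2:(h + 1), 2:(w + 1)] <- M
      # neighbours p2..p9 clockwise from north (row - 1)
      p2 <- shift_mask(P, h, w, -1L, 0L); p3 <- shift_mask(P, h, w, -1L, 1L)
      p4 <- shift_mask(P, h, w, 0L, 1L);  p5 <- shift_mask(P, h, w, 1L, 1L)
      p6 <- shift_mask(P, h, w, 1L, 0L);  p7 <- shift_mask(P, h, w, 1L, -1L)
      p8 <- shift_mask(P, h, w, 0L, -1L); p9 <- shift_mask(P, h, w, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- M & B >= 2 & B <= 6 & A == 1
      if (sub == 1)
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      else
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      if (any(cond)) {
        M[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  M
}

# 8-neighbour adjacency of skeleton pixels: list mapping each skeleton
# pixel (by position in idx) to the positions of its skeleton neighbours
skeleton_adjacency <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  idx <- which(skel)
  pos <- integer(h * w)
  pos[idx] <- seq_along(idx)
  adj <- vector("list", length(idx))
  if (!length(idx)) return(list(idx = idx, adj = adj))
  r <- (idx - 1L) %% h + 1L
  c <- (idx - 1L) %/% h + 1L
  offs <- cbind(dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    rn <- r + offs[k, 1]; cn <- c + offs[k, 2]
    ok <- rn >= 1L & rn <= h & cn >= 1L & cn <= w
    lin <- (cn[ok] - 1L) * h + rn[ok]
    hit <- pos[lin] > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, pos[lin[hit]])
  }
  if (length(from)) {
    ord <- order(from, to)
    adj <- split(to[ord], factor(from[ord], levels = seq_along(idx)))
  }
  list(idx = idx, adj = adj)
}

#' Split a skeleton into branch-free vessel segments
#'
#' Breaks a one-pixel-wide skeleton at branch points (pixels with three or
#' more skeleton neighbours); every returned segment is a maximal
#' branch-free polyline. Segment length is the sum of step costs along the
#' path: 1 per axial step, `sqrt(2)` per diagonal step (in pixels).
#' Isolated skeleton pixels become single-point segments of length 0;
#' isolated cycles are traced as closed segments.
#'
#' @param skel logical skeleton matrix (e.g. from [skeletonize_mask()]).
#' @return list of segments, each a list with `pixels` (linear indices into
#'   the matrix) and `length_px`.
#' @export
segment_skeleton <- function(skel) {
  skel <- check_flag_matrix(skel, "skel")
  h <- nrow(skel)
  net <- skeleton_adjacency(skel)
  idx <- net$idx
  if (!length(idx)) return(list())
  deg <- lengths(net$adj)
  step_cost <- function(a, b) {
    dr <- abs((idx[a] - 1L) %% h - (idx[b] - 1L) %% h)
    dc <- abs((idx[a] - 1L) %/% h - (idx[b] - 1L) %/% h)
    sqrt(dr^2 + dc^2)
  }
  edge_key <- function(a, b) paste0(pmin(a, b), "-", pmax(a, b))
  used <- new.env(hash = TRUE, parent = emptyenv())
  segments <- list()
  walk <- function(v, u) {
    # walk from node v through u until the next node; returns path positions
    path <- c(v, u)
    assign(edge_key(v, u), TRUE, envir = used)
    prev <- v
    while (deg[u] == 2L) {
      nxt <- net$adj[[u]]
      nxt <- nxt[nxt != prev]
      if (!length(nxt)) break              # defensive: dangling
      if (exists(edge_key(u, nxt[1]), envir = used)) break  # closed loop
      assign(edge_key(u, nxt[1]), TRUE, envir = used)
      path <- c(path, nxt[1])
      prev <- u
      u <- nxt[1]
    }
    path
  }
  nodes <- which(deg != 2L)
  for (v in nodes) {
    if (deg[v] == 0L) {
      segments[[length(segments) + 1L]] <-
        list(pixels = idx[v], length_px = 0)
      next
    }
    for (u in net$adj[[v]]) {
      if (exists(edge_key(v, u), envir = used)) next
      path <- walk(v, u)
      len <- sum(step_cost(path[-length(path)], path[-1]))
      segments[[length(segments) + 1L]] <-
        list(pixels = idx[path], length_px = len)
    }
  }
  # remaining degree-2 pixels not on any walked path belong to pure cycles
  on_path <- logical(length(idx))
  for (s in segments) on_path[match(s$pixels, idx)] <- TRUE
  for (v in which(deg == 2L & !on_path)) {
    if (on_path[v]) next
    path <- walk(v, net$adj[[v]][1])
    # close the loop back to the start
    last <- path[length(path)]
    if (v %in% net$adj[[last]] && length(path) > 2L) {
      assign(edge_key(last, v), TRUE, envir = used)
      path <- c(path, v)
    }
    on_path[path] <- TRUE
    len <- sum(step_cost(path[-length(path)], path[-1]))
    segments[[length(segments) + 1L]] <-
      list(pixels = idx[unique(path)], length_px = len)
  }
  segments
}

#' Per-segment mean vessel diameters from the Euclidean distance transform
#'
#' Local vessel caliber at each skeleton point is estimated from the
#' Euclidean distance transform of the vessel mask: `diameter = 2 d - 1`
#' pixels, where `d` is the distance from the skeleton pixel center to the
#' nearest background pixel center (exact for odd pixel widths). Each
#' segment contributes a single value — the mean over its skeleton points —
#' so long vessels do not dominate diameter statistics.
#'
#' @param mask logical vessel mask.
#' @param segments segment list from [segment_skeleton()].
#' @param pixel_size_um pixel edge length in micrometers.
#' @param mip optional MIP index recorded in the table.
#' @return a `data.frame` (the vessel segment table) with columns `id`,
#'   `length_um`, `diameter_um`, `area_um2` (area of the parent connected
#'   component) and `mip`.
#' @export
vessel_diameters <- function(mask, segments, pixel_size_um = 1, mip = 1L) {
  mask <- check_flag_matrix(mask, "mask")
  check_scalar_pos(pixel_size_um, "pixel_size_um")
  edt <- EBImage::imageData(EBImage::distmap(mask + 0))
  labels <- label_components(mask)
  sizes <- if (max(labels) > 0) tabulate(labels[labels > 0]) else integer(0)
  n <- length(segments)
  out <- data.frame(id = integer(n), length_um = numeric(n),
                    diameter_um = numeric(n), area_um2 = numeric(n),
                    mip = rep(as.integer(mip), n))
  for (i in seq_len(n)) {
    px <- segments[[i]]$pixels
    d <- edt[px]
    if (any(d == 0))
      stop("segment point lies on background: mask and skeleton disagree",
           call. = FALSE)
    comp <- labels[px[1]]
    out$id[i] <- i
    out$length_um[i] <- segments[[i]]$length_px * pixel_size_um
    out$diameter_um[i] <- mean(2 * d - 1) * pixel_size_um
    out$area_um2[i] <- sizes[comp] * pixel_size_um^2
  }
  out
}

#' Vessel density over the best-covered MIPs
#'
#' Ranks MIPs by their total skeleton length and computes vessel density as
#' total centerline length divided by total analyzed (ROI) area over the
#' `n_select` MIPs with the longest vessel lengths (default 5, matching the
#' variable 7-12 MIPs available per animal). With fewer MIPs than
#' `n_select`, all are used with a warning.
#'
#' @param tables list of vessel segment tables (one per MIP, from
#'   [vessel_diameters()]).
#' @param roi_areas_um2 numeric vector of analyzed ROI areas, one per MIP.
#' @param n_select number of MIPs to pool (default 5).
#' @return list with `density_per_um` (um / um^2 = 1/um), `selected` (MIP
#'   indices used), `total_length_um`, `total_area_um2`.
#' @export
vessel_density <- function(tables, roi_areas_um2, n_select = 5) {
  if (length(tables) != length(roi_areas_um2))
    stop("need one ROI area per MIP table", call. = FALSE)
  lens <- vapply(tables, function(tb) sum(tb$length_um), numeric(1))
  if (length(tables) < n_select) {
    warning(sprintf("only %d MIP(s) available; using all (n_select = %d)",
                    length(tables), n_select))
    n_select <- length(tables)
  }
  sel <- order(-lens, seq_along(lens))[seq_len(n_select)]
  tot_area <- sum(roi_areas_um2[sel])
  if (tot_area <= 0) stop("zero total ROI area", call. = FALSE)
  list(density_per_um = sum(lens[sel]) / tot_area, selected = sort(sel),
       total_length_um = sum(lens[sel]), total_area_um2 = tot_area)
}

#' Mode-normalized vessel diameter histogram
#'
#' Bins per-segment mean diameters on `(0, d_max]` and normalizes the
#' counts to the bin with the most counts, so the maximum normalized count
#' is exactly 1 for any nonempty input. The default 1-um bins up to 12 um
#' target the microvascular range.
#'
#' @param tables a vessel segment table, a list of them, or a numeric
#'   vector of diameters (um).
#' @param bin_width_um histogram bin width (default 1 um).
#' @param d_max_um upper diameter bound (default 12 um).
#' @return an object of class `diameter_histogram`: list with
#'   `bin_centers_um`, `counts`, `normalized`, `bin_width_um`, `n_segments`.
#' @export
diameter_histogram <- function(tables, bin_width_um = 1, d_max_um = 12) {
  d <- if (is.numeric(tables)) tables
  else if (is.data.frame(tables)) tables$diameter_um
  else unlist(lapply(tables, `[[`, "diameter_um"))
  if (!length(d)) stop("no segments supplied", call. = FALSE)
  d <- d[d > 0 & d <= d_max_um]
  if (!length(d))
    stop("all diameters fall outside (0, d_max_um]", call. = FALSE)
  breaks <- seq(0, d_max_um, by = bin_width_um)
  if (breaks[length(breaks)] < d_max_um) breaks <- c(breaks, d_max_um)
  counts <- as.numeric(table(cut(d, breaks, include.lowest = FALSE)))
  structure(list(bin_centers_um = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, normalized = counts / max(counts),
                 bin_width_um = bin_width_um, n_segments = length(d)),
            class = "diameter_histogram")
}

#' @export
print.diameter_histogram <- function(x, ...) {
  cat(sprintf("<diameter_histogram: %d segments, %g-um bins, mode at %g um>\n",
              x$n_segments, x$bin_width_um,
              x$bin_centers_um[which.max(x$counts)]))
  invisible(x)
}

#' @export
plot.diameter_histogram <- function(x, ...) {
  graphics::plot(x$bin_centers_um, x$normalized, type = "h", lwd = 6,
                 lend = 1, xlab = "vessel diameter (um)",
                 ylab = "normalized count", ylim = c(0, 1), ...)
  invisible(x)
}

#' Full single-MIP morphometry pipeline
#'
#' Chains iterative-selection thresholding (within the consensus ROI),
#' size filtering, skeletonization, segment extraction and per-segment
#' diameter estimation for one MIP.
#'
#' @param image MIP intensity matrix.
#' @param roi logical matrix or [consensus_roi()]; pixels outside it are
#'   excluded from all statistics.
#' @param pixel_size_um pixel edge length in micrometers.
#' @param min_area_um2 component size threshold (default 51).
#' @param mip MIP index recorded in the output table.
#' @return list with `threshold`, `mask`, `skeleton`, `segments`, `table`,
#'   and `roi_area_um2`.
#' @export
analyze_mip <- function(image, roi = NULL, pixel_size_um = 1,
                        min_area_um2 = 51, mip = 1L) {
  if (inherits(roi, "consensus_roi")) roi <- roi$mask
  if (is.null(roi)) roi <- matrix(TRUE, nrow(image), ncol(image))
  roi <- check_flag_matrix(roi, "roi")
  thr <- iterative_threshold(image, roi)
  mask <- image >= thr & roi
  mask <- size_filter(mask, pixel_size_um^2, min_area_um2)
  skel <- skeletonize_mask(mask)
  segs <- segment_skeleton(skel)
  tab <- vessel_diameters(mask, segs, pixel_size_um, mip = mip)
  list(threshold = thr, mask = mask, skeleton = skel, segments = segs,
       table = tab, roi_area_um2 = sum(roi) * pixel_size_um^2)
}
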