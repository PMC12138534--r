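test_that("MIP slabs partition the stack with the documented remainder rule", {
  # 10 slices at 7 um, 70-um slab: one MIP = pixelwise max of everything
  vol <- array(0, c(4, 4, 10))
  for (k in 1:10) vol[, , k] <- k
  st <- confocal_stack(vol, voxel_um = c(z = 7, y = 1, x = 1))
  ms <- make_mips(st, 70)
  expect_length(ms$mips, 1)
  expect_equal(ms$mips[[1]], matrix(10, 4, 4))

  # per-pixel max semantics with slice-dependent values
  vol2 <- array(0, c(2, 2, 100))
  for (k in 1:100) vol2[, , k] <- k
  ms2 <- make_mips(confocal_stack(vol2, c(z = 7, y = 1, x = 1)), 70)
  expect_length(ms2$mips, 10)  # floor(70/7) = 10 slices per block
  expect_equal(ms2$mips[[3]][1, 1], 30)  # max slice index of block 3

  # remainder >= half a slab is kept as a thin MIP, smaller is discarded
  vol3 <- array(1, c(2, 2, 25))
  expect_message(
    ms3 <- make_mips(confocal_stack(vol3, c(z = 7, y = 1, x = 1)), 70),
    "thin MIP")
  expect_length(ms3$mips, 3)
  vol4 <- array(1, c(2, 2, 23))
  expect_message(
    ms4 <- make_mips(confocal_stack(vol4, c(z = 7, y = 1, x = 1)), 70),
    "discarding")
  expect_length(ms4$mips, 2)

  expect_error(make_mips(confocal_stack(vol3, c(z = 7, y = 1, x = 1)), 3),
               "smaller")
})

test_that("consensus ROI is the per-pixel majority vote", {
  A <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(consensus_roi(list(A, A, A))$mask, A)
  empty <- matrix(FALSE, 2, 2)
  expect_equal(consensus_roi(list(A, A, empty))$mask, A)  # 2-of-3

  set.seed(12)
  for (rep in 1:20) {
    masks <- list(random_mask(9, 9), random_mask(9, 9), random_mask(9, 9))
    votes <- masks[[1]] + masks[[2]] + masks[[3]]
    cons <- consensus_roi(masks)$mask
    expect_equal(cons, votes >= 2)                     # brute-force tally
    inter <- masks[[1]] & masks[[2]] & masks[[3]]
    uni <- masks[[1]] | masks[[2]] | masks[[3]]
    expect_true(all(cons[inter]))                      # intersection subset
    expect_true(all(uni[cons]))                        # subset of union
  }
  expect_error(consensus_roi(list(A)), "at least 2")
  expect_error(consensus_roi(list(A, matrix(TRUE, 3, 3))), "shape")
})

test_that("iterative selection converges to the fixed-point threshold", {
  # two equal classes at 10 and 20: symmetry fixes the midpoint
  img <- matrix(rep(c(10, 20), each = 200), 20, 20)
  expect_equal(iterative_threshold(img), 15)
  # unequal counts 300/100: t0 = 12.5, class means 10 and 20, t = 15
  img2 <- matrix(c(rep(10, 300), rep(20, 100)), 20, 20)
  expect_equal(iterative_threshold(img2), 15)

  # random 8-bit phantoms: the induced partition must be an exhaustive
  # fixed-point partition, and t must satisfy the fixed-point equation
  set.seed(33)
  for (rep in 1:10) {
    v <- c(rpois(300, 30), rpois(120, 150))
    img3 <- matrix(pmin(v, 255), 21, 20)
    t <- iterative_threshold(img3)
    vv <- as.numeric(img3)
    expect_lt(abs(t - (mean(vv[vv < t]) + mean(vv[vv >= t])) / 2), 0.5)
    expect_true(sum(vv < t) %in% oracle_isodata_partitions(vv))
  }
  expect_error(iterative_threshold(matrix(5, 3, 3)), "degenerate")
})

test_that("thresholding restricts its statistics to the ROI", {
  img <- matrix(10, 10, 10)
  img[1:5, ] <- rep(c(50, 200), length.out = 50)
  roi <- matrix(FALSE, 10, 10); roi[1:5, ] <- TRUE
  expect_equal(iterative_threshold(img, roi), 125)  # outside-ROI 10s ignored
})

test_that("size filter removes strictly sub-threshold components only", {
  m <- matrix(FALSE, 40, 220)
  m[2:6, 2:11] <- TRUE       # 50 px
  m[12:14, 21:37] <- TRUE    # 51 px
  m[22:27, 41:50] <- TRUE    # 60 px
  out <- size_filter(m, pixel_area_um2 = 1, min_area_um2 = 51)
  expect_false(any(out[2:6, 2:11]))
  expect_true(all(out[12:14, 21:37]))
  expect_true(all(out[22:27, 41:50]))
  expect_equal(size_filter(out, 1, 51), out)          # idempotent
  expect_true(all(m[out]))                            # subset of input
  none <- matrix(FALSE, 5, 5)
  expect_equal(size_filter(none, 1, 51), none)
})

test_that("8-connected labelling matches a flood-fill oracle", {
  set.seed(9)
  for (rep in 1:10) {
    m <- random_mask(15, 15, p = 0.35)
    expect_equal(max(label_components(m)), oracle_n_components(m))
  }
  diagpair <- matrix(FALSE, 4, 4); diagpair[1, 1] <- diagpair[2, 2] <- TRUE
  expect_equal(max(label_components(diagpair)), 1)  # diagonal connectivity
})

test_that("skeletonization thins to centerlines preserving components", {
  # 100 x 5 bar: one centerline along the bar, shortened only by end
  # effects of the thinning (at most about one bar-width per end)
  m <- bar_mask(20, 120, 8, 11, 5, 100)
  sk <- skeletonize_mask(m)
  expect_true(all(m[sk]))                    # skeleton subset of mask
  segs <- segment_skeleton(sk)
  expect_length(segs, 1)
  expect_gt(segs[[1]]$length_px, 100 - 2 * 5)
  expect_lte(segs[[1]]$length_px, 100)
  # one-pixel-wide: no fully set 2x2 block
  expect_false(any(sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
                     sk[-nrow(sk), -1] & sk[-1, -1]))

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(skeletonize_mask(single), single)
  expect_equal(sum(skeletonize_mask(matrix(FALSE, 5, 5))), 0)

  set.seed(14)
  for (rep in 1:5) {
    blobs <- EBImage::imageData(EBImage::gblur(random_mask(40, 40, 0.3) + 0,
                                               2)) > 0.3
    sk2 <- skeletonize_mask(blobs)
    expect_true(all(blobs[sk2]))
    expect_equal(oracle_n_components(sk2), oracle_n_components(blobs))
  }
})

test_that("skeleton segmentation splits at branch points with weighted lengths", {
  # straight 10-px path: 9 unit steps
  p <- matrix(FALSE, 5, 15); p[3, 3:12] <- TRUE
  segs <- segment_skeleton(p)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$length_px, 9)

  # 10-px diagonal: 9 diagonal steps
  d <- matrix(FALSE, 14, 14)
  for (k in 1:10) d[2 + k, 2 + k] <- TRUE
  expect_equal(segment_skeleton(d)[[1]]$length_px, 9 * sqrt(2))

  # Y junction: three branch-free arms meeting at one pixel (a straight
  # 8-connected T has diagonally adjacent branch pixels, so a clean
  # three-arm junction needs diagonal arms)
  tj <- matrix(FALSE, 15, 15)
  tj[cbind(8 - (0:3), 8 - (0:3))] <- TRUE   # north-west diagonal arm
  tj[cbind(8 - (1:3), 8 + (1:3))] <- TRUE   # north-east diagonal arm
  tj[8:12, 8] <- TRUE                       # south arm
  deg3 <- sum(vapply(which(tj), function(i) {
    r <- (i - 1) %% 15 + 1; c <- (i - 1) %/% 15 + 1
    sum(tj[max(1, r - 1):min(15, r + 1), max(1, c - 1):min(15, c + 1)]) - 1
  }, numeric(1)) >= 3)
  expect_equal(deg3, 1)
  expect_length(segment_skeleton(tj), 3)
})

test_that("distance-transform diameters are exact on odd-width bars", {
  m <- bar_mask(20, 120, 8, 11, 5, 100)
  tab <- vessel_diameters(m, segment_skeleton(skeletonize_mask(m)), 1)
  expect_equal(tab$diameter_um, 5, tolerance = 0.2)

  two <- bar_mask(40, 120, 5, 11, 3, 100) |
    bar_mask(40, 120, 20, 11, 9, 100)
  tab2 <- vessel_diameters(two, segment_skeleton(skeletonize_mask(two)), 1)
  expect_equal(sort(tab2$diameter_um), c(3, 9), tolerance = 0.15)
  # each bar contributes exactly one value regardless of length
  expect_equal(nrow(tab2), 2)

  # disk of radius r: the maximum local diameter reaches about 2r
  r <- 9
  xs <- matrix(rep(1:40, each = 40), 40, 40)
  disk <- (xs - 20)^2 + (t(xs) - 20)^2 <= r^2
  skd <- skeletonize_mask(disk)
  edt <- EBImage::imageData(EBImage::distmap(disk + 0))
  expect_equal(max(2 * edt[skd] - 1), 2 * r, tolerance = 0.15)

  # a segment off the mask is an inconsistency, not a zero diameter
  bad <- list(list(pixels = which(!m)[1], length_px = 0))
  expect_error(vessel_diameters(m, bad, 1), "background")
})

test_that("vessel density pools the MIPs with the longest vessel length", {
  tab1 <- data.frame(id = 1, length_um = 100, diameter_um = 5,
                     area_um2 = 600, mip = 1)
  expect_equal(vessel_density(list(tab1), 10000, n_select = 1)$density_per_um,
               0.01)

  tab2 <- data.frame(id = 1, length_um = 250, diameter_um = 5,
                     area_um2 = 900, mip = 2)
  both <- vessel_density(list(tab1, tab2), c(5000, 5000), n_select = 2)
  expect_equal(both$density_per_um, (100 + 250) / 10000)

  # 7 tables: selection must match a brute-force sort of total lengths
  set.seed(6)
  lens <- sample(50:500, 7)
  tabs <- lapply(lens, function(L)
    data.frame(id = 1, length_um = L, diameter_um = 4, area_um2 = 100,
               mip = 1))
  vd <- vessel_density(tabs, rep(1000, 7), n_select = 5)
  expect_equal(sort(vd$selected), sort(order(-lens)[1:5]))
  expect_equal(vd$total_length_um, sum(sort(lens, decreasing = TRUE)[1:5]))

  expect_warning(vessel_density(list(tab1, tab2), c(1, 1), n_select = 5),
                 "using all")
  expect_error(vessel_density(list(tab1), 0, n_select = 1), "zero")
})

test_that("diameter histograms are normalized to the modal bin", {
  h <- diameter_histogram(c(3.5, 3.5, 5.5))
  expect_equal(max(h$normalized), 1)
  expect_equal(h$normalized[h$bin_centers_um == 3.5], 1)
  expect_equal(h$normalized[h$bin_centers_um == 5.5], 0.5)

  h1 <- diameter_histogram(7.2)
  expect_equal(sum(h1$counts), 1)
  expect_equal(max(h1$normalized), 1)

  set.seed(31)
  for (rep in 1:20) {
    d <- runif(sample(1:50, 1), 0.5, 11.5)
    expect_equal(max(diameter_histogram(d)$normalized), 1)
  }
  expect_error(diameter_histogram(c(15, 20)), "outside")
  expect_error(diameter_histogram(numeric(0)), "no segments")
})

test_that("phantom morphometry recovers geometry within tolerance", {
  # noiseless: density within 5% of truth, per-segment diameter within 1 px
  ph <- five_bar_phantom()
  a <- analyze_mip(ph$image, pixel_size_um = 1)
  truth <- ph$truth$parameters$segments
  expect_equal(nrow(a$table), 5)
  expect_true(all(abs(sort(a$table$diameter_um) - sort(truth$width_um)) <= 1))
  dens <- vessel_density(list(a$table), a$roi_area_um2, n_select = 1)
  expect_equal(dens$density_per_um, sum(truth$length_um) / a$roi_area_um2,
               tolerance = 0.05)

  # blur sigma 1 px + 5% noise: within 15% and 1.5 px
  phn <- five_bar_phantom(blur = 1, noise = 5, seed = 4)
  an <- analyze_mip(phn$image, pixel_size_um = 1)
  expect_true(all(abs(sort(an$table$diameter_um) - sort(truth$width_um)) <= 1.5))
  densn <- vessel_density(list(an$table), an$roi_area_um2, n_select = 1)
  expect_equal(densn$density_per_um, sum(truth$length_um) / an$roi_area_um2,
               tolerance = 0.15)
})

test_that("vessel phantoms are deterministic with exact raster truth", {
  spec <- vessel_phantom_spec(canvas = c(60, 120), segments = data.frame(
    x0 = 11, y0 = 30, x1 = 110, y1 = 30, width_um = 5, intensity = 100),
    blur_sigma_px = 0.8, noise_sigma = 3, seed = 77)
  p1 <- generate_vessel_phantom(spec)
  p2 <- generate_vessel_phantom(spec)
  expect_identical(p1$image, p2$image)

  # noiseless horizontal bar: capsule raster = 100 x 5 rectangle + round caps
  clean <- generate_vessel_phantom(vessel_phantom_spec(
    canvas = c(60, 120), segments = data.frame(
      x0 = 11, y0 = 30, x1 = 110, y1 = 30, width_um = 5, intensity = 100)))
  tr <- clean$truth$parameters$segments
  expect_equal(tr$length_um, 99)  # endpoint-to-endpoint distance
  expect_equal(tr$width_um, 5)
  expect_gte(tr$area_px, 99 * 5)

  expect_error(generate_vessel_phantom(vessel_phantom_spec(
    canvas = c(60, 120), segments = data.frame(
      x0 = 500, y0 = 500, x1 = 600, y1 = 500, width_um = 5,
      intensity = 100))), "outside")

  blank <- generate_vessel_phantom(vessel_phantom_spec(canvas = c(20, 20)))
  expect_equal(nrow(blank$truth$parameters$segments), 0)
  expect_true(all(blank$image == 10))
})
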