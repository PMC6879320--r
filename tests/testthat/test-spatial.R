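gauss_spot <- function(n, cx, cy, sigma = 2, amp = 1000) {
  x <- matrix(rep(seq_len(n), each = n), n, n)
  y <- matrix(rep(seq_len(n), times = n), n, n)
  amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
}

test_that("a single Gaussian spot segments into one centred blob", {
  img <- gauss_spot(64, 40.0, 25.0)
  seg <- segment_blobs(img)
  expect_equal(nrow(seg$table), 1)
  expect_lt(abs(seg$table$centroid_x - 40), 0.5)
  expect_lt(abs(seg$table$centroid_y - 25), 0.5)
})

test_that("blob area matches the analytic disk area within 5%", {
  img <- disk_image(n = 64, radius = 10, value = 100)
  seg <- segment_blobs(img, sigma = 0, threshold = 50, pixel_size = 0.1)
  expect_equal(nrow(seg$table), 1)
  expect_equal(seg$table$area_um2, pi * 1, tolerance = 0.05)
})

test_that("blank images give zero blobs, not an error", {
  expect_equal(nrow(segment_blobs(matrix(0, 32, 32))$table), 0)
  expect_equal(nrow(segment_blobs(matrix(5, 32, 32))$table), 0)
})

test_that("Otsu segmentation is intensity-scale invariant", {
  set.seed(14)
  img <- gauss_spot(64, 20, 20) + gauss_spot(64, 45, 50) +
    matrix(stats::runif(64 * 64, 0, 20), 64, 64)
  s1 <- segment_blobs(img)
  s2 <- segment_blobs(img * 7.3)
  expect_identical(s1$labels, s2$labels)
})

test_that("adhesion areas scale as the squared radius and honour min_size", {
  img <- disk_image(128, 3, 100, cx = 20, cy = 20) +
    disk_image(128, 6, 100, cx = 64, cy = 64) +
    disk_image(128, 9, 100, cx = 100, cy = 100)
  res <- adhesion_areas(img, sigma = 0, threshold = 50, min_size = 1,
                        use_gradient = FALSE, pixel_size = 0.1)
  a <- sort(res$areas$area_um2)
  expect_equal(length(a), 3)
  expect_equal(a[2] / a[1], 4, tolerance = 0.15)
  expect_equal(a[3] / a[1], 9, tolerance = 0.15)
  # min_size excludes the smallest
  res2 <- adhesion_areas(img, sigma = 0, threshold = 50,
                         min_size = sum(disk_image(128, 3, 1) > 0) + 5,
                         use_gradient = FALSE, pixel_size = 0.1)
  expect_equal(nrow(res2$areas), 2)
  # overlapping disks merge into one blob
  img3 <- disk_image(64, 6, 100, cx = 30, cy = 30) +
    disk_image(64, 6, 100, cx = 36, cy = 30)
  res3 <- adhesion_areas(img3, sigma = 0, threshold = 50, min_size = 1,
                         use_gradient = FALSE)
  expect_equal(nrow(res3$areas), 1)
})

test_that("mask anisotropy: uniform fields give equal inside and outside", {
  set <- uniform_set(r = 0.2, total = 400, n = 64)
  seg <- segment_blobs(gauss_spot(64, 32, 32), min_size = 4)
  st <- anisotropy_in_masks(seg, set)
  inside <- st$mean_anisotropy[grepl("blob", st$label)]
  outside <- st$mean_anisotropy[st$label == "outside"]
  expect_lt(abs(inside - outside), 0.002)
  # single-pixel blob with min_size 1 still yields a record
  lone <- matrix(0, 64, 64); lone[10, 10] <- 100
  seg1 <- segment_blobs(lone, sigma = 0, threshold = 50, min_size = 1)
  st1 <- anisotropy_in_masks(seg1, set)
  expect_true(any(st1$n_pixels == 1))
})

test_that("a configured anisotropy contrast inside blobs is recovered", {
  ps <- make_pattern_scene(seed = 31, poisson = TRUE, read_noise_sd = 2)
  seg <- segment_blobs(ps$marker)
  st <- anisotropy_in_masks(seg, ps$set)
  inside <- mean(st$mean_anisotropy[grepl("blob", st$label)])
  outside <- st$mean_anisotropy[st$label == "outside"]
  expect_lt(abs((inside - outside) - (-0.05)), 0.01)
})

test_that("pattern lines are detected from their intensity dips", {
  ps <- make_pattern_scene(seed = 1, poisson = TRUE, read_noise_sd = 2)
  am <- compute_anisotropy(ps$set)
  pr <- pattern_rois(am$total_intensity, pixel_size = ps$set$pixel_size)
  expect_equal(length(pr$layout$line_x), length(ps$layout$line_x))
  expect_true(all(abs(pr$layout$line_x - ps$layout$line_x) <= 1))
  # on-pattern ROIs are centred on the dips, 1 um wide
  ctrs <- vapply(pr$on_pattern, function(r) r$x + (r$width - 1) / 2,
                 numeric(1))
  expect_true(all(abs(ctrs - ps$layout$line_x) <= 1.5))
  # inter-pattern squares sit at the midpoints
  mids <- vapply(pr$inter_pattern, function(r) r$x + (r$width - 1) / 2,
                 numeric(1))
  expect_true(all(abs(mids - (head(ps$layout$line_x, -1) + 10)) <= 1.5))
})

test_that("explicit layouts are honoured and off-image ROIs clipped", {
  img <- matrix(100, 60, 60)   # featureless: detection must fail
  expect_error(pattern_rois(img), "supply the pattern layout")
  lay <- pattern_layout(c(5, 55), spacing_um = 2)
  pr <- pattern_rois(img, layout = lay, pixel_size = 0.1)
  expect_equal(length(pr$on_pattern), 2)
  expect_true(any(grepl("clipped", vapply(pr$on_pattern, `[[`, "", "label"))))
})

test_that("aligned profiles are shift invariant and peak at distance zero", {
  ps <- make_pattern_scene(seed = 2)   # noiseless
  tru <- ps$truth
  lines <- lapply(seq_len(nrow(tru$centers)), function(i)
    region_line(tru$centers[i, "x"] - 6, tru$centers[i, "y"],
                tru$centers[i, "x"] + 6, tru$centers[i, "y"],
                line_width = 3))
  # deliberately offset half the lines by 2 px along their direction
  lines_off <- lines
  for (i in seq(1, length(lines), by = 2)) {
    lines_off[[i]]$x0 <- lines_off[[i]]$x0 - 2
    lines_off[[i]]$x1 <- lines_off[[i]]$x1 - 2
  }
  p1 <- aligned_line_profiles(ps$marker, ps$set, lines = lines)
  p2 <- aligned_line_profiles(ps$marker, ps$set, lines = lines_off)
  # compare only bins covered by every line in both runs (the offset
  # shortens one flank, so outer bins pool different line subsets)
  shared <- intersect(p1$distance_um, p2$distance_um)
  shared <- shared[abs(shared) <= 4 * ps$set$pixel_size]
  expect_equal(p1$marker_norm[match(shared, p1$distance_um)],
               p2$marker_norm[match(shared, p2$distance_um)],
               tolerance = 1e-3)
  expect_equal(max(p1$marker_norm), 1)
  expect_equal(p1$distance_um[which.max(p1$marker_norm)], 0)
  # the lowered-anisotropy zone is flat, so assert the contrast shape:
  # depressed at the peak, baseline beyond the zone radius
  r0 <- p1$partner_r[p1$distance_um == 0]
  r_far <- mean(p1$partner_r[abs(p1$distance_um) > 0.55], na.rm = TRUE)
  expect_lt(abs(r0 - min(p1$partner_r, na.rm = TRUE)), 1e-6)
  expect_lt(abs((r_far - r0) - ps$truth$r_contrast), 0.01)
})

test_that("profiles recover the configured anisotropy contrast", {
  ps <- make_pattern_scene(seed = 17, clusters_per_line = 3,
                           poisson = TRUE, read_noise_sd = 2)
  tru <- ps$truth
  n_lines <- min(20, nrow(tru$centers))
  lines <- lapply(seq_len(n_lines), function(i)
    region_line(tru$centers[i, "x"] - 7, tru$centers[i, "y"],
                tru$centers[i, "x"] + 7, tru$centers[i, "y"],
                line_width = 3))
  prof <- aligned_line_profiles(ps$marker, ps$set, lines = lines)
  r_in <- prof$partner_r[abs(prof$distance_um) < 0.15]
  r_out <- prof$partner_r[abs(prof$distance_um) > 0.6]
  contrast <- mean(r_out, na.rm = TRUE) - mean(r_in, na.rm = TRUE)
  expect_lt(abs(contrast - tru$r_contrast), 0.01)
})

test_that("flat marker lines are excluded", {
  set <- uniform_set(n = 64)
  flat <- matrix(1, 64, 64)
  expect_error(
    suppressMessages(
      aligned_line_profiles(flat, set,
                            lines = region_line(10, 10, 30, 10))),
    "no line with an interior marker peak")
})

test_that("cluster averaging reduces noise and orients patterns left", {
  ps <- make_pattern_scene(seed = 23, poisson = TRUE, read_noise_sd = 2)
  seg <- segment_blobs(ps$marker)
  avg <- cluster_average_image(ps$marker, ps$set, seg, layout = ps$layout)
  expect_gt(avg$n_clusters, 5)
  expect_equal(max(avg$marker_avg), 1, tolerance = 0.05)
  # average of n noisy identical clusters approaches the noiseless crop
  ps0 <- make_pattern_scene(seed = 23)
  seg0 <- segment_blobs(ps0$marker)
  avg0 <- cluster_average_image(ps0$marker, ps0$set, seg0,
                                layout = ps0$layout)
  expect_equal(avg$intensity_avg, avg0$intensity_avg, tolerance = 0.02)
  # orientation contract: clusters sit on alternating sides of their
  # line, yet after mirroring the pattern dip is always on the left
  w <- ncol(avg$intensity_avg)
  left <- mean(avg$intensity_avg[, 1:(w %/% 2)])
  right <- mean(avg$intensity_avg[, (w %/% 2 + 2):w])
  expect_lt(left, right)
  # zero clusters is an error
  empty <- segment_blobs(matrix(0, 200, 200))
  expect_error(cluster_average_image(ps$marker, ps$set, empty), "no cluster")
})
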