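grid_rois <- function(dims, n = 10, size = 16)
  ndimg:::default_grid_rois(dims, n = n, size = size)

test_that("monomer-only bleach series gives a flat curve", {
  ser <- make_bleach_series(r_start = 0.23, r_mono = 0.23, dims = c(48, 48),
                            poisson = TRUE, read_noise_sd = 2, seed = 4)
  bc <- bleach_analysis(ser, regions = grid_rois(c(48, 48), n = 6, size = 12))
  # slope confidence interval contains zero
  expect_lt(abs(bc$slope), 2 * bc$slope_se + 1e-3)
  expect_lt(abs(bc$asymptote - 0.23), 0.01)
})

test_that("bleach extrapolation recovers the monomer anisotropy", {
  ser <- make_bleach_series(dims = c(48, 48))   # noiseless line 0.19 -> 0.23
  bc <- bleach_analysis(ser, regions = grid_rois(c(48, 48), n = 6, size = 12))
  expect_equal(bc$asymptote, 0.23, tolerance = 0.005)
  expect_equal(bc$intercept, 0.19, tolerance = 0.005)
  # frame-0 normalization: first-frame i_rel is exactly 1
  expect_true(all(bc$pairs$i_rel[bc$pairs$frame == 1] == 1))
})

test_that("asymptote estimator is unbiased over seeds", {
  est <- vapply(1:20, function(sd) {
    ser <- make_bleach_series(dims = c(48, 48), poisson = TRUE,
                              read_noise_sd = 2, seed = sd)
    bleach_analysis(ser,
                    regions = grid_rois(c(48, 48), n = 6, size = 12))$asymptote
  }, numeric(1))
  expect_lt(mean(abs(est - 0.23)), 0.01)
})

test_that("ROIs with non-positive initial intensity are dropped", {
  ser <- make_bleach_series(dims = c(32, 32))
  ser$ipa[1:8, 1:8, 1] <- 0
  ser$ipe[1:8, 1:8, 1] <- 0
  regs <- list(region_rect(1, 1, 8, 8), region_rect(16, 16, 8, 8))
  expect_message(bc <- bleach_analysis(ser, regions = regs), "dropped")
  expect_equal(max(bc$pairs$roi), 2)
  expect_false(1 %in% bc$pairs$roi)
})

test_that("cell segmentation matches the analytic disk area", {
  img <- disk_image(n = 128, radius = 50, value = 500)
  seg <- segment_cell(img, threshold = 100, pixel_size = 0.1)
  expect_equal(seg$area_um2, pi * 25, tolerance = 0.02)
  # two components: the smaller is discarded
  img2 <- img + disk_image(n = 128, radius = 5, value = 500, cx = 10, cy = 10)
  seg2 <- segment_cell(img2, threshold = 100, pixel_size = 0.1)
  expect_equal(sum(seg2$mask), sum(img > 100))
  expect_error(segment_cell(img, threshold = 1e6), "empty cell mask")
})

test_that("whole-cell anisotropy is invariant to edge erosion on uniform cells", {
  set <- make_polarized_scene(r_field = 0.2, intensity = 600,
                              dims = c(128, 128), poisson = TRUE,
                              read_noise_sd = 2, seed = 8)
  disk <- disk_image(n = 128, radius = 50)
  set$ipa[, , 1] <- set$ipa[, , 1] * disk
  set$ipe[, , 1] <- set$ipe[, , 1] * disk
  total <- set$ipa[, , 1] + 2 * set$ipe[, , 1]
  r_at <- function(er) {
    seg <- segment_cell(total, threshold = 100, edge_erosion_px = er)
    ndimg:::mask_anisotropy(set$ipa[, , 1], set$ipe[, , 1], seg$mask)$r
  }
  expect_lt(abs(r_at(0) - r_at(5)), 0.002)
  expect_lt(abs(r_at(0) - r_at(20)), 0.002)
})

test_that("static scenes give zero area and anisotropy change", {
  img <- disk_image(n = 64, radius = 20, value = 300)
  stack <- array(rep(img, 4), c(64, 64, 4))
  set <- polarized_image_set(stack, stack, frame_interval = 15,
                             pixel_size = 0.15)
  tr <- spreading_kinetics(set, threshold = 50)
  expect_true(all(tr$d_area[-1] == 0))
  expect_true(all(tr$d_r[-1] == 0))
})

test_that("spreading kinetics recover the generator's peak growth time", {
  for (sd in 1:3) {
    mv <- make_spreading_movie(seed = sd, poisson = TRUE, read_noise_sd = 2)
    tr <- spreading_kinetics(mv, threshold = 100)
    truth <- attr(mv, "truth")
    expect_lte(abs(peak_d_area_time(tr) - truth$t_mid), 15)
  }
})

test_that("anisotropy drop leads the area peak by the configured 150 s", {
  mv <- make_spreading_movie(seed = 5, poisson = TRUE, read_noise_sd = 2)
  tr <- spreading_kinetics(mv, threshold = 100)
  lag <- peak_d_area_time(tr) - anisotropy_drop_time(tr)
  expect_lte(abs(lag - 150), 15)      # within one frame
})

test_that("trace alignment is invariant to a global time shift", {
  mv <- make_spreading_movie()
  tr1 <- spreading_kinetics(mv, threshold = 100)
  tr2 <- tr1
  tr2$t_s <- tr2$t_s + 30            # same cell, started 30 s later
  al1 <- align_traces(list(tr1))
  al2 <- align_traces(list(tr1, tr2))
  shared <- intersect(al1$t_s, al2$t_s)
  expect_equal(al1$mean_r[match(shared, al1$t_s)],
               al2$mean_r[match(shared, al2$t_s)], tolerance = 1e-12)
  # single trace: no dispersion
  expect_true(all(is.na(al1$sem_r) | al1$sem_r == 0))
})

test_that("aligned traces put every area-change peak at t = 0", {
  trs <- lapply(1:3, function(sd) {
    mv <- make_spreading_movie(seed = sd, t_mid = 240 + 30 * sd,
                               poisson = TRUE)
    spreading_kinetics(mv, threshold = 100)
  })
  al <- align_traces(trs)
  da <- c(NA, diff(al$mean_area_um2))
  expect_equal(al$t_s[which.max(ifelse(is.finite(da), da, -Inf))], 0)
  expect_equal(length(attr(al, "peak_times")), 3)
})

test_that("kymograph stacks line profiles over time", {
  img <- disk_image(n = 64, radius = 20, value = 300)
  stack <- array(rep(img, 5), c(64, 64, 5))
  set <- polarized_image_set(stack, stack, frame_interval = 15)
  ky <- kymograph(set, line = region_line(5, 32, 60, 32))
  expect_equal(ncol(ky$intensity), 5)
  # static scene: every column identical
  expect_equal(ky$intensity[, 1], ky$intensity[, 5])
  expect_equal(ky$anisotropy[!is.na(ky$anisotropy)],
               rep(0, sum(!is.na(ky$anisotropy))))
})

test_that("kymograph tracks an advancing front at 1 px per frame", {
  nf <- 10
  ipa <- array(0, c(32, 64, nf))
  for (k in seq_len(nf)) ipa[, , k] <- 300 * (col(matrix(0, 32, 64)) <= 20 + k)
  set <- polarized_image_set(ipa, ipa, frame_interval = 1)
  ky <- kymograph(set, line = region_line(1, 16, 64, 16))
  fronts <- apply(ky$intensity, 2, function(v) max(which(v > 150)))
  expect_equal(diff(fronts), rep(1, nf - 1))
})

test_that("lines leaving the image are truncated with a warning", {
  img <- matrix(100, 32, 32)
  set <- polarized_image_set(img, img)
  expect_warning(ky <- kymograph(set, line = region_line(16, 16, 50, 16)),
                 "truncated")
  expect_lt(length(ky$position_px), 35)
})
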