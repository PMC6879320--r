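test_that("background subtraction removes offsets, clips negatives, is idempotent", {
  set <- polarized_image_set(matrix(110, 4, 4), matrix(110, 4, 4),
                             background_ipa = 10, background_ipe = 10)
  out <- subtract_background(set)
  expect_equal(out$ipa[, , 1], matrix(100, 4, 4))
  expect_equal(subtract_background(out)$ipa, out$ipa)  # background now 0

  # zero background leaves the stack untouched
  set0 <- polarized_image_set(matrix(7, 3, 3), matrix(5, 3, 3))
  expect_identical(subtract_background(set0)$ipa, set0$ipa)

  # pixel below background clips to zero
  ipa <- matrix(5, 2, 2)
  setc <- polarized_image_set(ipa, ipa, background_ipa = 10,
                              background_ipe = 10)
  expect_equal(subtract_background(setc)$ipa[, , 1], matrix(0, 2, 2))

  # background image of wrong shape is rejected
  expect_error(polarized_image_set(matrix(1, 4, 4), matrix(1, 4, 4),
                                   background_ipa = matrix(0, 3, 3)),
               "dimensions")
})

test_that("G-factor field is the pixelwise channel ratio with dark-pixel imputation", {
  img <- matrix(100, 8, 8)
  expect_equal(compute_gfactor(img, img)$g, matrix(1, 8, 8))
  expect_equal(compute_gfactor(matrix(120, 8, 8), img)$g,
               matrix(1.2, 8, 8))

  ipe <- matrix(100, 8, 8); ipe[3, 3] <- 0
  gf <- compute_gfactor(matrix(120, 8, 8), ipe)
  expect_equal(gf$g[3, 3], 1.2)          # imputed with the median g
  expect_true(gf$flagged[3, 3])
  expect_equal(sum(gf$flagged), 1)

  expect_error(compute_gfactor(img, matrix(0, 8, 8)), "dark floor")
  expect_error(gfactor_field(-1), "positive")
})

test_that("anisotropy formula: isotropic 0, fully polarized 1, hand value 0.25", {
  r_of <- function(ipa, ipe, g = 1) {
    set <- polarized_image_set(matrix(ipa, 2, 2), matrix(ipe, 2, 2))
    compute_anisotropy(set, gfactor_field(g))$r[1, 1]
  }
  expect_equal(r_of(100, 100), 0)
  expect_equal(r_of(100, 0), 1)
  expect_equal(r_of(300, 150), 150 / 600)
  # G-factor multiplies Ipe before the formula
  expect_equal(r_of(300, 125, g = 1.2), 150 / 600)
})

test_that("anisotropy respects physical bounds for any nonnegative inputs", {
  set.seed(11)
  for (i in 1:20) {
    ipa <- matrix(stats::runif(64, 0, 500), 8, 8)
    ipe <- matrix(stats::runif(64, 0, 500), 8, 8)
    g <- stats::runif(1, 0.5, 2)
    set <- polarized_image_set(ipa, ipe)
    r <- compute_anisotropy(set, gfactor_field(g))$r
    expect_true(all(r >= -0.5 & r <= 1, na.rm = TRUE))
  }
  # r = 1 iff corrected Ipe = 0; r = 0 iff Ipa = corrected Ipe
  set <- polarized_image_set(matrix(c(50, 80), 1, 2), matrix(c(0, 40), 1, 2))
  r <- compute_anisotropy(set, gfactor_field(2))$r
  expect_equal(r[1, 1], 1)
  expect_equal(r[1, 2], 0)
})

test_that("thresholding masks exactly the low-intensity pixels", {
  ipa <- matrix(c(300, 10), 1, 2); ipe <- matrix(c(150, 5), 1, 2)
  set <- polarized_image_set(ipa, ipe)
  am <- compute_anisotropy(set, threshold = 100)
  expect_equal(am$mask, matrix(c(TRUE, FALSE), 1, 2))
  expect_true(is.na(am$r[1, 2]))
  expect_false(is.na(am$r[1, 1]))
  expect_warning(compute_anisotropy(set, threshold = 1e9), "empty mask")
})

test_that("smoothing is cosmetic: ROI statistics read the unsmoothed field", {
  set.seed(5)
  set <- make_polarized_scene(
    r_field = matrix(stats::runif(32 * 32, 0.1, 0.3), 32, 32),
    intensity = 300)
  reg <- region_rect(4, 4, 10, 10)
  am1 <- compute_anisotropy(set, smoothing_window = 1)
  am5 <- compute_anisotropy(set, smoothing_window = 5)
  expect_identical(am1$r, am5$r)
  expect_false(identical(am5$r, am5$r_smooth))
  s1 <- roi_anisotropy(set, regions = list(reg))
  expect_equal(s1$mean_anisotropy,
               roi_anisotropy(set, regions = list(reg))$mean_anisotropy)
})

test_that("ROI anisotropy uses summed channel intensities", {
  mk <- function(pa, pe) {
    polarized_image_set(matrix(pa, 1, length(pa)),
                        matrix(pe, 1, length(pe)))
  }
  # uniform region: photon-weighted equals pixelwise
  s <- roi_anisotropy(mk(c(300, 300), c(150, 150)),
                      regions = region_rect(1, 1, 2, 1))
  expect_equal(s$mean_anisotropy, 0.25)
  # mixed region: summed-intensity rule, not the mean of pixel r
  s2 <- roi_anisotropy(mk(c(300, 100), c(150, 100)),
                       regions = region_rect(1, 1, 2, 1))
  expect_equal(s2$mean_anisotropy, (400 - 250) / (400 + 500))
  s2p <- roi_anisotropy(mk(c(300, 100), c(150, 100)),
                        regions = region_rect(1, 1, 2, 1),
                        method = "pixelmean")
  expect_equal(s2p$mean_anisotropy, mean(c(0.25, 0)))
  expect_equal(s2$total_intensity, 900)
  expect_equal(s2$n_pixels, 2)
})

test_that("photon-weighted and pixel-mean ROI anisotropy agree on uniform regions", {
  set <- uniform_set(r = 0.18, total = 420)
  reg <- region_rect(3, 3, 20, 20)
  a <- roi_anisotropy(set, regions = reg)$mean_anisotropy
  b <- roi_anisotropy(set, regions = reg,
                      method = "pixelmean")$mean_anisotropy
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(a, 0.18, tolerance = 1e-12)
})

test_that("out-of-bounds or empty regions are skipped, valid ones kept", {
  set <- uniform_set()
  regs <- list(region_rect(100, 100, 5, 5), region_rect(2, 2, 4, 4))
  expect_message(st <- roi_anisotropy(set, regions = regs), "skipped")
  expect_equal(nrow(st), 1)
})

test_that("intensity binning follows the edge conventions", {
  st <- data.frame(label = letters[1:4], mean_anisotropy = c(.1, .2, .3, .4),
                   sd_anisotropy = 0, total_intensity = c(10, 20, 30, 40),
                   n_pixels = 1)
  one <- bin_by_intensity(st, n_bins = 1)
  expect_equal(one$mean_anisotropy, 0.25)
  expect_equal(one$count, 4)

  two <- bin_by_intensity(st, edges = c(0, 25, 50))
  expect_equal(two$count, c(2, 2))
  expect_equal(two$mean_anisotropy, c(0.15, 0.35))

  # value on an interior right edge goes to the lower bin
  st25 <- st; st25$total_intensity[2] <- 25
  expect_equal(bin_by_intensity(st25, edges = c(0, 25, 50))$count, c(2, 2))

  # empty bin: count 0, mean NA
  gap <- bin_by_intensity(st, edges = c(0, 45, 100, 200))
  expect_equal(gap$count, c(4, 0, 0))
  expect_true(all(is.na(gap$mean_anisotropy[2:3])))

  # identical intensities fall into a single auto bin
  same <- st; same$total_intensity <- 30
  expect_equal(nrow(bin_by_intensity(same)), 1)
})
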