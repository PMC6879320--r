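#' Synthetic polarized-TIRF scene
#'
#' Forward model for a dual-channel polarized image: a known per-pixel
#' anisotropy field and total-intensity field are converted to ideal
#' channels by inverting the anisotropy formula
#' (`Ipa = I (1 + 2 r) / 3`, `Ipe = I (1 - r) / 3`), then the
#' perpendicular channel is divided by the G-factor (detection-sensitivity
#' imbalance), optionally misaligned, and both channels receive additive
#' background plus Poisson and Gaussian read noise. Running the analysis
#' pipeline on the output recovers the truth; in the noiseless, aligned,
#' `g = 1` case the round trip is exact to machine precision.
#'
#' The homoFRET photophysics is deliberately abstracted: nanoclusters are
#' represented by a depolarized anisotropy value rather than simulated
#' photon-by-photon, because every analysis in the package operates purely
#' on channel intensities.
#'
#' @param r_field matrix (or scalar) of true anisotropy values in
#'   (-0.5, 1).
#' @param intensity matrix (or scalar) of true total intensity
#'   `Ipa + 2 Ipe`.
#' @param gfactor true detection-ratio; the recorded `ipe` is the ideal
#'   perpendicular intensity divided by it.
#' @param misalignment optional [affine_transform()]; the recorded `ipe` is
#'   displaced so that applying exactly this transform re-aligns it.
#' @param background scalar background added to both channels (recorded in
#'   the set for [subtract_background()]).
#' @param poisson logical; apply Poisson photon noise.
#' @param read_noise_sd Gaussian read-noise SD in ADU (default 0).
#' @param seed optional integer seed (same seed, same scene, bit-identical).
#' @param dims image dimensions when `r_field` is scalar.
#' @param pixel_size,frame_interval forwarded to [polarized_image_set()].
#' @return A `PolarizedImageSet` whose `truth` attribute is a `SceneTruth`
#'   list recording every generating parameter.
#' @export
make_polarized_scene <- function(r_field, intensity = 300, gfactor = 1,
                                 misalignment = NULL, background = 0,
                                 poisson = FALSE, read_noise_sd = 0,
                                 seed = NULL, dims = c(64, 64),
                                 pixel_size = 0.0977, frame_interval = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.matrix(r_field)) r_field <- matrix(r_field, dims[1], dims[2])
  if (!is.matrix(intensity))
    intensity <- matrix(intensity, nrow(r_field), ncol(r_field))
  stopifnot(all(r_field > -0.5), all(r_field < 1))
  ch <- channels_from_r(r_field, intensity, gfactor)
  ipa <- ch$ipa; ipe <- ch$ipe
  if (!is.null(misalignment))
    ipe <- strip_attr(warp_affine(ipe, invert_transform(misalignment)))
  if (poisson) {
    ipa <- matrix(stats::rpois(length(ipa), pmax(ipa, 0)), nrow(ipa))
    ipe <- matrix(stats::rpois(length(ipe), pmax(ipe, 0)), nrow(ipe))
  }
  if (read_noise_sd > 0) {
    ipa <- ipa + matrix(stats::rnorm(length(ipa), 0, read_noise_sd), nrow(ipa))
    ipe <- ipe + matrix(stats::rnorm(length(ipe), 0, read_noise_sd), nrow(ipe))
  }
  set <- polarized_image_set(ipa + background, ipe + background,
                             pixel_size = pixel_size,
                             frame_interval = frame_interval,
                             background_ipa = background,
                             background_ipe = background)
  attr(set, "truth") <- scene_truth(
    r_field = r_field, intensity = intensity, gfactor = gfactor,
    misalignment = misalignment, background = background,
    poisson = poisson, read_noise_sd = read_noise_sd, seed = seed)
  set
}

# Ideal channel pair for a given anisotropy/intensity field; the recorded
# ipe is divided by the detection G-factor.
channels_from_r <- function(r, total, gfactor = 1) {
  list(ipa = total * (1 + 2 * r) / 3,
       ipe = total * (1 - r) / (3 * gfactor))
}

strip_attr <- function(m) { attr(m, "support") <- NULL; m }

#' @rdname make_polarized_scene
#' @param ... named ground-truth fields.
#' @export
scene_truth <- function(...) structure(list(...), class = "SceneTruth")

#' Synthetic photobleaching series
#'
#' Emulates a homoFRET photobleaching experiment on a mixed
#' monomer/nanocluster population: frame `k` carries relative intensity
#' `i_rel = beta^k` and anisotropy rising linearly toward the monomer
#' value as the sample bleaches,
#' `r(i_rel) = r_mono - (r_mono - r_start) * i_rel`. With `r_start =
#' r_mono` (no clusters) the series has constant anisotropy; with
#' `beta = 1` the intensity stays constant.
#'
#' @param n_frames number of frames (default 30).
#' @param r_start anisotropy of the unbleached mixture at `i_rel = 1`
#'   (default 0.19).
#' @param r_mono limiting monomer anisotropy reached at complete bleaching
#'   (default 0.23).
#' @param beta per-frame intensity retention factor (default 0.9).
#' @param intensity0 initial total intensity per pixel.
#' @param dims frame dimensions.
#' @inheritParams make_polarized_scene
#' @return A `PolarizedImageSet` stack with a `SceneTruth` attribute.
#' @export
make_bleach_series <- function(n_frames = 30, r_start = 0.19, r_mono = 0.23,
                               beta = 0.9, intensity0 = 600,
                               dims = c(64, 64), gfactor = 1,
                               poisson = FALSE, read_noise_sd = 0,
                               seed = NULL, pixel_size = 0.0977,
                               frame_interval = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  ipa <- array(0, c(dims, n_frames)); ipe <- array(0, c(dims, n_frames))
  i_rel <- beta^(seq_len(n_frames) - 1)
  r_true <- r_mono - (r_mono - r_start) * i_rel
  for (k in seq_len(n_frames)) {
    ch <- channels_from_r(matrix(r_true[k], dims[1], dims[2]),
                          matrix(intensity0 * i_rel[k], dims[1], dims[2]),
                          gfactor)
    a <- ch$ipa; e <- ch$ipe
    if (poisson) {
      a <- matrix(stats::rpois(length(a), a), dims[1])
      e <- matrix(stats::rpois(length(e), e), dims[1])
    }
    if (read_noise_sd > 0) {
      a <- a + matrix(stats::rnorm(length(a), 0, read_noise_sd), dims[1])
      e <- e + matrix(stats::rnorm(length(e), 0, read_noise_sd), dims[1])
    }
    ipa[, , k] <- a; ipe[, , k] <- e
  }
  set <- polarized_image_set(ipa, ipe, pixel_size = pixel_size,
                             frame_interval = frame_interval)
  attr(set, "truth") <- scene_truth(
    r_start = r_start, r_mono = r_mono, beta = beta, i_rel = i_rel,
    r_true = r_true, gfactor = gfactor, seed = seed)
  set
}

#' Synthetic FCS autocorrelation curve and blinking trace
#'
#' `make_fcs_curve()` evaluates the triplet + two-component diffusion
#' model on a log-spaced lag grid and adds multiplicative Gaussian noise.
#' `make_blinking_trace()` simulates a two-state (on/off) telegraph
#' emitter with Poisson photon counting; its normalized autocorrelation
#' has the closed form `G(tau) = (k_off / k_on) * exp(-(k_on + k_off)
#' tau)`, which serves as an independent oracle for the correlator.
#'
#' @param params an [fcs_params()] list.
#' @param noise_sd multiplicative noise SD (0.01 = 1 percent).
#' @param lags lag grid in seconds; defaults to 128 log-spaced lags
#'   spanning 5e-6 to 2 s, the fitted range.
#' @param seed optional integer seed.
#' @return `make_fcs_curve()`: an `ACFCurve` (see [autocorrelate()]) with a
#'   `SceneTruth` attribute.
#' @export
make_fcs_curve <- function(params, noise_sd = 0.01,
                           lags = 10^seq(log10(5e-6), log10(2),
                                         length.out = 128),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g0 <- fcs_model(params, lags)
  g <- g0 * (1 + stats::rnorm(length(lags), 0, noise_sd))
  curve <- acf_curve(lags, g)
  attr(curve, "truth") <- scene_truth(params = params, noise_sd = noise_sd,
                                      seed = seed)
  curve
}

#' @rdname make_fcs_curve
#' @param k_on,k_off off-to-on and on-to-off switching rates (1/s).
#' @param rate_on mean photon rate in the on state (counts/s).
#' @param dwell sampling bin width (s).
#' @param duration trace length (s).
#' @return `make_blinking_trace()`: an [intensity_trace()] with a
#'   `SceneTruth` attribute recording the closed-form correlation time
#'   `1 / (k_on + k_off)` and amplitude `k_off / k_on`.
#' @export
make_blinking_trace <- function(k_on = 50, k_off = 50, rate_on = 5e4,
                                dwell = 1e-4, duration = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration / dwell)
  # alternating exponential sojourns, then the state of each dwell bin
  t_tot <- 0; times <- numeric(0)
  state0 <- stats::runif(1) < k_on / (k_on + k_off)  # stationary start
  s <- state0
  while (t_tot < duration) {
    t_tot <- t_tot + stats::rexp(1, if (s) k_off else k_on)
    times <- c(times, t_tot)
    s <- !s
  }
  bin_t <- (seq_len(n) - 0.5) * dwell
  n_switch <- findInterval(bin_t, times)
  on <- if (state0) n_switch %% 2 == 0 else n_switch %% 2 == 1
  counts <- stats::rpois(n, rate_on * dwell * on)
  tr <- intensity_trace(counts, dwell)
  attr(tr, "truth") <- scene_truth(
    k_on = k_on, k_off = k_off, rate_on = rate_on,
    tau_corr = 1 / (k_on + k_off), amplitude = k_off / k_on, seed = seed)
  tr
}

#' Synthetic two-channel Laurdan scene
#'
#' Inverts the generalized-polarization formula: for a known GP field and
#' total intensity, `ICh1 = I (1 + gp) / 2` and
#' `ICh2 = I (1 - gp) / (2 G)`, so that [compute_gp()] with the same
#' G-factor recovers the field exactly in the noiseless case.
#'
#' @param gp_field matrix (or scalar) of true GP values in (-1, 1).
#' @param intensity matrix (or scalar) total intensity `ICh1 + G ICh2`.
#' @param gfactor true channel G-factor.
#' @inheritParams make_polarized_scene
#' @return list with `ch1`, `ch2` image matrices and `truth`.
#' @export
make_gp_scene <- function(gp_field, intensity = 400, gfactor = 1,
                          poisson = FALSE, read_noise_sd = 0, seed = NULL,
                          dims = c(64, 64)) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.matrix(gp_field)) gp_field <- matrix(gp_field, dims[1], dims[2])
  if (!is.matrix(intensity))
    intensity <- matrix(intensity, nrow(gp_field), ncol(gp_field))
  ch1 <- intensity * (1 + gp_field) / 2
  ch2 <- intensity * (1 - gp_field) / (2 * gfactor)
  if (poisson) {
    ch1 <- matrix(stats::rpois(length(ch1), ch1), nrow(ch1))
    ch2 <- matrix(stats::rpois(length(ch2), ch2), nrow(ch2))
  }
  if (read_noise_sd > 0) {
    ch1 <- ch1 + matrix(stats::rnorm(length(ch1), 0, read_noise_sd), nrow(ch1))
    ch2 <- ch2 + matrix(stats::rnorm(length(ch2), 0, read_noise_sd), nrow(ch2))
  }
  list(ch1 = ch1, ch2 = ch2,
       truth = scene_truth(gp_field = gp_field, intensity = intensity,
                           gfactor = gfactor, seed = seed))
}

#' Synthetic nanopattern scene with marker clusters
#'
#' Emulates a cell on an RGD-functionalized bilayer assembled over
#' chromium line patterns: the GPI total-intensity image dips along the
#' (vertical) pattern lines, bright marker (vinculin-like) clusters sit
#' adjacent to the lines, and the anisotropy field is lowered by
#' `r_contrast` within `contrast_radius_um` of each cluster (nanoclusters
#' form near immobilized ligand).
#'
#' @param dims image dimensions (default 200 x 200).
#' @param spacing_px pattern line spacing in pixels (default 20,
#'   i.e. ~2 um at the default pixel size).
#' @param dip_depth fractional intensity dip at the lines (0-1).
#' @param dip_sigma_px Gaussian half-width of the dip.
#' @param clusters_per_line marker clusters per pattern line.
#' @param cluster_offset_px cluster-centre distance from its line (px).
#' @param cluster_sigma_px marker spot Gaussian sigma (px).
#' @param r_out baseline anisotropy away from clusters.
#' @param r_contrast anisotropy reduction near clusters (default 0.05).
#' @param contrast_radius_um radius of the lowered-anisotropy zone
#'   (default 0.5 um on either side of a cluster).
#' @inheritParams make_polarized_scene
#' @return list with `marker` image, polarized `set`, `layout`
#'   (a `PatternLayout`), and `truth`.
#' @export
make_pattern_scene <- function(dims = c(200, 200), spacing_px = 20,
                               dip_depth = 0.5, dip_sigma_px = 1.5,
                               clusters_per_line = 3,
                               cluster_offset_px = 3, cluster_sigma_px = 2,
                               r_out = 0.22, r_contrast = 0.05,
                               contrast_radius_um = 0.5, intensity = 600,
                               gfactor = 1, poisson = FALSE,
                               read_noise_sd = 0, seed = NULL,
                               pixel_size = 0.0977) {
  if (!is.null(seed)) set.seed(seed)
  ny <- dims[1]; nx <- dims[2]
  line_x <- seq(spacing_px, nx - spacing_px / 2, by = spacing_px)
  xg <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  yg <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  dip <- matrix(0, ny, nx)
  for (lx in line_x)
    dip <- dip + exp(-(xg - lx)^2 / (2 * dip_sigma_px^2))
  total <- intensity * (1 - dip_depth * pmin(dip, 1))
  # marker clusters flanking the lines (alternating sides)
  centers <- do.call(rbind, lapply(seq_along(line_x), function(i) {
    side <- rep_len(c(1, -1), clusters_per_line) *
      if (i %% 2 == 0) -1 else 1
    cy <- round(seq(0.2, 0.8, length.out = clusters_per_line) * ny)
    cbind(x = line_x[i] + side * cluster_offset_px, y = cy,
          line = line_x[i])
  }))
  marker <- matrix(0, ny, nx)
  r_field <- matrix(r_out, ny, nx)
  rad_px <- contrast_radius_um / pixel_size
  for (j in seq_len(nrow(centers))) {
    d2 <- (xg - centers[j, "x"])^2 + (yg - centers[j, "y"])^2
    marker <- marker + 1000 * exp(-d2 / (2 * cluster_sigma_px^2))
    r_field[d2 <= rad_px^2] <- r_out - r_contrast
  }
  set <- make_polarized_scene(r_field, total, gfactor = gfactor,
                              poisson = poisson,
                              read_noise_sd = read_noise_sd,
                              pixel_size = pixel_size)
  if (poisson)
    marker <- matrix(stats::rpois(length(marker), marker), ny, nx)
  layout <- pattern_layout(line_x = line_x, orientation = "vertical",
                           spacing_um = spacing_px * pixel_size)
  list(marker = marker, set = set, layout = layout,
       truth = scene_truth(centers = centers, r_out = r_out,
                           r_contrast = r_contrast,
                           contrast_radius_um = contrast_radius_um,
                           layout = layout, seed = seed))
}

#' Synthetic cell-spreading movie
#'
#' A circular cell whose area follows a logistic (sigmoidal) growth curve
#' — maximal area change at `t_mid`, emulating the P1 rapid-expansion
#' phase — while its whole-cell anisotropy drops sigmoidally beginning
#' `drop_lead` seconds *before* the area-change peak (default 150 s, the
#' nanocluster-formation lead observed during integrin-driven spreading).
#'
#' @param n_frames number of frames.
#' @param frame_interval frame interval in seconds (default 15).
#' @param t_mid time of maximal area growth (s).
#' @param growth_tau logistic time constant of area growth (s).
#' @param area0,area_max initial and plateau cell areas (um^2).
#' @param r_hi,r_drop baseline anisotropy and total drop amplitude.
#' @param drop_lead lead of the anisotropy-drop midpoint before `t_mid`
#'   (s, default 150).
#' @param drop_tau logistic time constant of the anisotropy drop (s).
#' @inheritParams make_polarized_scene
#' @return A `PolarizedImageSet` movie with a `SceneTruth` attribute.
#' @export
make_spreading_movie <- function(n_frames = 40, frame_interval = 15,
                                 t_mid = 300, growth_tau = 45,
                                 area0 = 20, area_max = 180,
                                 r_hi = 0.22, r_drop = 0.04,
                                 drop_lead = 150, drop_tau = 30,
                                 dims = c(128, 128), intensity = 600,
                                 gfactor = 1, poisson = FALSE,
                                 read_noise_sd = 0, seed = NULL,
                                 pixel_size = 0.15) {
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n_frames) - 1) * frame_interval
  area <- area0 + (area_max - area0) * stats::plogis((t - t_mid) / growth_tau)
  r_t <- r_hi - r_drop * stats::plogis((t - (t_mid - drop_lead)) / drop_tau)
  radius_px <- sqrt(area / pi) / pixel_size
  ny <- dims[1]; nx <- dims[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xg <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  yg <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  d2 <- (xg - cx)^2 + (yg - cy)^2
  ipa <- array(0, c(ny, nx, n_frames)); ipe <- array(0, c(ny, nx, n_frames))
  for (k in seq_len(n_frames)) {
    inside <- d2 <= radius_px[k]^2
    tot <- matrix(0, ny, nx); tot[inside] <- intensity
    ch <- channels_from_r(matrix(r_t[k], ny, nx), tot, gfactor)
    a <- ch$ipa; e <- ch$ipe
    if (poisson) {
      a <- matrix(stats::rpois(length(a), a), ny)
      e <- matrix(stats::rpois(length(e), e), ny)
    }
    if (read_noise_sd > 0) {
      a <- a + matrix(stats::rnorm(length(a), 0, read_noise_sd), ny)
      e <- e + matrix(stats::rnorm(length(e), 0, read_noise_sd), ny)
    }
    ipa[, , k] <- a; ipe[, , k] <- e
  }
  set <- polarized_image_set(ipa, ipe, pixel_size = pixel_size,
                             frame_interval = frame_interval)
  attr(set, "truth") <- scene_truth(
    t = t, area = area, r_t = r_t, t_mid = t_mid, drop_lead = drop_lead,
    r_hi = r_hi, r_drop = r_drop, seed = seed)
  set
}
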