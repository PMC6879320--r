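#' FCS data containers
#'
#' `intensity_trace()` holds a photon-count (or intensity) time series
#' sampled at a fixed dwell time; `acf_curve()` holds a lag-domain
#' autocorrelation curve `G(tau)`.
#'
#' @param counts numeric vector of counts/intensity per dwell bin.
#' @param dwell dwell time per sample in seconds (> 0).
#' @return An `IntensityTrace`.
#' @export
intensity_trace <- function(counts, dwell) {
  stopifnot(length(counts) >= 2, dwell > 0)
  structure(list(counts = as.numeric(counts), dwell = dwell,
                 duration = length(counts) * dwell),
            class = "IntensityTrace")
}

#' @rdname intensity_trace
#' @param lags strictly increasing positive lag times (s).
#' @param g correlation values `G(tau)`.
#' @param g_sd optional per-lag SD (e.g. over repeats), used as fit
#'   weights.
#' @export
acf_curve <- function(lags, g, g_sd = NULL) {
  stopifnot(length(lags) == length(g), all(lags > 0), !is.unsorted(lags),
            all(is.finite(g)))
  structure(list(lags = as.numeric(lags), g = as.numeric(g), g_sd = g_sd),
            class = "ACFCurve")
}

#' Multi-tau autocorrelation of an intensity trace
#'
#' Computes the normalized fluctuation autocorrelation
#' `G(tau) = <dI(t) dI(t + tau)> / <I>^2` with `dI = I - <I>`, on a
#' multi-tau (quasi-logarithmic) lag grid: `m` linear lags at the base
#' dwell, then `m/2` lags per octave with the trace coarsened by a factor
#' of 2 between octaves — the scheme hardware correlators use to span
#' microseconds to seconds. Lags extend to one tenth of the trace
#' duration.
#'
#' @param trace an [intensity_trace()].
#' @param m lags per octave at the base level (default 16).
#' @return An `ACFCurve`; if the trace has zero variance, all-zero values
#'   with attribute `flat = TRUE`.
#' @export
autocorrelate <- function(trace, m = 16) {
  stopifnot(inherits(trace, "IntensityTrace"))
  x <- trace$counts
  mu <- mean(x)
  if (mu <= 0) stop("mean intensity must be positive")
  if (stats::var(x) == 0) {
    lag <- trace$dwell * seq_len(m)
    out <- acf_curve(lag, rep(0, m))
    attr(out, "flat") <- TRUE
    return(out)
  }
  max_lag_s <- trace$duration / 10
  lags <- numeric(0); vals <- numeric(0)
  dt <- trace$dwell
  level <- 0L
  repeat {
    ks <- if (level == 0L) seq_len(m) else seq.int(m / 2 + 1, m)
    ks <- ks[ks * dt <= max_lag_s & ks < length(x)]
    if (!length(ks)) break
    mx <- mean(x)
    for (k in ks) {
      n <- length(x) - k
      lags <- c(lags, k * dt)
      vals <- c(vals, mean((x[1:n] - mx) * (x[(k + 1):(n + k)] - mx)) / mx^2)
    }
    # coarsen by 2 for the next octave
    nn <- floor(length(x) / 2)
    if (nn < m) break
    x <- (x[seq(1, 2 * nn, by = 2)] + x[seq(2, 2 * nn, by = 2)]) / 2
    dt <- dt * 2
    level <- level + 1L
    if (dt * (m / 2 + 1) > max_lag_s) break
  }
  acf_curve(lags, vals)
}

#' FCS model parameters
#'
#' Parameter set of the triplet + two-component diffusion model: `n` mean
#' particles in the confocal volume, dark-state (triplet/blinking)
#' fraction `T` and lifetime `tau_t`, fast-component fraction `f` with 3-D
#' diffusion time `tau_d1` (the free/unbound pool), slow 2-D diffusion
#' time `tau_d2` (the actin-bound pool), and structure factor `s` — the
#' axial-to-lateral detection-volume ratio entering the 3-D term, fixed at
#' 0.2 by default (free fits converge to about this value).
#'
#' @param n mean particle number (> 0).
#' @param t_dark dark-state fraction in [0, 1).
#' @param tau_t dark-state lifetime (s).
#' @param f fast-component fraction in [0, 1].
#' @param tau_d1 fast diffusion time (s); convention `tau_d1 < tau_d2`.
#' @param tau_d2 slow diffusion time (s).
#' @param s structure factor (> 0, default 0.2).
#' @return An `FCSParams` list.
#' @export
fcs_params <- function(n = 2, t_dark = 0.15, tau_t = 50e-6, f = 0.7,
                       tau_d1 = 1e-3, tau_d2 = 50e-3, s = 0.2) {
  p <- list(n = n, t_dark = t_dark, tau_t = tau_t, f = f,
            tau_d1 = tau_d1, tau_d2 = tau_d2, s = s)
  validate_fcs_params(p)
  structure(p, class = "FCSParams")
}

validate_fcs_params <- function(p) {
  stopifnot(p$n > 0, p$t_dark >= 0, p$t_dark < 1, p$tau_t > 0,
            p$f >= 0, p$f <= 1, p$tau_d1 > 0, p$tau_d2 > 0, p$s > 0)
  invisible(p)
}

#' Evaluate the triplet + two-component FCS model
#'
#' `G(tau) = (1/N) G_T(tau) G_D(tau)` with
#' `G_T = 1 + (T / (1 - T)) exp(-tau / tau_t)` and
#' `G_D = f (1 + tau/tau_d1)^-1 (1 + tau/(s^2 tau_d1))^-1/2 +
#' (1 - f) (1 + tau/tau_d2)^-1`:
#' a 3-D free-diffusion component for the unbound pool and a 2-D membrane
#' component for the filament-bound pool.
#'
#' @param params an [fcs_params()] set.
#' @param lags lag times (s).
#' @return Model values `G(tau)`.
#' @export
fcs_model <- function(params, lags) {
  p <- validate_fcs_params(params)
  gt <- 1 + (p$t_dark / (1 - p$t_dark)) * exp(-lags / p$tau_t)
  gd <- p$f / ((1 + lags / p$tau_d1) * sqrt(1 + lags / (p$s^2 * p$tau_d1))) +
    (1 - p$f) / (1 + lags / p$tau_d2)
  gt * gd / p$n
}

#' Quality control of an FCS intensity trace
#'
#' Flags traces unusable for correlation analysis: significant linear
#' drift of the mean intensity (`|slope| * duration > drift_frac * <I>`)
#' or sporadic bright bursts (any rolling-window mean exceeding
#' `<I> + k_sd * SD` of the window means).
#'
#' @param trace an [intensity_trace()].
#' @param drift_frac maximal tolerated fractional drift over the trace
#'   (default 0.1).
#' @param k_sd burst threshold in SD units (default 5).
#' @param window rolling-window length in seconds (default 0.1).
#' @return list with `pass` (logical) and `reasons` (character vector,
#'   subset of `"drift"`, `"burst"`).
#' @export
qc_trace <- function(trace, drift_frac = 0.1, k_sd = 5, window = 0.1) {
  stopifnot(inherits(trace, "IntensityTrace"))
  x <- trace$counts
  t <- (seq_along(x) - 0.5) * trace$dwell
  mu <- mean(x)
  reasons <- character(0)
  slope <- stats::coef(stats::lm.fit(cbind(1, t), x))[2]
  if (abs(slope) * trace$duration > drift_frac * mu)
    reasons <- c(reasons, "drift")
  w <- max(2L, round(window / trace$dwell))
  roll <- stats::filter(x, rep(1 / w, w), sides = 1)
  roll <- roll[!is.na(roll)]
  if (any(roll > mean(roll) + k_sd * stats::sd(roll)))
    reasons <- c(reasons, "burst")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Fit the FCS model to an autocorrelation curve
#'
#' Weighted least squares of [fcs_model()] against a measured curve using
#' Levenberg-Marquardt with box constraints. The structure factor is fixed
#' at its default (0.2) unless listed in `free`; after fitting, the
#' component ordering convention `tau_d1 < tau_d2` is enforced by swapping
#' the components (and `f -> 1 - f`) if needed. Weights are `1/sd` when
#' per-lag SDs exist, else uniform.
#'
#' @param curve an [acf_curve()] (lags within `lag_range` are fitted).
#' @param free character vector of free parameter names (default: all but
#'   `s`).
#' @param init an [fcs_params()] with starting values, or `NULL` for
#'   automatic initialization (`n` from `1/G` at the first lag, `tau_t`
#'   50 us, component times from their allowed windows).
#' @param lower,upper named numeric vectors overriding the default box
#'   constraints. Defaults confine `tau_d1` to 0.3-3 ms (free pool) and
#'   `tau_d2` to 10-200 ms (bound pool), the component timescale windows.
#' @param lag_range fitted lag window in seconds (default `c(5e-6, 2)`).
#' @param multi_start also start from a small deterministic grid over the
#'   fast-component window and keep the lowest-RSS solution (default
#'   `TRUE`); guards against stalls at a parameter bound.
#' @return An `FCSFit`: list with `params` (`FCSParams`), `se` (named
#'   standard errors, `NA` for fixed), `rss`, `free`, `converged`, and the
#'   fitted curve (`lags`, `fitted`).
#' @export
fit_acf <- function(curve, free = c("n", "t_dark", "tau_t", "f",
                                    "tau_d1", "tau_d2"),
                    init = NULL, lower = NULL, upper = NULL,
                    lag_range = c(5e-6, 2), multi_start = TRUE) {
  stopifnot(inherits(curve, "ACFCurve"))
  keep <- curve$lags >= lag_range[1] & curve$lags <= lag_range[2]
  lags <- curve$lags[keep]; g <- curve$g[keep]
  wt <- if (!is.null(curve$g_sd)) 1 / pmax(curve$g_sd[keep], 1e-12)
        else rep(1, length(g))
  all_names <- c("n", "t_dark", "tau_t", "f", "tau_d1", "tau_d2", "s")
  free <- intersect(all_names, free)
  if (length(lags) < length(free) + 2)
    stop("not enough lag points for the number of free parameters")
  lo <- c(n = 1e-3, t_dark = 0, tau_t = 1e-6, f = 0, tau_d1 = 3e-4,
          tau_d2 = 1e-2, s = 0.05)
  hi <- c(n = 1e6, t_dark = 0.99, tau_t = 1e-2, f = 1, tau_d1 = 3e-3,
          tau_d2 = 0.2, s = 5)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (is.null(init)) {
    n0 <- 1 / max(g[1], 1e-6)
    init <- fcs_params(n = min(max(n0, lo["n"]), hi["n"]),
                       t_dark = 0.1, tau_t = 50e-6, f = 0.5,
                       tau_d1 = sqrt(lo["tau_d1"] * hi["tau_d1"]),
                       tau_d2 = sqrt(lo["tau_d2"] * hi["tau_d2"]))
  }
  p_full <- unlist(init[all_names])
  names(p_full) <- all_names
  eps <- 1e-9
  p_full <- pmin(pmax(p_full, lo + eps), hi - eps)
  # fit on log (positive parameters) / logit (fractions) scales so the
  # optimizer sees comparably scaled, unconstrained-looking coordinates
  frac <- c("t_dark", "f")
  to_theta <- function(p) {
    out <- ifelse(names(p) %in% frac,
                  stats::qlogis(pmin(pmax(p, 1e-9), 1 - 1e-9)), log(p))
    stats::setNames(out, names(p))
  }
  from_theta <- function(th) {
    out <- ifelse(names(th) %in% frac, stats::plogis(th), exp(th))
    stats::setNames(out, names(th))
  }
  theta_full <- to_theta(p_full)
  th_lo <- to_theta(pmax(lo, 1e-12)); th_hi <- to_theta(pmin(hi, 1 - 1e-12))
  th_lo[!(all_names %in% frac)] <- log(pmax(lo[!(all_names %in% frac)], 1e-12))
  th_hi[!(all_names %in% frac)] <- log(hi[!(all_names %in% frac)])
  resid_fn <- function(thf) {
    th <- theta_full; th[free] <- thf
    wt * (fcs_model(as_fcs_params(from_theta(th)), lags) - g)
  }
  run_lm <- function(start_theta) {
    minpack.lm::nls.lm(
      par = start_theta, lower = th_lo[free], upper = th_hi[free],
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                           ptol = 1e-14))
  }
  # Levenberg-Marquardt can stall at a box bound from an unlucky start;
  # a small deterministic multi-start over the component windows fixes it
  starts <- list(theta_full[free])
  if (multi_start) {
    grid <- expand.grid(
      tau_d1 = exp(log(lo["tau_d1"]) + c(0.25, 0.75) *
                     (log(hi["tau_d1"]) - log(lo["tau_d1"]))),
      f = c(0.4, 0.8))
    for (i in seq_len(nrow(grid))) {
      p_i <- p_full
      p_i["tau_d1"] <- grid$tau_d1[i]
      p_i["f"] <- grid$f[i]
      starts[[length(starts) + 1]] <- to_theta(p_i)[free]
    }
  }
  fit <- NULL
  for (st in starts) {
    cand <- tryCatch(run_lm(st), error = function(e) NULL)
    if (!is.null(cand) && (is.null(fit) || cand$deviance < fit$deviance))
      fit <- cand
  }
  if (is.null(fit)) stop("Levenberg-Marquardt failed from every start")
  converged <- fit$info %in% 1:4
  theta_full[free] <- fit$par
  p_full <- from_theta(theta_full)
  se <- rep(NA_real_, length(all_names)); names(se) <- all_names
  # delta method back to the natural scale
  se_theta <- tryCatch(sqrt(diag(solve(fit$hessian)) * fit$deviance /
                              max(1, length(g) - length(free))),
                       error = function(e) rep(NA_real_, length(free)))
  jac <- ifelse(free %in% frac,
                p_full[free] * (1 - p_full[free]), p_full[free])
  se[free] <- se_theta * jac
  # ordering convention: tau_d1 is the fast component
  if (p_full["tau_d1"] > p_full["tau_d2"]) {
    p_full[c("tau_d1", "tau_d2")] <- p_full[c("tau_d2", "tau_d1")]
    se[c("tau_d1", "tau_d2")] <- se[c("tau_d2", "tau_d1")]
    p_full["f"] <- 1 - p_full["f"]
  }
  params <- as_fcs_params(p_full)
  structure(list(params = params, se = se, rss = fit$deviance,
                 free = free, converged = converged, lags = lags,
                 fitted = fcs_model(params, lags)),
            class = "FCSFit")
}

as_fcs_params <- function(v) {
  fcs_params(n = v[["n"]], t_dark = v[["t_dark"]], tau_t = v[["tau_t"]],
             f = v[["f"]], tau_d1 = v[["tau_d1"]], tau_d2 = v[["tau_d2"]],
             s = v[["s"]])
}

#' @export
print.FCSFit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "FCSFit (%s): N = %.3g, T = %.3f, tauT = %.3g s, f = %.3f,\n  tauD1 = %.3g s, tauD2 = %.3g s, S = %.3f, RSS = %.3g\n",
    if (x$converged) "converged" else "NOT converged",
    p$n, p$t_dark, p$tau_t, p$f, p$tau_d1, p$tau_d2, p$s, x$rss))
  invisible(x)
}
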