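#' Despike and smooth a corrected-OD series
#'
#' Micro-volume yeast cultures aggregate and sediment in wells, producing
#' isolated spikes in OD readings. Smoothing is a running-median despike
#' followed by a centered moving average; both window widths are odd and
#' endpoints use shrunken symmetric windows so output length equals input
#' length. A window of 1 disables the corresponding filter.
#'
#' @param od Numeric corrected-OD series.
#' @param despike_window Odd integer width of the running median (default 5).
#' @param avg_window Odd integer width of the moving average (default 3).
#' @return Smoothed series of the same length.
#' @export
smooth_series <- function(od, despike_window = 5, avg_window = 3) {
  n <- length(od)
  for (w in c(despike_window, avg_window)) {
    if (w < 1 || w %% 2 == 0) stop("windows must be odd integers >= 1")
    if (w > n) stop("window larger than series length")
  }
  out <- od
  if (despike_window > 1) {
    out <- as.numeric(stats::runmed(out, despike_window, endrule = "median"))
  }
  if (avg_window > 1) {
    h <- (avg_window - 1) / 2
    out <- vapply(seq_len(n), function(i) {
      hh <- min(h, i - 1, n - i)  # shrink symmetrically at the edges
      mean(out[(i - hh):(i + hh)])
    }, numeric(1))
  }
  out
}

#' Log-ratio transform of a corrected-OD series
#'
#' Builds the growth curve `L(t) = ln(od_corr(t) / od_init)` where `od_init`
#' is the mean of the first `init_cycles` corrected readings (averaging
#' suppresses first-cycle noise). Both `od_init` and every reading are
#' clamped below at `od_floor` before division so the log is always finite.
#'
#' @param od Corrected-OD series (post blank correction, calibration and
#'   smoothing).
#' @param times Reading times in minutes.
#' @param init_cycles Number of initial readings averaged into `od_init`
#'   (default 3).
#' @param od_floor Lower clamp for OD values (default 1e-4).
#' @return A `growth_curve` object with elements `times`, `od_corr`,
#'   `od_init`, `log_ratio` and `flags`.
#' @export
log_transform <- function(od, times, init_cycles = 3, od_floor = 1e-4) {
  n <- length(od)
  if (length(times) != n) stop("od and times must have equal length")
  if (init_cycles < 1 || init_cycles > n) {
    stop("init_cycles must be in [1, length(od)]")
  }
  flags <- character()
  od_cl <- pmax(od, od_floor)
  od_init <- max(mean(od[seq_len(init_cycles)]), od_floor)
  if (all(od <= od_floor)) flags <- c(flags, "degenerate_curve")
  structure(list(times = as.numeric(times), od_corr = od_cl,
                 od_init = od_init, log_ratio = log(od_cl / od_init),
                 flags = flags),
            class = "growth_curve")
}

# OLS slopes of L(t) in sliding windows; returns window-center times and
# slopes (length n - window + 1)
sliding_slopes <- function(times, lr, window) {
  n <- length(times)
  if (window %% 2 == 0 || window < 3) stop("slope window must be odd, >= 3")
  if (n < window) stop("curve shorter than the slope window")
  h <- (window - 1) / 2
  centers <- (h + 1):(n - h)
  slopes <- vapply(centers, function(i) {
    idx <- (i - h):(i + h)
    tt <- times[idx]; yy <- lr[idx]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  list(t = times[centers], slope = slopes, center_idx = centers)
}

#' Extract growth traits from a log-ratio curve
#'
#' Nonparametric extraction of the three derived growth traits: the maximum
#' specific growth rate `mu` is the largest sliding-window OLS slope of
#' `L(t)`; the lag `lambda` is where the tangent through the point of
#' maximal slope crosses `L = 0`; the carrying capacity `kappa` is the
#' maximal corrected OD.
#'
#' @param curve A `growth_curve`.
#' @param slope_window Odd window (points) for the sliding OLS slope
#'   (default 5, i.e. 50 min at 10-min cycles).
#' @return A list with `lambda` (min), `mu` (per min), `kappa` (OD),
#'   `t_mu` (min, window center achieving `mu`; earliest on ties).
#' @export
estimate_traits <- function(curve, slope_window = 5) {
  sl <- sliding_slopes(curve$times, curve$log_ratio, slope_window)
  i <- which.max(sl$slope)  # which.max takes the earliest maximum
  mu <- max(sl$slope[i], 0)
  t_mu <- sl$t[i]
  L_mu <- curve$log_ratio[sl$center_idx[i]]
  lambda <- if (mu > 0) max(0, t_mu - L_mu / mu) else 0
  list(lambda = lambda, mu = mu, kappa = max(curve$od_corr), t_mu = t_mu)
}

#' Average replicate growth curves
#'
#' @param curves List of `growth_curve` objects on an identical time grid.
#' @return List with `mean` (a `growth_curve` of pointwise means) and `sem`
#'   (per-time standard error of the log-ratio; 0 when n = 1).
#' @export
aggregate_replicates <- function(curves) {
  if (!length(curves)) stop("need at least one curve")
  t0 <- curves[[1]]$times
  for (cv in curves) {
    if (length(cv$times) != length(t0) || any(cv$times != t0)) {
      stop("replicate curves are not on a shared time grid")
    }
  }
  L <- vapply(curves, function(cv) cv$log_ratio, numeric(length(t0)))
  OD <- vapply(curves, function(cv) cv$od_corr, numeric(length(t0)))
  L <- matrix(L, nrow = length(t0)); OD <- matrix(OD, nrow = length(t0))
  n <- ncol(L)
  sem <- if (n > 1) apply(L, 1, stats::sd) / sqrt(n) else rep(0, length(t0))
  mean_curve <- structure(
    list(times = t0, od_corr = rowMeans(OD),
         od_init = mean(vapply(curves, function(cv) cv$od_init, 0)),
         log_ratio = rowMeans(L), flags = character()),
    class = "growth_curve")
  list(mean = mean_curve, sem = sem, n = n)
}

#' Locate the dynamic measuring point Phi
#'
#' Phi is the time at which the reference culture's population growth rate
#' (sliding-window slope of `L(t)`) first drops below a fraction (default
#' 5%) of its maximum, scanning forward from the time of maximal rate, with
#' linear interpolation between adjacent window centers. Phi is computed on
#' the mean curve of a genotype's reference condition and then reused for
#' all treatments of that genotype. An additive shift (`phi + t`) captures
#' late growth of slow cultures; the result is capped at the last observed
#' time.
#'
#' @param reference Mean `growth_curve` of the reference condition.
#' @param traits Traits of that same curve from [estimate_traits()].
#' @param threshold_fraction Fraction of `mu` defining the cutoff
#'   (default 0.05).
#' @param shift Additive shift in minutes (default 0).
#' @param slope_window Odd slope window, matching the trait estimate.
#' @param reference_group Label of the genotype x condition defining Phi.
#' @return A `phi_point` list: `phi` (min), `threshold_fraction`, `shift`,
#'   `reference_group`, `reached` (FALSE if the rate never fell below the
#'   threshold, in which case `phi` is the last time).
#' @export
find_phi <- function(reference, traits, threshold_fraction = 0.05,
                     shift = 0, slope_window = 5, reference_group = "") {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must be in (0, 1)")
  }
  if (shift < 0) stop("shift must be >= 0")
  if (traits$mu <= 0) stop("Phi is undefined on a non-growing reference")
  sl <- sliding_slopes(reference$times, reference$log_ratio, slope_window)
  thr <- threshold_fraction * traits$mu
  after <- which(sl$t > traits$t_mu)
  reached <- FALSE
  phi <- max(reference$times)
  for (j in after) {
    if (sl$slope[j] < thr) {
      reached <- TRUE
      if (j == 1 || sl$slope[j - 1] < thr) {
        phi <- sl$t[j]
      } else {  # interpolate the crossing between adjacent window centers
        s0 <- sl$slope[j - 1]; s1 <- sl$slope[j]
        phi <- sl$t[j - 1] + (s0 - thr) / (s0 - s1) * (sl$t[j] - sl$t[j - 1])
      }
      break
    }
  }
  if (!reached) {
    warning("growth rate never fell below ",
            100 * threshold_fraction, "% of maximum; Phi set to last time")
  }
  structure(list(phi = min(phi + shift, max(reference$times)),
                 threshold_fraction = threshold_fraction, shift = shift,
                 reference_group = reference_group, reached = reached),
            class = "phi_point")
}

#' Area under the log-ratio curve up to Phi
#'
#' Trapezoidal integral of `L(t)` over `[0, phi]`, with the final partial
#' interval linearly interpolated. Negative log-ratios (measurement noise
#' below the starting OD) are clipped to 0 by default, since cumulative
#' growth cannot be negative in this readout.
#'
#' @param curve A `growth_curve`.
#' @param phi A `phi_point`, or a numeric time in minutes.
#' @param clip_negative Clip negative `L` to 0 before integration
#'   (default TRUE).
#' @return List with `auc` (log-ratio x minutes), `phi_used` (min) and
#'   `flags`.
#' @export
compute_auc <- function(curve, phi, clip_negative = TRUE) {
  phi_t <- if (inherits(phi, "phi_point")) phi$phi else as.numeric(phi)
  flags <- character()
  tt <- curve$times
  L <- if (clip_negative) pmax(curve$log_ratio, 0) else curve$log_ratio
  if (phi_t > max(tt)) {
    flags <- c(flags, "phi_beyond_grid")
    phi_t <- max(tt)
  }
  keep <- tt <= phi_t
  t_in <- tt[keep]; L_in <- L[keep]
  if (phi_t > max(t_in)) {  # partial last interval
    j <- sum(keep)
    frac <- (phi_t - tt[j]) / (tt[j + 1] - tt[j])
    t_in <- c(t_in, phi_t)
    L_in <- c(L_in, L[j] + frac * (L[j + 1] - L[j]))
  }
  # integrate from t = 0: prepend L(0) extrapolated as the first reading
  if (t_in[1] > 0) {
    t_in <- c(0, t_in); L_in <- c(L_in[1], L_in)
  }
  auc <- sum(diff(t_in) * (utils::head(L_in, -1) + utils::tail(L_in, -1)) / 2)
  list(auc = auc, phi_used = phi_t, flags = flags)
}

#' Relative AUC of a treated culture versus its control
#'
#' `delta_AUC = AUC_treated / AUC_control`, both computed to the same Phi.
#'
#' @param auc_treated,auc_control Results of [compute_auc()].
#' @param epsilon_scale Control AUCs below `epsilon_scale * phi` are
#'   considered zero and raise an error (default 1e-6).
#' @return The ratio (a single number).
#' @export
relative_auc <- function(auc_treated, auc_control, epsilon_scale = 1e-6) {
  if (abs(auc_treated$phi_used - auc_control$phi_used) > 1e-9) {
    stop("treated and control AUCs were computed at different Phi")
  }
  eps <- epsilon_scale * max(auc_control$phi_used, 1)
  if (auc_control$auc <= eps) {
    stop("control AUC is (near) zero; delta AUC undefined")
  }
  auc_treated$auc / auc_control$auc
}
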