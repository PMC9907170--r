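#' Construct an OD calibration model
#'
#' A zero-intercept quartic `y = c4*x^4 + c3*x^3 + c2*x^2 + c1*x` mapping
#' blank-subtracted recorded OD650 (`x`) to true OD at a 1-cm path length
#' (`y`). Plate readers saturate nonlinearly at high cell density; the
#' quartic absorbs both path-length and detector effects. The relationship
#' is spectrophotometer-dependent, so the model carries an instrument id and
#' downstream steps refuse to mix instruments unless overridden.
#'
#' @param coefficients Numeric vector `c(c1, c2, c3, c4)`.
#' @param domain Validity interval `c(0, x_max)` of recorded OD.
#' @param r_squared Goodness of fit in `[0, 1]` (NA if not from a fit).
#' @param instrument_id Instrument identifier string.
#' @return A `calibration_model` object.
#' @export
calibration_model <- function(coefficients, domain = c(0, 1.5),
                              r_squared = NA_real_,
                              instrument_id = "unknown") {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != 4 || any(!is.finite(coefficients))) {
    stop("coefficients must be 4 finite numbers c(c1, c2, c3, c4)")
  }
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1]")
  }
  m <- structure(list(coefficients = coefficients,
                      domain = c(0, as.numeric(domain[2])),
                      r_squared = as.numeric(r_squared),
                      instrument_id = as.character(instrument_id)),
                 class = "calibration_model")
  if (!poly_monotone(coefficients, m$domain)) {
    stop("calibration polynomial is not strictly increasing on its domain")
  }
  m
}

# numeric check of strict monotonicity of the zero-intercept quartic
poly_monotone <- function(cf, domain, n = 512) {
  x <- seq(max(domain[1], 1e-9), domain[2], length.out = n)
  deriv <- cf[1] + 2 * cf[2] * x + 3 * cf[3] * x^2 + 4 * cf[4] * x^3
  all(deriv > 0)
}

#' Calibration determined on the reference spectrophotometer
#'
#' The quartic `y = 1.9481 x^4 - 4.2474 x^3 + 5.0329 x^2 + 0.3441 x`
#' relating recorded to true OD650 for the microplate reader on which the
#' yeast micro-cultivation assay was developed. Used as the packaged default
#' for simulation and examples; real deployments should fit their own model
#' from a dilution series ([fit_calibration()]).
#'
#' @return A `calibration_model`.
#' @export
reference_calibration <- function() {
  calibration_model(c(0.3441, 5.0329, -4.2474, 1.9481),
                    domain = c(0, 1.5), r_squared = 0.999,
                    instrument_id = "reference-reader")
}

#' Subtract the per-cycle blank mean from a well series
#'
#' @param series A `well_timeseries` (sample well).
#' @param blanks List of `well_timeseries` for blank (medium-only) wells, or
#'   a single scalar blank override.
#' @param tol_min Tolerance (minutes) for matching time grids; defaults to
#'   one 10-min cycle.
#' @return The series with the blank mean subtracted per cycle, floored at 0.
#' @export
blank_correct <- function(series, blanks, tol_min = 10) {
  if (is.numeric(blanks) && length(blanks) == 1) {
    blank_mean <- rep(blanks, length(series$times))
  } else {
    if (inherits(blanks, "well_timeseries")) blanks <- list(blanks)
    if (!length(blanks)) {
      stop("no blank wells supplied; pass a scalar blank override instead")
    }
    for (b in blanks) {
      if (length(b$times) != length(series$times) ||
          any(abs(b$times - series$times) > tol_min)) {
        stop("blank well ", b$well, " is not on the same time grid")
      }
    }
    blank_mean <- rowMeans(vapply(blanks, function(b) b$od_raw,
                                  numeric(length(series$times))))
  }
  out <- series
  out$od_raw <- pmax(series$od_raw - blank_mean, 0)
  out
}

#' True ODs of a dilution series from its dilution factors
#'
#' The most dilute point (smallest factor) is anchored in the linear
#' detection regime at a user-supplied true OD; all other true ODs follow by
#' proportionality: `od_true_i = anchor_true_od * factor_i / factor_anchor`.
#'
#' @param points Data frame with columns `dilution_factor` (> 0, relative
#'   concentration) and `od_recorded` (blank-subtracted recorded OD).
#' @param anchor_true_od True OD of the most dilute point (> 0).
#' @return Data frame with columns `od_recorded`, `od_true`.
#' @export
true_od_from_dilution <- function(points, anchor_true_od) {
  if (anchor_true_od <= 0) stop("anchor_true_od must be positive")
  if (any(points$dilution_factor <= 0)) stop("dilution factors must be > 0")
  if (any(points$od_recorded < 0)) stop("od_recorded must be >= 0")
  f0 <- min(points$dilution_factor)
  data.frame(od_recorded = points$od_recorded,
             od_true = anchor_true_od * points$dilution_factor / f0)
}

#' Fit the zero-intercept quartic calibration by least squares
#'
#' Ordinary least squares on the monomial basis `{x, x^2, x^3, x^4}` with no
#' constant term, so that a zero recorded OD maps to a zero true OD by
#' construction. The fitted polynomial must be strictly increasing on the
#' observed recorded-OD range.
#'
#' @param pairs Data frame with columns `od_recorded`, `od_true`.
#' @param instrument_id Instrument identifier stored in the model.
#' @param min_pairs Minimum number of pairs (default 8).
#' @return A `calibration_model` with `r_squared = 1 - SS_res/SS_tot`.
#' @export
fit_calibration <- function(pairs, instrument_id = "unknown", min_pairs = 8) {
  x <- as.numeric(pairs$od_recorded)
  y <- as.numeric(pairs$od_true)
  if (length(x) < min_pairs) {
    stop("need at least ", min_pairs, " calibration pairs")
  }
  X <- cbind(x, x^2, x^3, x^4)
  if (qr(X)$rank < 4) stop("rank-deficient calibration design")
  if (min(x) > 0.05 || max(x) < 0.8) {
    warning("recorded OD range [", signif(min(x), 3), ", ", signif(max(x), 3),
            "] does not span [0.05, 0.8]; calibration may extrapolate")
  }
  fit <- stats::lm.fit(X, y)
  cf <- unname(fit$coefficients)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  calibration_model(cf, domain = c(0, max(x)),
                    r_squared = max(0, min(1, r2)),
                    instrument_id = instrument_id)
}

#' Apply a calibration model to recorded OD values
#'
#' Elementwise evaluation of the zero-intercept quartic. Values above the
#' fitted domain are extrapolated with a warning (growth curves can slightly
#' exceed the calibration series).
#'
#' @param model A `calibration_model`.
#' @param od_recorded Non-negative recorded OD value(s).
#' @return True OD value(s), same shape as the input.
#' @export
apply_calibration <- function(model, od_recorded) {
  x <- as.numeric(od_recorded)
  if (any(x < 0)) stop("recorded OD must be non-negative")
  if (any(x > model$domain[2])) {
    warning("recorded OD above calibration domain (max ",
            signif(model$domain[2], 4), "); extrapolating")
  }
  cf <- model$coefficients
  cf[1] * x + cf[2] * x^2 + cf[3] * x^3 + cf[4] * x^4
}

#' Invert a calibration model (true OD to recorded OD)
#'
#' Finds the unique root of the monotone quartic by bisection to absolute
#' tolerance 1e-10. Needed by the simulator to compress true OD back into
#' recorded OD.
#'
#' @param model A `calibration_model`.
#' @param od_true True OD value(s), within the attainable range
#'   `[0, apply_calibration(model, domain_max)]`.
#' @return Recorded OD value(s).
#' @export
invert_calibration <- function(model, od_true) {
  y <- as.numeric(od_true)
  xmax <- model$domain[2]
  ymax <- suppressWarnings(apply_calibration(model, xmax))
  if (any(y < 0 | y > ymax + 1e-12)) {
    stop("true OD outside attainable range [0, ", signif(ymax, 6), "]")
  }
  vapply(y, function(yy) {
    if (yy <= 0) return(0)
    lo <- 0; hi <- xmax
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (suppressWarnings(apply_calibration(model, mid)) < yy) lo <- mid
      else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Write a calibration model to JSON
#'
#' @param model A `calibration_model`.
#' @param path Output JSON path.
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(
    list(instrument_id = model$instrument_id,
         coefficients = model$coefficients,
         domain = model$domain,
         r_squared = model$r_squared),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path JSON path written by [write_calibration()].
#' @return A `calibration_model`.
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(j$coefficients, domain = j$domain,
                    r_squared = if (is.null(j$r_squared)) NA_real_
                                else j$r_squared,
                    instrument_id = j$instrument_id)
}
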