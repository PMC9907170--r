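#' Evaluate a two-phase exponential decay
#'
#' `y(t) = a1 * exp(-t/tau1) + a2 * exp(-t/tau2)`. In spheroplast bursting
#' traces the fast phase (a1, tau1) is the rapid OD650 drop as spheroplasts
#' swell and burst under hypotonic shock — its amplitude a1 indexes
#' membrane water permeability — while the slow phase reflects spheroplast
#' settling or drift (its time constant may be negative, i.e. a slowly
#' growing component).
#'
#' @param params List or `burst_kinetics` with `a1`, `tau1`, `a2`, `tau2`.
#' @param t Time(s) in seconds.
#' @return Model value(s).
#' @export
evaluate_two_phase <- function(params, t) {
  if (params$tau1 == 0 || params$tau2 == 0) {
    stop("time constants must be nonzero")
  }
  params$a1 * exp(-t / params$tau1) + params$a2 * exp(-t / params$tau2)
}

#' Fit a two-phase exponential to a spheroplast bursting trace
#'
#' Unconstrained nonlinear least squares of the two-term model with
#' multi-start initialization: tau1 over \{0.05, 0.1, 0.2, 0.5\} s, tau2
#' over \{1, 3, 10, -10\} s, and starting amplitudes from a linear solve
#' given the time constants. After convergence the term with the smallest
#' positive time constant is labeled the fast phase (a1, tau1); a fit in
#' which both time constants are negative is rejected, since the fast phase
#' must decay to be interpretable as bursting.
#'
#' @param trace List or data frame with `times` (seconds, >= 10 points,
#'   strictly increasing) and `od650` (change-in-OD values, pre-baselined).
#' @param baseline_subtract If TRUE, subtract the mean of the final 0.5 s
#'   before fitting (default FALSE; traces are normally pre-baselined).
#' @return A `burst_kinetics` list: `a1`, `tau1` (> 0), `a2`, `tau2`, `rss`.
#' @export
fit_two_phase <- function(trace, baseline_subtract = FALSE) {
  tt <- as.numeric(trace$times)
  y <- as.numeric(trace$od650)
  if (length(tt) < 10) stop("trace needs at least 10 points")
  if (any(diff(tt) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(y))) stop("trace values must be finite")
  if (baseline_subtract) {
    tail_idx <- tt >= max(tt) - 0.5
    y <- y - mean(y[tail_idx])
  }
  best <- NULL
  for (t1 in c(0.05, 0.1, 0.2, 0.5)) for (t2 in c(1, 3, 10, -10)) {
    # linear solve for amplitudes at the starting time constants
    E <- cbind(exp(-tt / t1), exp(-tt / t2))
    ab <- tryCatch(stats::lm.fit(E, y)$coefficients, error = function(e) NULL)
    if (is.null(ab) || any(!is.finite(ab))) ab <- c(max(y), 0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * exp(-tt / tau1) + a2 * exp(-tt / tau2),
        start = list(a1 = ab[1], tau1 = t1, a2 = ab[2], tau2 = t2),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      p <- as.list(stats::coef(fit))
      if (p$tau1 > 0 || p$tau2 > 0) {
        if (is.null(best) || rss < best$rss) best <- c(p, list(rss = rss))
      }
    }
  }
  if (is.null(best)) {
    stop("two-phase fit failed: no convergent start with a positive ",
         "time constant")
  }
  # label the phase with the smallest positive time constant as fast
  taus <- c(best$tau1, best$tau2)
  amps <- c(best$a1, best$a2)
  pos <- which(taus > 0)
  fast <- pos[which.min(taus[pos])]
  slow <- setdiff(1:2, fast)
  structure(list(a1 = amps[fast], tau1 = taus[fast],
                 a2 = amps[slow], tau2 = taus[slow], rss = best$rss),
            class = "burst_kinetics")
}

#' Rank samples by water permeability (fast-phase amplitude)
#'
#' Orders fitted bursting kinetics by descending a1 — a greater fast-phase
#' amplitude indicates more efficient water influx into spheroplasts. Ties
#' break by smaller tau1, then by name.
#'
#' @param fits Named list of `burst_kinetics`.
#' @return Character vector of names in descending permeability order.
#' @export
rank_permeability <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits to rank")
  a1 <- vapply(fits, function(f) f$a1, 0)
  tau1 <- vapply(fits, function(f) f$tau1, 0)
  names(fits)[order(-a1, tau1, names(fits))]
}

#' Reference spheroplast bursting parameter sets
#'
#' Published two-phase exponential fits of osmotic-shock bursting traces
#' for yeast expressing selected Arabidopsis PIP aquaporins and the
#' empty-vector control, used as simulation fixtures and regression
#' anchors. The empty-vector slow phase has negative amplitude and negative
#' time constant (a slow drift), which the fitter must tolerate.
#'
#' @return Named list of parameter lists (`a1`, `tau1`, `a2`, `tau2`).
#' @export
reference_burst_params <- function() {
  list(
    "empty"     = list(a1 = 0.00881, tau1 = 0.243,
                       a2 = -0.05398, tau2 = -6.47128),
    "AtPIP1;5"  = list(a1 = 0.02937, tau1 = 0.09966,
                       a2 = 0.13874, tau2 = 3.76055),
    "AtPIP2;1"  = list(a1 = 0.10037, tau1 = 0.15797,
                       a2 = 0.10763, tau2 = 3.51469),
    "AtPIP2;7"  = list(a1 = 0.16814, tau1 = 0.18973,
                       a2 = 0.07791, tau2 = 2.43538)
  )
}
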