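#' Build a dose-response table from per-well results
#'
#' Aggregates replicate delta-AUC values per concentration into means and
#' SEMs for one genotype. Inhibitory series (cytotoxic compounds) are
#' anchored at the untreated condition (delta AUC = 1 by construction);
#' growth-promoting series (required nutrients) are anchored at the maximal
#' supplementation, renormalizing so its mean is 1.
#'
#' @param results Results rows (data frame) for a single genotype, with
#'   columns `concentration` and `delta_auc_vs_control`.
#' @param direction `"inhibitory"` or `"promoting"`.
#' @return A `dose_response_table`: data frame `(concentration,
#'   delta_auc_mean, delta_auc_sem, n)` sorted by concentration, with
#'   attribute `direction`.
#' @export
build_dose_response <- function(results, direction = c("inhibitory",
                                                       "promoting")) {
  direction <- match.arg(direction)
  d <- results[is.finite(results$delta_auc_vs_control), , drop = FALSE]
  concs <- sort(unique(d$concentration))
  if (length(concs) < 3) {
    stop("need at least 3 distinct concentrations (including the reference)")
  }
  ref_conc <- if (direction == "inhibitory") 0 else max(concs)
  if (!ref_conc %in% concs) {
    stop("reference condition (concentration ", ref_conc, ") missing")
  }
  agg <- do.call(rbind, lapply(concs, function(cc) {
    v <- d$delta_auc_vs_control[d$concentration == cc]
    data.frame(concentration = cc, delta_auc_mean = mean(v),
               delta_auc_sem = if (length(v) > 1)
                 stats::sd(v) / sqrt(length(v)) else 0,
               n = length(v))
  }))
  if (direction == "promoting") {
    top_mean <- agg$delta_auc_mean[agg$concentration == ref_conc]
    agg$delta_auc_mean <- agg$delta_auc_mean / top_mean
    agg$delta_auc_sem <- agg$delta_auc_sem / top_mean
  }
  structure(agg, class = c("dose_response_table", "data.frame"),
            direction = direction)
}

#' Evaluate a four-parameter logistic dose-response curve
#'
#' Inhibitory orientation: `y(c) = bottom + (top - bottom) / (1 +
#' (c/ec50)^hill)`, decreasing in concentration with `y(0) = top`.
#' Promoting orientation swaps the asymptotes so the curve rises to `top`.
#'
#' @param conc Concentration(s), >= 0.
#' @param bottom,top Asymptotes.
#' @param ec50 Half-effect concentration (> 0).
#' @param hill Hill slope magnitude (> 0).
#' @param direction `"inhibitory"` or `"promoting"`.
#' @return Fitted response value(s).
#' @export
four_pl <- function(conc, bottom, top, ec50, hill,
                    direction = c("inhibitory", "promoting")) {
  direction <- match.arg(direction)
  r <- (conc / ec50)^hill          # 0^positive = 0, so conc 0 is exact
  if (direction == "inhibitory") bottom + (top - bottom) / (1 + r)
  else bottom + (top - bottom) * r / (1 + r)
}

#' Fit a four-parameter logistic to a dose-response table
#'
#' Nonlinear least squares on the untransformed 4PL form (no log(c)
#' singularity at zero concentration), multi-start over a grid of Hill
#' slopes (0.5, 1, 2, 4) and EC50 values (geometric grid over the tested
#' positive range); the best residual sum of squares wins. With fewer than
#' 4 distinct concentrations the top asymptote is fixed at 1 and 3
#' parameters are fitted. A response spanning less than 0.05 delta-AUC is
#' flagged flat and no EC50 is reported.
#'
#' @param table A `dose_response_table` from [build_dose_response()].
#' @return A `four_pl_fit` list: `bottom`, `top`, `ec50`, `hill`, `rss`,
#'   `direction`, `flat` (logical).
#' @export
fit_four_pl <- function(table) {
  direction <- attr(table, "direction")
  cc <- table$concentration
  y <- table$delta_auc_mean
  span <- max(y) - min(y)
  if (span < 0.05) {
    return(structure(list(bottom = min(y), top = max(y), ec50 = NA_real_,
                          hill = NA_real_, rss = sum((y - mean(y))^2),
                          direction = direction, flat = TRUE),
                     class = "four_pl_fit"))
  }
  fix_top <- length(unique(cc)) < 4
  pos <- cc[cc > 0]
  ec50_grid <- exp(seq(log(min(pos)), log(max(pos)), length.out = 5))
  best <- NULL
  for (h0 in c(0.5, 1, 2, 4)) for (e0 in ec50_grid) {
    fit <- tryCatch({
      if (fix_top) {
        minpack.lm::nlsLM(
          y ~ four_pl(cc, bottom, 1, ec50, hill, direction),
          start = list(bottom = min(y), ec50 = e0, hill = h0),
          lower = c(bottom = -Inf, ec50 = 1e-12, hill = 1e-3),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        minpack.lm::nlsLM(
          y ~ four_pl(cc, bottom, top, ec50, hill, direction),
          start = list(bottom = min(y), top = max(y), ec50 = e0, hill = h0),
          lower = c(bottom = -Inf, top = -Inf, ec50 = 1e-12, hill = 1e-3),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("four-parameter logistic fit failed at all starts")
  p <- as.list(stats::coef(best$fit))
  if (fix_top) p$top <- 1
  structure(list(bottom = p$bottom, top = p$top, ec50 = p$ec50,
                 hill = p$hill, rss = best$rss, direction = direction,
                 flat = FALSE),
            class = "four_pl_fit")
}

#' Predict from a fitted four-parameter logistic
#'
#' @param object A `four_pl_fit`.
#' @param conc Concentrations at which to evaluate.
#' @param ... Unused.
#' @return Fitted delta-AUC values.
#' @export
predict.four_pl_fit <- function(object, conc, ...) {
  if (object$flat) stop("flat-response fit has no dose-response curve")
  four_pl(conc, object$bottom, object$top, object$ec50, object$hill,
          object$direction)
}

#' Recommend screening concentrations from a dose-response fit
#'
#' Screening doses are chosen at the commencement of pronounced growth
#' inhibition — the upper shoulder / linear range of the dose-response
#' curve — operationalized as the tested concentrations whose fitted
#' delta-AUC values are nearest the target levels (default 0.75 and 0.5).
#' If every tested dose is already saturating (fitted delta-AUC < 0.1), the
#' two smallest tested doses are returned instead.
#'
#' @param fit A `four_pl_fit`.
#' @param tested Concentrations actually tested (the recommendation is
#'   restricted to these).
#' @param targets Target delta-AUC levels (default `c(0.75, 0.5)`).
#' @return List with `concentrations` (ascending, one per target;
#'   duplicates moved to adjacent tested doses), `targets` and `note`.
#' @export
recommend_concentrations <- function(fit, tested, targets = c(0.75, 0.5)) {
  if (!length(tested)) stop("no tested concentrations supplied")
  tested <- sort(unique(tested))
  if (fit$flat) {
    return(list(concentrations = numeric(), targets = targets,
                note = "flat response; no recommendation"))
  }
  note <- ""
  if (length(tested) == 1) {
    return(list(concentrations = rep(tested, length(targets)),
                targets = targets,
                note = "single tested dose; returned for every target"))
  }
  yhat <- predict(fit, tested)
  if (all(yhat < 0.1)) {
    return(list(concentrations = tested[1:2], targets = targets,
                note = "all tested doses saturating; two smallest returned"))
  }
  picks <- vapply(targets, function(lv) tested[which.min(abs(yhat - lv))],
                  numeric(1))
  # collapse duplicates onto adjacent tested concentrations
  for (i in seq_along(picks)[-1]) {
    while (picks[i] %in% picks[seq_len(i - 1)]) {
      j <- match(picks[i], tested)
      if (j < length(tested)) picks[i] <- tested[j + 1]
      else if (j > 1) picks[i] <- tested[j - 1]
      else break
    }
  }
  list(concentrations = sort(picks), targets = targets, note = note)
}
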