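#' Analysis configuration for a screen
#'
#' Bundles every tunable parameter of the pipeline with its default. The
#' `direction` determines the reference condition of each genotype's
#' treatment series: `"toxic"` compounds use the untreated culture
#' (concentration 0), `"nutrient"` agents use the highest supplementation.
#'
#' @param despike_window,avg_window Smoothing windows
#'   (see [smooth_series()]).
#' @param init_cycles,od_floor Log-transform parameters
#'   (see [log_transform()]).
#' @param slope_window Sliding OLS slope window (points).
#' @param phi_threshold Fraction of mu defining Phi (default 0.05).
#' @param phi_shift Additive Phi shift in minutes (default 0).
#' @param clip_negative Clip negative log-ratios in AUC (default TRUE).
#' @param direction `"toxic"` or `"nutrient"`.
#' @param control_genotype Name of the empty-vector control genotype.
#' @param phi_mode `"per_genotype"` (each genotype's own reference
#'   condition defines its Phi; the default, since heterologous expression
#'   alters inherent growth) or `"global"` (the control genotype's Phi is
#'   applied to all, for sensitivity analysis).
#' @param alpha_levels Significance thresholds for LSD marks.
#' @return A `screen_config` list.
#' @export
screen_config <- function(despike_window = 5, avg_window = 3,
                          init_cycles = 3, od_floor = 1e-4,
                          slope_window = 5, phi_threshold = 0.05,
                          phi_shift = 0, clip_negative = TRUE,
                          direction = c("toxic", "nutrient"),
                          control_genotype = "empty",
                          phi_mode = c("per_genotype", "global"),
                          alpha_levels = c(0.05, 0.01)) {
  structure(list(despike_window = despike_window, avg_window = avg_window,
                 init_cycles = init_cycles, od_floor = od_floor,
                 slope_window = slope_window, phi_threshold = phi_threshold,
                 phi_shift = phi_shift, clip_negative = clip_negative,
                 direction = match.arg(direction),
                 control_genotype = control_genotype,
                 phi_mode = match.arg(phi_mode),
                 alpha_levels = alpha_levels),
            class = "screen_config")
}

# blank-correct, calibrate and smooth one sample well; returns growth_curve
process_well <- function(series, blanks, calib, config) {
  bc <- blank_correct(series, blanks)
  od_true <- suppressWarnings(apply_calibration(calib, bc$od_raw))
  extrapolated <- any(bc$od_raw > calib$domain[2])
  od_s <- smooth_series(od_true, config$despike_window, config$avg_window)
  curve <- log_transform(od_s, series$times, config$init_cycles,
                         config$od_floor)
  if (extrapolated) curve$flags <- c(curve$flags, "calibration_extrapolated")
  curve
}

#' Run the full screen analysis
#'
#' Orchestrates blank correction, calibration, smoothing, log transform,
#' per-genotype Phi on the reference condition, AUC and relative AUC
#' (delta AUC versus the genotype's reference; rel AUC versus the
#' empty-vector control), and the comparison statistics.
#'
#' @param timeseries Named list of `well_timeseries` (samples and blanks),
#'   e.g. from [read_plate_timeseries()] or [simulate_screen()].
#' @param map A `plate_map` covering the wells.
#' @param calib A `calibration_model`.
#' @param config A `screen_config`.
#' @return A `screen_result` list: `results` (per-well table), `phi` (per
#'   genotype), `traits` (per genotype, reference condition),
#'   `comparisons` (per concentration: LSD table and Tukey letters),
#'   `warnings` (data frame of well-level flags), `config`.
#' @export
run_screen <- function(timeseries, map, calib, config = screen_config()) {
  map <- as.data.frame(map)
  key <- paste0(map$plate_id, ":", map$well)
  ts_key <- names(timeseries)
  if (is.null(ts_key)) stop("timeseries must be a named list")
  samples <- map[map$role == "sample", , drop = FALSE]
  if (!config$control_genotype %in% samples$genotype) {
    stop("control genotype '", config$control_genotype,
         "' absent from plate map")
  }
  warn_rows <- list()
  note <- function(plate, well, flag) {
    warn_rows[[length(warn_rows) + 1]] <<- data.frame(
      plate_id = plate, well = well, flag = flag, stringsAsFactors = FALSE)
  }
  # blanks per plate
  blanks_by_plate <- lapply(split(map[map$role == "blank", , drop = FALSE],
                                  map$plate_id[map$role == "blank"]),
                            function(d) timeseries[paste0(d$plate_id, ":",
                                                          d$well)])
  # process every sample well
  curves <- list()
  for (i in seq_len(nrow(samples))) {
    k <- paste0(samples$plate_id[i], ":", samples$well[i])
    s <- timeseries[[k]]
    if (is.null(s)) stop("no time series for mapped well ", k)
    bl <- blanks_by_plate[[samples$plate_id[i]]]
    if (is.null(bl) || !length(bl)) {
      stop("plate ", samples$plate_id[i], " has no blank wells")
    }
    cv <- process_well(s, bl, calib, config)
    for (f in cv$flags) note(samples$plate_id[i], samples$well[i], f)
    curves[[k]] <- cv
  }
  samples$key <- paste0(samples$plate_id, ":", samples$well)
  # reference condition per genotype
  ref_conc_for <- function(d) {
    flagged <- d$concentration[d$is_reference_condition]
    if (length(flagged)) return(flagged[1])
    if (config$direction == "toxic") 0 else max(d$concentration)
  }
  genos <- unique(samples$genotype)
  phi_by_geno <- list(); traits_by_geno <- list(); ref_auc <- list()
  excluded <- character()
  for (g in genos) {
    d <- samples[samples$genotype == g, , drop = FALSE]
    rc <- ref_conc_for(d)
    ref_keys <- d$key[d$concentration == rc]
    if (!length(ref_keys)) {
      note("", "", paste0("genotype ", g, " missing reference condition"))
      excluded <- c(excluded, g)
      next
    }
    agg <- aggregate_replicates(curves[ref_keys])
    tr <- estimate_traits(agg$mean, config$slope_window)
    ph <- withCallingHandlers(
      find_phi(agg$mean, tr, config$phi_threshold, config$phi_shift,
               config$slope_window,
               reference_group = paste0(g, " @ ", rc)),
      warning = function(w) {
        note("", "", paste0("genotype ", g, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    phi_by_geno[[g]] <- ph
    traits_by_geno[[g]] <- tr
  }
  if (config$control_genotype %in% excluded) {
    stop("control genotype lacks its reference condition")
  }
  if (config$phi_mode == "global") {
    for (g in names(phi_by_geno)) {
      phi_by_geno[[g]] <- phi_by_geno[[config$control_genotype]]
    }
  }
  # per-well AUC at the genotype's Phi
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    g <- samples$genotype[i]
    if (g %in% excluded) next
    res <- compute_auc(curves[[samples$key[i]]], phi_by_geno[[g]],
                       config$clip_negative)
    for (f in res$flags) note(samples$plate_id[i], samples$well[i], f)
    # per-well traits are diagnostic; Phi/AUC are the screen readout
    tr <- estimate_traits(curves[[samples$key[i]]], config$slope_window)
    rows[[length(rows) + 1]] <- data.frame(
      genotype = g, treatment = samples$treatment[i],
      concentration = samples$concentration[i],
      replicate = samples$replicate[i],
      lambda = tr$lambda, mu = tr$mu, kappa = tr$kappa,
      phi_used = res$phi_used, auc = res$auc,
      delta_auc_vs_control = NA_real_, rel_auc_vs_empty = NA_real_,
      flags = paste(curves[[samples$key[i]]]$flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  # delta AUC versus the genotype's reference-condition mean AUC
  for (g in setdiff(genos, excluded)) {
    d <- samples[samples$genotype == g, , drop = FALSE]
    rc <- ref_conc_for(d)
    sel <- results$genotype == g
    ref_mean <- mean(results$auc[sel & results$concentration == rc])
    if (ref_mean <= 1e-6 * max(results$phi_used[sel], 1)) {
      note("", "", paste0("genotype ", g, ": reference AUC near zero"))
      next
    }
    results$delta_auc_vs_control[sel] <- results$auc[sel] / ref_mean
  }
  # second-level normalization to the empty-vector control
  ev <- config$control_genotype
  for (cc in unique(results$concentration)) {
    sel_c <- results$concentration == cc
    ev_mean <- mean(results$delta_auc_vs_control[sel_c &
                                                   results$genotype == ev])
    if (is.finite(ev_mean) && ev_mean > 0) {
      results$rel_auc_vs_empty[sel_c] <-
        results$delta_auc_vs_control[sel_c] / ev_mean
    }
  }
  # comparison statistics per non-reference concentration
  comparisons <- list()
  for (cc in sort(unique(results$concentration))) {
    d <- results[results$concentration == cc &
                   is.finite(results$delta_auc_vs_control), , drop = FALSE]
    grp <- split(d$delta_auc_vs_control, d$genotype)
    grp <- grp[vapply(grp, length, 0L) >= 2]
    if (length(grp) >= 2 && ev %in% names(grp)) {
      lsd <- anova_lsd(grp, ev, config$alpha_levels)
      lsd$tukey_letters <- unname(tukey_letters(grp,
                                                config$alpha_levels[1]))[
        match(lsd$group, names(grp))]
      comparisons[[as.character(cc)]] <- lsd
    }
  }
  warnings_df <- if (length(warn_rows)) do.call(rbind, warn_rows) else
    data.frame(plate_id = character(), well = character(),
               flag = character(), stringsAsFactors = FALSE)
  structure(list(results = results, phi = phi_by_geno,
                 traits = traits_by_geno, comparisons = comparisons,
                 warnings = warnings_df, config = config),
            class = "screen_result")
}

#' Recompute delta AUC over a sweep of Phi shifts
#'
#' Shifting Phi forward (`phi + t`) captures late growth of slowly
#' recovering cultures (e.g. after freeze-thaw), at the cost of
#' underestimating delta AUC because the control plateaued earlier. AUC is
#' non-decreasing in the shift for every culture (asserted).
#'
#' @param timeseries,map,calib,config As for [run_screen()].
#' @param shifts Numeric vector of shifts in minutes (0 reproduces
#'   [run_screen()]).
#' @return Data frame of per-well rows `(shift, genotype, treatment,
#'   concentration, replicate, phi_used, auc, delta_auc_vs_control,
#'   rel_auc_vs_empty)`.
#' @export
run_phi_shift_sweep <- function(timeseries, map, calib,
                                config = screen_config(),
                                shifts = c(0, 1000)) {
  out <- list()
  prev_auc <- NULL
  for (sh in sort(shifts)) {
    cfg <- config
    cfg$phi_shift <- sh
    res <- run_screen(timeseries, map, calib, cfg)$results
    key <- paste(res$genotype, res$concentration, res$replicate)
    auc <- res$auc[order(key)]
    if (!is.null(prev_auc) && any(auc < prev_auc - 1e-9)) {
      stop("AUC decreased with a larger Phi shift; integration is broken")
    }
    prev_auc <- auc
    res$shift <- sh
    out[[as.character(sh)]] <- res[c("shift", "genotype", "treatment",
                                     "concentration", "replicate",
                                     "phi_used", "auc",
                                     "delta_auc_vs_control",
                                     "rel_auc_vs_empty")]
  }
  do.call(rbind, out)
}
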