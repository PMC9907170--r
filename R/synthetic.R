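#' Specification of a simulated well's growth
#'
#' Growth is simulated with the Zwietering reparameterization of the
#' Gompertz curve, whose parameters are exactly the derived growth traits:
#' lag `lambda` (min), maximum specific rate `mu` (per min) and asymptotic
#' log-ratio `A` (so carrying capacity kappa = od_init * exp(A)).
#'
#' @param od_init True initial OD (default 0.05).
#' @param lambda Lag time in minutes.
#' @param mu Maximum specific growth rate per minute.
#' @param A Asymptotic log-ratio (<= 6).
#' @return A `well_sim_spec` list.
#' @export
well_sim_spec <- function(od_init = 0.05, lambda = 300, mu = 0.012, A = 3) {
  if (any(c(od_init, lambda, mu, A) <= 0)) {
    stop("all simulation parameters must be positive")
  }
  if (A > 6) stop("asymptotic log-ratio A must be <= 6")
  structure(list(od_init = od_init, lambda = lambda, mu = mu, A = A),
            class = "well_sim_spec")
}

#' Zwietering-Gompertz log-ratio curve
#'
#' `L(t) = A * exp(-exp((mu * e / A) * (lambda - t) + 1))`. The tangent at
#' the inflection has slope `mu` and crosses `L = 0` at `t = lambda`, so
#' the generator parameters are directly the traits the analysis recovers.
#'
#' @param spec A `well_sim_spec`.
#' @param t Time(s) in minutes (>= 0).
#' @return Log-ratio value(s); true OD is `od_init * exp(L)`.
#' @export
gompertz_log_ratio <- function(spec, t) {
  spec$A * exp(-exp((spec$mu * exp(1) / spec$A) * (spec$lambda - t) + 1))
}

#' Treatment effect model for the simulator
#'
#' Phenomenological trait modifiers. `toxic`: Hill-shaped dose effects
#' lengthen lag and depress rate and capacity. `nutrient`: rate and
#' capacity rise saturably with supplementation (multiplier
#' `1 - emax + emax * Hill(dose)`, so the maximal dose restores the
#' unstressed trait). `freeze_thaw`: each cycle multiplies the viable
#' inoculum by survivorship `s`, leaving traits unchanged — lag extends
#' emergently because the curve starts lower.
#'
#' @param kind `"toxic"`, `"nutrient"` or `"freeze_thaw"`.
#' @param on_lambda,on_mu,on_kappa Per-trait Hill parameters
#'   `c(emax, ec50, h)` (toxic/nutrient kinds).
#' @param survivorship Per-cycle survival fraction in (0, 1]
#'   (freeze_thaw kind).
#' @return A `treatment_model` list.
#' @export
treatment_model <- function(kind = c("toxic", "nutrient", "freeze_thaw"),
                            on_lambda = c(0, 1, 1), on_mu = c(0, 1, 1),
                            on_kappa = c(0, 1, 1), survivorship = 1) {
  kind <- match.arg(kind)
  for (p in list(on_lambda, on_mu, on_kappa)) {
    if (length(p) != 3 || p[2] <= 0 || p[3] <= 0) {
      stop("Hill parameters must be c(emax, ec50 > 0, h > 0)")
    }
  }
  if (survivorship <= 0 || survivorship > 1) {
    stop("survivorship must be in (0, 1]")
  }
  structure(list(kind = kind, on_lambda = on_lambda, on_mu = on_mu,
                 on_kappa = on_kappa, survivorship = survivorship),
            class = "treatment_model")
}

hill_effect <- function(p, dose) {
  if (dose <= 0) return(0)
  p[1] * dose^p[3] / (dose^p[3] + p[2]^p[3])
}

#' Apply a treatment model to a well specification
#'
#' @param spec A `well_sim_spec`.
#' @param model A `treatment_model`.
#' @param dose Concentration (toxic/nutrient) or number of freeze-thaw
#'   cycles (>= 0).
#' @return The modified `well_sim_spec`.
#' @export
apply_treatment <- function(spec, model, dose) {
  if (dose < 0) stop("dose must be >= 0")
  out <- spec
  if (model$kind == "toxic") {
    out$lambda <- spec$lambda * (1 + hill_effect(model$on_lambda, dose))
    out$mu <- spec$mu * (1 - hill_effect(model$on_mu, dose))
    out$A <- spec$A * (1 - hill_effect(model$on_kappa, dose))
  } else if (model$kind == "nutrient") {
    sat <- function(p) 1 - p[1] + hill_effect(p, dose)
    out$mu <- spec$mu * sat(model$on_mu)
    out$A <- spec$A * sat(model$on_kappa)
  } else {  # freeze_thaw: reduce viable inoculum, keep traits
    out$od_init <- max(spec$od_init * model$survivorship^dose, 1e-6)
  }
  if (out$mu <= 0 || out$A <= 0 || out$lambda < 0) {
    stop("treatment effect drove a trait non-positive; check emax bounds")
  }
  out
}

#' Measurement noise specification
#'
#' @param od_sd Additive recorded-OD noise SD (default 0.003).
#' @param spike_prob Per-reading probability of a sedimentation spike
#'   (default 0.002).
#' @param spike_scale Multiplicative spike factor (default 1.5).
#' @param blank_offset Recorded-OD blank level (default 0.08).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(od_sd = 0.003, spike_prob = 0.002,
                       spike_scale = 1.5, blank_offset = 0.08) {
  if (spike_prob < 0 || spike_prob > 1) stop("spike_prob must be in [0, 1]")
  if (od_sd < 0) stop("od_sd must be >= 0")
  structure(list(od_sd = od_sd, spike_prob = spike_prob,
                 spike_scale = spike_scale, blank_offset = blank_offset),
            class = "noise_spec")
}

#' Convert true-OD series into recorded plate readings
#'
#' Inverts the calibration (compressing true OD into what the detector
#' records), adds the blank offset, Gaussian detector noise on the recorded
#' scale, and sporadic multiplicative sedimentation spikes. Blank wells
#' emit the blank offset plus noise. Deterministic given `seed`.
#'
#' @param true_plate Named list of true-OD numeric series (one per sample
#'   well), all on the grid `times`.
#' @param times Reading times in minutes.
#' @param calib A `calibration_model`.
#' @param noise A `noise_spec`.
#' @param n_blanks Number of blank wells to append (default 3).
#' @param plate_id Plate identifier.
#' @param wells Optional well coordinates for the sample series (defaults
#'   to row-major A1, A2, ...).
#' @param seed Integer RNG seed.
#' @return Named list of `well_timeseries` (samples then blanks).
#' @export
measure_plate <- function(true_plate, times, calib, noise = noise_spec(),
                          n_blanks = 3, plate_id = "plate1", wells = NULL,
                          seed = 1) {
  n_series <- length(true_plate)
  all_wells <- plate_wells()
  if (is.null(wells)) wells <- all_wells[seq_len(n_series)]
  blank_wells <- setdiff(all_wells, wells)[seq_len(n_blanks)]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_series)) {
    od_true <- true_plate[[i]]
    rec <- invert_calibration(calib, od_true)
    rec <- rec + noise$blank_offset +
      stats::rnorm(length(rec), 0, noise$od_sd)
    spikes <- stats::runif(length(rec)) < noise$spike_prob
    rec[spikes] <- rec[spikes] * noise$spike_scale
    out[[wells[i]]] <- well_timeseries(plate_id, wells[i], times,
                                       pmax(rec, 0))
  }
  for (w in blank_wells) {
    rec <- noise$blank_offset + stats::rnorm(length(times), 0, noise$od_sd)
    out[[w]] <- well_timeseries(plate_id, w, times, pmax(rec, 0))
  }
  out
}

plate_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default cultivation grid
#'
#' 250 cycles at 10 minutes per cycle (~42 h), the routine micro-cultivation
#' cycling conditions.
#'
#' @param cycles Number of cycles (default 250).
#' @param cycle_min Minutes per cycle (default 10).
#' @return Times in minutes, starting at 0.
#' @export
default_time_grid <- function(cycles = 250, cycle_min = 10) {
  seq(0, by = cycle_min, length.out = cycles)
}

#' Simulate a full screen (time series + plate map)
#'
#' Generates a synthetic screen dataset: per genotype a growth
#' specification, per treatment a dose series, replicate wells with small
#' trait jitter (CV 2%), measured through the calibration inverse with
#' noise, plus blank wells, split across plates of at most 93 sample wells.
#'
#' @param genotypes Named list of `well_sim_spec` (one per genotype; must
#'   include the empty-vector control genotype).
#' @param treatment A `treatment_model`.
#' @param doses Numeric vector of doses; for toxic kind must include 0 (the
#'   untreated reference).
#' @param replicates Replicate wells per genotype x dose (default 3).
#' @param calib A `calibration_model` (default [reference_calibration()]).
#' @param noise A `noise_spec`.
#' @param times Time grid (default [default_time_grid()]).
#' @param treatment_name Label written to the plate map.
#' @param conc_unit Concentration unit label.
#' @param empty_vector_genotype Name of the empty-vector genotype in
#'   `genotypes` (flagged in the map).
#' @param jitter_cv Replicate-level coefficient of variation on traits
#'   (default 0.02).
#' @param seed Integer RNG seed; the whole simulation is deterministic
#'   given it.
#' @return List with `timeseries` (named list of `well_timeseries`) and
#'   `map` (a `plate_map`).
#' @export
simulate_screen <- function(genotypes, treatment, doses, replicates = 3,
                            calib = reference_calibration(),
                            noise = noise_spec(),
                            times = default_time_grid(),
                            treatment_name = "treatment", conc_unit = "mM",
                            empty_vector_genotype = "empty",
                            jitter_cv = 0.02, seed = 1) {
  if (treatment$kind == "toxic" && !0 %in% doses) {
    stop("toxic treatment series must include dose 0 (untreated reference)")
  }
  design <- expand.grid(replicate = seq_len(replicates), dose = doses,
                        genotype = names(genotypes),
                        stringsAsFactors = FALSE)
  ref_dose <- if (treatment$kind == "nutrient") max(doses) else 0
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(design)
  per_plate <- 93
  design$plate <- ceiling(seq_len(n) / per_plate)
  all_ts <- list()
  map_rows <- list()
  for (pl in unique(design$plate)) {
    idx <- which(design$plate == pl)
    plate_id <- paste0("plate", pl)
    wells <- plate_wells()[seq_along(idx)]
    true_series <- list()
    for (k in seq_along(idx)) {
      row <- design[idx[k], ]
      spec0 <- genotypes[[row$genotype]]
      # replicate-level trait jitter
      spec <- well_sim_spec(
        od_init = spec0$od_init,
        lambda = spec0$lambda * (1 + stats::rnorm(1, 0, jitter_cv)),
        mu = spec0$mu * (1 + stats::rnorm(1, 0, jitter_cv)),
        A = min(spec0$A * (1 + stats::rnorm(1, 0, jitter_cv)), 6))
      spec <- apply_treatment(spec, treatment, row$dose)
      true_series[[wells[k]]] <- spec$od_init *
        exp(gompertz_log_ratio(spec, times))
      map_rows[[length(map_rows) + 1]] <- data.frame(
        plate_id = plate_id, well = wells[k], genotype = row$genotype,
        vector = if (row$genotype == empty_vector_genotype) "empty"
                 else row$genotype,
        treatment = treatment_name, concentration = row$dose,
        conc_unit = conc_unit, replicate = row$replicate, role = "sample",
        is_reference_condition = row$dose == ref_dose,
        is_empty_vector = row$genotype == empty_vector_genotype,
        stringsAsFactors = FALSE)
    }
    plate_ts <- measure_plate(true_series, times, calib, noise,
                              n_blanks = 3, plate_id = plate_id,
                              wells = wells,
                              seed = seed + pl)
    blank_wells <- setdiff(names(plate_ts), wells)
    for (w in blank_wells) {
      map_rows[[length(map_rows) + 1]] <- data.frame(
        plate_id = plate_id, well = w, genotype = "", vector = "",
        treatment = "", concentration = NA_real_, conc_unit = "",
        replicate = 1L, role = "blank",
        is_reference_condition = FALSE, is_empty_vector = FALSE,
        stringsAsFactors = FALSE)
    }
    names(plate_ts) <- paste0(plate_id, ":", names(plate_ts))
    all_ts <- c(all_ts, plate_ts)
  }
  list(timeseries = all_ts, map = plate_map(do.call(rbind, map_rows)))
}

#' Simulate a spheroplast bursting trace
#'
#' @param params Two-phase parameters (`a1`, `tau1`, `a2`, `tau2`).
#' @param grid Times in seconds (default 0 to 5 s at 0.1 s).
#' @param noise_sd Additive Gaussian noise SD (default 0).
#' @param seed RNG seed.
#' @return List with `times` and `od650`, usable by [fit_two_phase()].
#' @export
simulate_burst_trace <- function(params, grid = seq(0, 5, by = 0.1),
                                 noise_sd = 0, seed = 1) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  y <- evaluate_two_phase(params, grid)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    y <- y + stats::rnorm(length(grid), 0, noise_sd)
  }
  list(times = grid, od650 = y)
}

#' Simulate a calibration dilution series
#'
#' Constructs recorded ODs by inverting the calibration at
#' `anchor_true * factor` for each dilution factor, optionally with
#' multiplicative noise.
#'
#' @param calib A `calibration_model`.
#' @param anchor_true True OD of the most dilute point.
#' @param factors Positive dilution factors (smallest = anchor).
#' @param noise_sd Multiplicative noise SD on recorded OD (default 0).
#' @param seed RNG seed.
#' @return Data frame with `dilution_factor`, `od_recorded`.
#' @export
simulate_dilution_series <- function(calib, anchor_true, factors,
                                     noise_sd = 0, seed = 1) {
  if (any(factors <= 0)) stop("dilution factors must be positive")
  f0 <- min(factors)
  true_od <- anchor_true * factors / f0
  rec <- invert_calibration(calib, true_od)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    rec <- rec * (1 + stats::rnorm(length(rec), 0, noise_sd))
  }
  data.frame(dilution_factor = factors, od_recorded = pmax(rec, 0))
}
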