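#' Read plate-reader time series from CSV
#'
#' Parses raw OD650 time series for a plate, either in long format (one row
#' per reading) or wide format (one column per well). Long format is the
#' canonical dialect; wide is accepted for common reader exports.
#'
#' @param path Path to a CSV file. Long dialect requires columns `plate_id`,
#'   `well`, `time_min`, `od_raw`; wide dialect requires a `time_min` column
#'   plus one numeric column per well (column name = well coordinate).
#' @param dialect Either `"long"` or `"wide"`.
#' @param plate_id Plate identifier used for the wide dialect (which carries
#'   none in the file). Ignored for long input.
#' @return A list of `well_timeseries` objects, one per well, each with
#'   elements `plate_id`, `well`, `times` (minutes, strictly increasing) and
#'   `od_raw`.
#' @export
read_plate_timeseries <- function(path, dialect = c("long", "wide"),
                                  plate_id = "plate1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "long") {
    needed <- c("plate_id", "well", "time_min", "od_raw")
    missing <- setdiff(needed, names(df))
    if (length(missing)) {
      stop("long time-series CSV is missing column(s): ",
           paste(missing, collapse = ", "))
    }
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$od_raw))))
    if (length(bad)) {
      stop("non-numeric or non-finite od_raw at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    df$od_raw <- as.numeric(df$od_raw)
    df$time_min <- as.numeric(df$time_min)
    df$well <- normalize_well(df$well)
    key <- interaction(df$plate_id, df$well, drop = TRUE)
    out <- lapply(split(df, key), function(d) {
      d <- d[order(d$time_min), , drop = FALSE]
      if (anyDuplicated(d$time_min)) {
        stop("duplicate time points for well ", d$well[1],
             " on plate ", d$plate_id[1])
      }
      well_timeseries(d$plate_id[1], d$well[1], d$time_min, d$od_raw)
    })
    names(out) <- vapply(out, function(s) paste0(s$plate_id, ":", s$well), "")
    out[order(names(out))]
  } else {
    if (!"time_min" %in% names(df)) {
      stop("wide time-series CSV is missing column: time_min")
    }
    wells <- setdiff(names(df), "time_min")
    times <- as.numeric(df$time_min)
    ord <- order(times)
    if (anyDuplicated(times)) stop("duplicate time points in wide CSV")
    out <- lapply(wells, function(w) {
      v <- suppressWarnings(as.numeric(df[[w]]))
      if (any(!is.finite(v))) {
        stop("non-numeric or non-finite od_raw in column ", w,
             " at row(s): ", paste(utils::head(which(!is.finite(v)), 5),
                                   collapse = ", "))
      }
      well_timeseries(plate_id, normalize_well(w), times[ord], v[ord])
    })
    names(out) <- vapply(out, function(s) paste0(s$plate_id, ":", s$well), "")
    out[order(names(out))]
  }
}

#' Write plate time series as long CSV
#'
#' @param series List of `well_timeseries` objects.
#' @param path Output CSV path.
#' @export
write_plate_timeseries <- function(series, path) {
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(plate_id = s$plate_id, well = s$well,
               time_min = s$times, od_raw = s$od_raw,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a single-well time series
#'
#' @param plate_id Plate identifier.
#' @param well Well coordinate (A1..H12, case-insensitive).
#' @param times Reading times in minutes, strictly increasing.
#' @param od_raw Recorded OD650 readings, same length as `times`.
#' @return A `well_timeseries` object.
#' @export
well_timeseries <- function(plate_id, well, times, od_raw) {
  times <- as.numeric(times)
  od_raw <- as.numeric(od_raw)
  if (length(times) != length(od_raw)) {
    stop("times and od_raw must have equal length")
  }
  if (length(times) < 2) stop("a well time series needs at least 2 readings")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(od_raw))) stop("od_raw must be finite")
  structure(list(plate_id = as.character(plate_id),
                 well = normalize_well(well),
                 times = times, od_raw = od_raw),
            class = "well_timeseries")
}

# A1..H12, case-insensitive in, upper-case out
normalize_well <- function(w) {
  w <- toupper(trimws(as.character(w)))
  ok <- grepl("^[A-H](1[0-2]|[1-9])$", w)
  if (any(!ok)) stop("invalid well coordinate(s): ",
                     paste(unique(w[!ok]), collapse = ", "))
  w
}

#' Read a plate map from CSV
#'
#' A plate map assigns each well its genotype/vector, treatment,
#' concentration, replicate and role (`sample` or `blank`), plus flags for
#' the reference condition of a treatment series and the empty-vector
#' control genotype.
#'
#' @param path CSV with header `well, genotype, vector, treatment,
#'   concentration, conc_unit, replicate, role, is_reference_condition,
#'   is_empty_vector` and optionally `plate_id`.
#' @return A `plate_map` object: a data frame of validated entries with an
#'   attribute `warnings` (character vector, e.g. when no blank wells exist).
#' @export
read_plate_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("well", "genotype", "vector", "treatment", "concentration",
              "conc_unit", "replicate", "role", "is_reference_condition",
              "is_empty_vector")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("plate-map CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"plate_id" %in% names(df)) df$plate_id <- "plate1"
  plate_map(df)
}

#' Construct and validate a plate map
#'
#' @param df Data frame with the plate-map columns (see [read_plate_map()]).
#' @return A validated `plate_map` data frame.
#' @export
plate_map <- function(df) {
  df$well <- normalize_well(df$well)
  if (!"plate_id" %in% names(df)) df$plate_id <- "plate1"
  df$role <- as.character(df$role)
  df$role[is.na(df$role) | df$role == ""] <- "sample"
  if (!all(df$role %in% c("sample", "blank"))) {
    stop("role must be 'sample' or 'blank'")
  }
  df$is_reference_condition <- parse_bool(df$is_reference_condition)
  df$is_empty_vector <- parse_bool(df$is_empty_vector)
  df$concentration <- as.numeric(df$concentration)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df[c("plate_id", "well")])) {
    stop("duplicate (plate_id, well) entries in plate map")
  }
  samp <- df[df$role == "sample", , drop = FALSE]
  if (any(is.na(samp$genotype) | samp$genotype == "")) {
    stop("sample well(s) without genotype: ",
         paste(samp$well[is.na(samp$genotype) | samp$genotype == ""],
               collapse = ", "))
  }
  warn <- character()
  if (!any(df$role == "blank")) {
    warn <- c(warn, "plate map has no blank wells")
  }
  # at most one reference concentration per genotype x treatment series
  if (nrow(samp)) {
    ref <- samp[samp$is_reference_condition, , drop = FALSE]
    if (nrow(ref)) {
      by <- split(ref, interaction(ref$genotype, ref$treatment, drop = TRUE))
      for (d in by) {
        if (length(unique(d$concentration)) > 1) {
          stop("genotype '", d$genotype[1], "' treatment '", d$treatment[1],
               "' flags more than one concentration as reference condition")
        }
      }
    }
  }
  structure(df, class = c("plate_map", "data.frame"), warnings = warn)
}

parse_bool <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("1", "true", "t", "yes")
  bad <- !x %in% c("1", "true", "t", "yes", "0", "false", "f", "no", "", "na")
  if (any(bad)) stop("cannot parse boolean value(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  out
}

results_columns <- c("genotype", "treatment", "concentration", "replicate",
                     "lambda", "mu", "kappa", "phi_used", "auc",
                     "delta_auc_vs_control", "rel_auc_vs_empty", "flags")

#' Write a results table to CSV
#'
#' One row per analyzed well with the extracted growth traits, the Phi used,
#' AUC and the relative-AUC statistics. Numeric fields are serialized with 6
#' significant digits; missing values become empty fields.
#'
#' @param table Data frame with columns `genotype, treatment, concentration,
#'   replicate, lambda, mu, kappa, phi_used, auc, delta_auc_vs_control,
#'   rel_auc_vs_empty, flags`.
#' @param path Output CSV path.
#' @export
write_results <- function(table, path) {
  missing <- setdiff(results_columns, names(table))
  if (length(missing)) {
    stop("results table missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- table[results_columns]
  num <- setdiff(results_columns, c("genotype", "treatment", "flags"))
  for (cn in num) {
    v <- out[[cn]]
    out[[cn]] <- ifelse(is.na(v), "", signif(as.numeric(v), 6))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return Data frame with the fixed results columns.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(results_columns, names(df))
  if (length(missing)) {
    stop("results CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  df$flags <- ifelse(is.na(df$flags), "", as.character(df$flags))
  df
}
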