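#' One-way ANOVA with Fisher's LSD versus a designated control
#'
#' Pools the within-group variance across all groups (one-way ANOVA MSE),
#' then compares each non-control group to the control with the LSD t
#' statistic `(mean_g - mean_c) / sqrt(MSE * (1/n_g + 1/n_c))` on `N - k`
#' degrees of freedom (two-sided). Comparisons are made only against the
#' control, as in screen figures where asterisks mark differences from the
#' empty-vector control; Tukey letters ([tukey_letters()]) cover all pairs.
#'
#' @param groups Named list of numeric replicate vectors (each n >= 2).
#' @param control Name of the control group.
#' @param alpha_levels Two significance thresholds for the `*` and `**`
#'   marks (default `c(0.05, 0.01)`).
#' @return Data frame per group: `group`, `mean`, `sem`, `n`,
#'   `p_vs_control` (NA for the control itself), `mark` ("", "*", "**"),
#'   plus attribute `flags`.
#' @export
anova_lsd <- function(groups, control, alpha_levels = c(0.05, 0.01)) {
  check_groups(groups)
  if (!control %in% names(groups)) stop("control group '", control,
                                        "' not found")
  ns <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  k <- length(groups); N <- sum(ns)
  df_err <- N - k
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0)) / df_err
  flags <- character()
  p <- vapply(names(groups), function(g) {
    if (g == control) return(NA_real_)
    se <- sqrt(mse * (1 / ns[[g]] + 1 / ns[[control]]))
    if (se == 0) {
      if (means[[g]] == means[[control]]) return(1)
      return(0)  # degenerate: zero pooled variance, unequal means
    }
    tval <- (means[[g]] - means[[control]]) / se
    2 * stats::pt(-abs(tval), df_err)
  }, 0)
  if (mse == 0 && any(p == 0, na.rm = TRUE)) {
    flags <- c(flags, "degenerate_variance")
  }
  mark <- ifelse(is.na(p), "",
                 ifelse(p < alpha_levels[2], "**",
                        ifelse(p < alpha_levels[1], "*", "")))
  out <- data.frame(group = names(groups), mean = unname(means),
                    sem = unname(vapply(groups, function(v)
                      stats::sd(v) / sqrt(length(v)), 0)),
                    n = unname(ns), p_vs_control = unname(p),
                    mark = unname(mark), stringsAsFactors = FALSE)
  attr(out, "flags") <- flags
  out
}

check_groups <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  for (g in names(groups)) {
    v <- groups[[g]]
    if (length(v) < 2) stop("group '", g, "' has fewer than 2 replicates")
    if (any(!is.finite(v))) stop("group '", g, "' has non-finite values")
  }
}

#' All-pairs Tukey HSD p-value matrix
#'
#' Studentized-range p-values for every pair of groups using the pooled
#' one-way ANOVA MSE; unbalanced designs use the Tukey-Kramer standard
#' error `sqrt(MSE/2 * (1/n_i + 1/n_j))`.
#'
#' @param groups Named list of numeric replicate vectors.
#' @return Symmetric matrix of adjusted p-values (diagonal 1).
#' @export
tukey_p_matrix <- function(groups) {
  check_groups(groups)
  ns <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  k <- length(groups); N <- sum(ns)
  df_err <- N - k
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0)) / df_err
  P <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- if (se == 0) {
      if (means[i] == means[j]) 0 else Inf
    } else abs(means[i] - means[j]) / se
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
    P[i, j] <- P[j, i] <- p
  }
  P
}

#' Compact letter display from Tukey HSD
#'
#' Assigns letters so that two groups share a letter if and only if their
#' Tukey-adjusted pairwise p-value is >= `alpha` (insert-and-absorb
#' algorithm on groups sorted by descending mean; redundant letter columns
#' are absorbed to keep the letter set minimal).
#'
#' @param groups Named list of numeric replicate vectors (each n >= 2).
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter strings, in input group order.
#' @export
tukey_letters <- function(groups, alpha = 0.05) {
  P <- tukey_p_matrix(groups)
  k <- nrow(P)
  ord <- order(-vapply(groups, mean, 0))
  # membership matrix: rows = groups in `ord` order, columns = letters
  M <- matrix(TRUE, nrow = k, ncol = 1)
  absorb <- function(M) {
    drop <- rep(FALSE, ncol(M))
    for (a in seq_len(ncol(M))) {
      for (b in seq_len(ncol(M))) {
        if (a == b || drop[b]) next
        subset_ab <- all(M[, a] <= M[, b])
        proper <- subset_ab && any(M[, a] < M[, b])
        duplicate_later <- subset_ab && !proper && a > b
        if (proper || duplicate_later) { drop[a] <- TRUE; break }
      }
    }
    M[, !drop, drop = FALSE]
  }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    gi <- ord[i]; gj <- ord[j]
    if (P[gi, gj] < alpha) {
      cols <- which(M[i, ] & M[j, ])
      if (length(cols)) {
        # split every letter containing both: one copy loses i, one loses j
        new_cols <- do.call(cbind, lapply(cols, function(col) {
          n1 <- M[, col]; n1[j] <- FALSE
          n2 <- M[, col]; n2[i] <- FALSE
          cbind(n1, n2)
        }))
        M <- absorb(cbind(M[, -cols, drop = FALSE], new_cols))
      }
    }
  }
  # order letters by first (highest-mean) member for stable display
  first <- apply(M, 2, function(cl) which(cl)[1])
  M <- M[, order(first), drop = FALSE]
  letters_used <- letters[seq_len(ncol(M))]
  lab_sorted <- apply(M, 1, function(row)
    paste0(letters_used[row], collapse = ""))
  out <- character(k)
  out[ord] <- lab_sorted
  names(out) <- names(groups)
  out
}

#' Two-sample t-test p-value
#'
#' Student's pooled-variance test by default; Welch's unpooled optional.
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @param pooled Use pooled variance (default TRUE).
#' @return Two-sided p-value.
#' @export
two_sample_t <- function(a, b, pooled = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = pooled)$p.value
}

#' Normalize fluorescence to culture density
#'
#' Expresses a GFP signal as fluorescence units per cell at OD 1
#' (`signal / culture_od`), the scale on which heterologous protein
#' abundance is compared across lines.
#'
#' @param gfp_signal Fluorescence units.
#' @param culture_od Corrected culture OD (> 0).
#' @return Units per cell-OD1.
#' @export
normalize_fluorescence <- function(gfp_signal, culture_od) {
  if (any(culture_od <= 0)) stop("culture OD must be positive")
  gfp_signal / culture_od
}

#' Percent of the group mean, rounded to integer percent
#'
#' Expresses each value as a percentage of the group average (e.g. one
#' line's normalized GFP signal against the mean of the whole protein
#' family), rounded to the nearest integer percent for reporting.
#'
#' @param values Numeric vector.
#' @param group_mean Mean to compare against (default: mean of `values`;
#'   pass the family-wide mean when `values` is a subset).
#' @return Integer percents.
#' @export
percent_of_group_mean <- function(values, group_mean = mean(values)) {
  if (group_mean <= 0) stop("group mean must be positive")
  round(100 * values / group_mean)
}

#' Fold change
#'
#' @param before Baseline value (> 0).
#' @param after Value after treatment.
#' @return `after / before`.
#' @export
fold_change <- function(before, after) {
  if (any(before <= 0)) stop("baseline must be positive")
  after / before
}
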