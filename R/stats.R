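# Statistical layer: condition summaries (mean +/- SEM), unpaired t-tests
# with Holm-Sidak step-down correction across a comparison family, and
# two-sample Kolmogorov-Smirnov tests for distribution-valued metrics.

#' Holm-Sidak step-down adjustment of p-values
#'
#' Sort the m raw p-values ascending, set `adj_(i) = 1 - (1 - p_(i))^(m - i
#' + 1)`, enforce a running maximum, and restore the input order. `NA`
#' entries are excluded from m and returned as `NA`.
#'
#' @param p Raw p-values.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_sidak <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(out)
  o <- order(p[ok])
  ps <- p[ok][o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out[ok[o]] <- adj
  out
}

#' Unpaired t-tests with Holm-Sidak correction across a family
#'
#' Runs a two-sided unpaired t-test for every comparison in the family and
#' adjusts the p-values with the Holm-Sidak step-down method. Welch
#' (unequal-variance) tests are the default; set `var_equal = TRUE` for the
#' pooled-variance test. Comparisons with fewer than 2 observations in
#' either group are flagged and excluded from the family size m.
#'
#' @param comparisons Named list; each element a list/data frame with
#'   elements `a` and `b`, the two samples (replicate values, typically one
#'   per independent experiment).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return A data frame of class `sc_comparison` with one row per
#'   comparison: group means and SEMs, `n_a`, `n_b`, `t`, `p_raw`, `p_adj`,
#'   `test`, `flag`.
#' @export
holm_sidak_ttests <- function(comparisons, var_equal = FALSE) {
  stopifnot(is.list(comparisons), length(comparisons) > 0)
  nm <- names(comparisons)
  if (is.null(nm)) nm <- paste0("cmp", seq_along(comparisons))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(seq_along(comparisons), function(i) {
    a <- as.numeric(comparisons[[i]]$a)
    b <- as.numeric(comparisons[[i]]$b)
    ok <- length(a) >= 2 && length(b) >= 2
    tt <- if (ok) stats::t.test(a, b, var.equal = var_equal) else NULL
    data.frame(comparison = nm[i],
               mean_a = mean(a), sem_a = if (length(a) > 1) sem(a) else NA,
               mean_b = mean(b), sem_b = if (length(b) > 1) sem(b) else NA,
               n_a = length(a), n_b = length(b),
               t = if (ok) unname(tt$statistic) else NA_real_,
               p_raw = if (ok) tt$p.value else NA_real_,
               flag = if (ok) "" else "insufficient_n",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_sidak(out$p_raw)
  out$test <- if (var_equal) "t" else "t_welch"
  class(out) <- c("sc_comparison", "data.frame")
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS statistic `D = sup |ECDF_a - ECDF_b|` with the
#' asymptotic p-value (no exact small-sample enumeration; ties permitted).
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @return A one-row data frame of class `sc_comparison`: `D`, `p_raw`,
#'   `n_a`, `n_b`, `test = "KS"`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  out <- data.frame(D = unname(kt$statistic), p_raw = kt$p.value,
                    n_a = length(sample_a), n_b = length(sample_b),
                    test = "KS", stringsAsFactors = FALSE)
  class(out) <- c("sc_comparison", "data.frame")
  out
}

#' Mean +/- SEM summary per condition
#'
#' @param values Named list of replicate value vectors (one element per
#'   condition), or a data frame with `condition` and `value` columns.
#' @return Data frame `condition`, `n`, `mean`, `sem` (NA and flagged
#'   `undefined_sem` when n = 1).
#' @export
condition_summary <- function(values) {
  if (is.data.frame(values))
    values <- split(values$value, values$condition)
  stopifnot(length(values) > 0)
  if (any(!lengths(values)))
    stop("every condition needs at least one replicate")
  data.frame(condition = names(values),
             n = unname(lengths(values)),
             mean = vapply(values, mean, 0),
             sem = vapply(values, function(x)
               if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_, 0),
             flag = ifelse(lengths(values) > 1, "", "undefined_sem"),
             row.names = NULL, stringsAsFactors = FALSE)
}
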