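#' Summary statistics of ROI measurements
#'
#' Median, range, mean and standard deviation of a measurement vector, the
#' per-group summary used in the results tables (median with range in
#' parentheses). The median of an even-length vector is the midpoint of the
#' two central order statistics; the sd of a single value is 0.
#'
#' @param values non-empty numeric vector.
#' @return List with `median`, `min`, `max`, `mean`, `sd`, `n`.
#' @export
summarize_ratios <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("cannot summarize an empty vector")
  if (!all(is.finite(values))) stop("values must be finite")
  list(median = stats::median(values), min = min(values), max = max(values),
       mean = mean(values),
       sd = if (length(values) == 1L) 0 else stats::sd(values),
       n = length(values))
}

#' Two-sample Wilcoxon rank-sum test (with a paired option)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum comparison of two measurement
#' groups. The exact null distribution is used when the combined sample size
#' is at most `exact_limit` and there are no ties; otherwise the normal
#' approximation with midranks and continuity/tie correction. If every value
#' in both groups is identical the test is degenerate: `p = 1` is returned
#' with a warning and `degenerate = TRUE`.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param exact_limit combined-size threshold for the exact distribution
#'   (default 12).
#' @param paired if `TRUE`, the Wilcoxon signed-rank test on paired
#'   differences (groups must have equal length).
#' @return An object of class `rank_sum_result`: list with `statistic`,
#'   `p_value`, `method`, `n1`, `n2`, `degenerate`.
#' @export
rank_sum_test <- function(group_a, group_b, exact_limit = 12, paired = FALSE) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  if (!all(is.finite(c(a, b)))) stop("group values must be finite")
  res <- function(stat, p, method, degenerate = FALSE) {
    structure(list(statistic = unname(stat), p_value = min(1, p),
                   method = method, n1 = length(a), n2 = length(b),
                   degenerate = degenerate),
              class = "rank_sum_result")
  }
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical in both groups; test is degenerate")
    return(res(if (paired) 0 else length(a) * length(b) / 2, 1,
               "degenerate (all values identical)", degenerate = TRUE))
  }
  if (paired) {
    if (length(a) != length(b)) stop("paired test requires equal group sizes")
    d <- a - b
    exact <- length(d) <= exact_limit && !any(d == 0) &&
      !any(duplicated(abs(d)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = exact, correct = TRUE))
    return(res(wt$statistic, wt$p.value,
               paste0("Wilcoxon signed-rank, ",
                      if (exact) "exact" else "normal approximation")))
  }
  exact <- (length(a) + length(b)) <= exact_limit && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  res(wt$statistic, wt$p.value,
      paste0("Wilcoxon rank-sum, ",
             if (exact) "exact" else "normal approximation (tie-corrected)"))
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("%s: statistic=%.6g, p=%.4g (n1=%d, n2=%d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

validate_ratio_table <- function(table) {
  need <- c("subject_id", "roi_name", "role", "replicate_index", "ratio")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L)
    stop("ratio table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(table$ratio))) stop("ratios must be finite")
  if (any(table$replicate_index < 1)) stop("replicate_index must be >= 1")
  table
}

#' Compare two measurement roles across subjects
#'
#' Replicated measurements are first averaged within subject and role (the
#' "average of three measurements" protocol), so each subject contributes one
#' value per role and pseudo-replication is avoided; the per-subject means are
#' then compared with [rank_sum_test()] and summarized per group.
#'
#' @param table `data.frame` with columns `subject_id`, `roi_name`, `role`,
#'   `replicate_index`, `ratio` (e.g. from [phantom_ratio_table()]).
#' @param role_a,role_b roles to compare (e.g. `"probe"` vs `"background"`).
#' @inheritParams rank_sum_test
#' @return List with `test` (a `rank_sum_result`), `summary_a`, `summary_b`
#'   (from [summarize_ratios()]) and `subject_means` (the aggregated
#'   per-subject data).
#' @export
compare_groups <- function(table, role_a = "probe", role_b = "background",
                           exact_limit = 12, paired = FALSE) {
  table <- validate_ratio_table(table)
  for (r in c(role_a, role_b))
    if (!any(table$role == r))
      stop(sprintf("role '%s' not present in table (roles: %s)", r,
                   paste(unique(table$role), collapse = ", ")))
  sub <- table[table$role %in% c(role_a, role_b), ]
  agg <- stats::aggregate(ratio ~ subject_id + role, data = sub, FUN = mean)
  va <- agg$ratio[agg$role == role_a]
  vb <- agg$ratio[agg$role == role_b]
  list(test = rank_sum_test(va, vb, exact_limit = exact_limit,
                            paired = paired),
       summary_a = summarize_ratios(va), summary_b = summarize_ratios(vb),
       subject_means = agg)
}

#' Read/write ratio tables and test reports
#'
#' CSV round trip of the measurement table and a JSON report of a group
#' comparison (`method`, `statistic`, `p_value`, `n1`, `n2`, medians and
#' ranges).
#'
#' @param table a ratio table `data.frame`.
#' @param path file path.
#' @export
write_ratio_table <- function(table, path) {
  utils::write.csv(validate_ratio_table(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratio_table
#' @export
read_ratio_table <- function(path) {
  validate_ratio_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname write_ratio_table
#' @param comparison result of [compare_groups()].
#' @param roles character vector of the two role names compared.
#' @export
write_test_report <- function(comparison, path, roles = c("probe", "background")) {
  rep <- list(method = comparison$test$method,
              statistic = comparison$test$statistic,
              p_value = comparison$test$p_value,
              n1 = comparison$test$n1, n2 = comparison$test$n2,
              groups = stats::setNames(list(
                comparison$summary_a[c("median", "min", "max", "mean", "sd", "n")],
                comparison$summary_b[c("median", "min", "max", "mean", "sd", "n")]),
                roles))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
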