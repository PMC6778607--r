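#' Descriptive statistics for one variable
#'
#' Mean, sample standard deviation (n-1 denominator), median and
#' interquartile range (Q3 - Q1 with linearly interpolated quantiles,
#' `stats::quantile` type 7 -- the common statistical-package default).
#'
#' @param values Numeric vector, length >= 2.
#' @return A list with `mean`, `sd`, `median`, `iqr`, `n`.
#' @export
describe <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values)) {
    stop("describe needs at least 2 non-missing values")
  }
  list(mean = mean(values),
       sd = stats::sd(values),
       median = stats::median(values),
       iqr = unname(stats::quantile(values, 0.75) - stats::quantile(values, 0.25)),
       n = length(values))
}

#' Pearson correlation with two-tailed significance
#'
#' Product-moment correlation between two vectors, with the two-tailed p
#' value from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against the t
#' distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return A list with `r`, `p` (two-tailed) and `n`.
#' @examples
#' pearson(1:10, (1:10)^2)
#' @export
pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("pearson needs at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("pearson does not accept missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-tailed p value for a reported correlation coefficient
#'
#' Recovers the significance of a Pearson r at sample size n via the t
#' transform -- useful for checking the internal consistency of published
#' correlation tables, where r and p are printed but the raw data are not
#' available.
#'
#' @param r Correlation coefficient, `|r| < 1`.
#' @param n Sample size, n >= 3.
#' @return Two-tailed p value.
#' @examples
#' pearson_p_from_r(0.596, 17)  # 0.0116 -> prints as 0.012
#' @export
pearson_p_from_r <- function(r, n) {
  if (abs(r) >= 1) stop("|r| must be < 1")
  if (n < 3) stop("n must be >= 3")
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
}

table3_variables <- c("incorrect_choice_cost", "expected_value", "utility",
                      "opened_fraction", "correct_pct", "choice_quality")

#' Cohort summary tables
#'
#' Builds the three standard cohort summaries from a per-subject metrics
#' table (see [cohort_metrics()]):
#'
#' * `table1` -- descriptives of search and accuracy (opened boxes,
#'   opened fraction, mean opened per round, correct/wrong/no-response
#'   counts, percent correct);
#' * `table2` -- descriptives of the economics (expected value, utility,
#'   choice quality);
#' * `table3` -- the Pearson correlation matrix, with two-tailed p values
#'   and significance stars (`*` p < 0.05, `**` p < 0.01), over
#'   incorrect-choice cost, expected value, utility, opened fraction,
#'   percent correct and choice quality.
#'
#' A variable that is constant across subjects yields `NA` correlation
#' cells (undefined) rather than an error.
#'
#' @param metrics Data.frame from [cohort_metrics()], >= 3 rows.
#' @return An object of class `mlq_cohort_tables`: a list with `table1`
#'   and `table2` (data.frames of descriptives) and `table3` (list with
#'   `variables`, `r`, `p`, `stars`, `n`).
#' @export
build_tables <- function(metrics) {
  if (!is.data.frame(metrics)) stop("metrics must be a data.frame")
  if (nrow(metrics) < 3) {
    stop("insufficient data: cohort tables need at least 3 subjects, got ",
         nrow(metrics))
  }
  describe_rows <- function(vars) {
    do.call(rbind, lapply(vars, function(v) {
      d <- describe(metrics[[v]])
      data.frame(variable = v, mean = d$mean, sd = d$sd, median = d$median,
                 iqr = d$iqr, n = d$n, stringsAsFactors = FALSE)
    }))
  }
  table1 <- describe_rows(c("opened_total", "opened_fraction",
                            "opened_per_round_mean", "n_correct", "n_wrong",
                            "n_noresponse", "correct_pct"))
  table2 <- describe_rows(c("expected_value", "utility", "choice_quality"))

  vars <- table3_variables
  k <- length(vars)
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    r[i, i] <- 1
    p[i, i] <- 0
    for (j in seq_len(k)) {
      if (j >= i) next
      x <- metrics[[vars[i]]]; y <- metrics[[vars[j]]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        ct <- pearson(x[ok], y[ok])
        r[i, j] <- r[j, i] <- ct$r
        p[i, j] <- p[j, i] <- ct$p
      }
    }
  }
  stars <- matrix("", k, k, dimnames = list(vars, vars))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  diag(stars) <- ""
  out <- list(table1 = table1, table2 = table2,
              table3 = list(variables = vars, r = r, p = p, stars = stars,
                            n = nrow(metrics)))
  class(out) <- "mlq_cohort_tables"
  out
}

format_p <- function(p) {
  ifelse(is.na(p), "NA", ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p)))
}

#' Render cohort tables as aligned plain text
#'
#' @param tables An `mlq_cohort_tables` from [build_tables()].
#' @return A character vector of lines.
#' @export
format_cohort_tables <- function(tables) {
  stopifnot(inherits(tables, "mlq_cohort_tables"))
  fmt_desc <- function(df, title) {
    rows <- sprintf("%-24s %14.2f (%.2f) %14.2f (%.2f)",
                    df$variable, df$mean, df$sd, df$median, df$iqr)
    c(title,
      sprintf("%-24s %22s %22s", "variable", "mean (sd)", "median (IQR)"),
      rows, "")
  }
  t3 <- tables$table3
  k <- length(t3$variables)
  cell <- function(i, j) {
    if (is.na(t3$r[i, j])) return("undef")
    sprintf("%.3f%s", t3$r[i, j], t3$stars[i, j])
  }
  header <- paste(c(sprintf("%-24s", ""),
                    sprintf("%12s", abbreviate(t3$variables, 12))), collapse = " ")
  rows <- character(0)
  for (i in seq_len(k)) {
    rcells <- vapply(seq_len(k), function(j) sprintf("%12s", cell(i, j)), "")
    pcells <- vapply(seq_len(k), function(j) {
      if (i == j || is.na(t3$p[i, j])) sprintf("%12s", "")
      else sprintf("%12s", format_p(t3$p[i, j]))
    }, "")
    rows <- c(rows,
              paste(c(sprintf("%-24s", t3$variables[i]), rcells), collapse = " "),
              paste(c(sprintf("%-24s", "  sig. (2-tailed)"), pcells), collapse = " "))
  }
  c(fmt_desc(tables$table1, "Table 1. Search and accuracy of choices"),
    fmt_desc(tables$table2, "Table 2. Cost-based outcomes"),
    sprintf("Table 3. Pearson correlations (N = %d)", t3$n),
    header, rows,
    "* p < 0.05, ** p < 0.01", "")
}

#' @export
print.mlq_cohort_tables <- function(x, ...) {
  cat(format_cohort_tables(x), sep = "\n")
  invisible(x)
}

#' Write cohort tables to files
#'
#' Writes each table in delimited form (`table1.csv`, `table2.csv`,
#' `table3_r.csv`, `table3_p.csv`) plus an aligned plain-text rendering
#' (`tables.txt`) into a directory.
#'
#' @param tables An `mlq_cohort_tables`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "mlq_cohort_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tables$table1, file.path(dir, "table1.csv"), row.names = FALSE)
  utils::write.csv(tables$table2, file.path(dir, "table2.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(tables$table3$r), file.path(dir, "table3_r.csv"))
  utils::write.csv(as.data.frame(tables$table3$p), file.path(dir, "table3_p.csv"))
  writeLines(format_cohort_tables(tables), file.path(dir, "tables.txt"))
  invisible(dir)
}
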