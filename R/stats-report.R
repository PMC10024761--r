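# Statistical tests, behavioral indices and cohort report assembly.
# Tests are delegated to the standard routines in stats::; the wrappers
# fix the conventions used throughout the pipeline (two-sided p-values,
# point-probability Fisher, tie-corrected ranks) and return a uniform
# result structure.

test_result <- function(statistic, p_value, method, n,
                        extra = NULL) {
  out <- c(list(statistic = statistic, p_value = p_value,
                method = method, n = n, tails = "two-sided"), extra)
  class(out) <- "test_result"
  out
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: p = %.4g (n = %s)\n", x$method, x$p_value,
              paste(x$n, collapse = "+")))
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2 x 2 table
#'
#' The two-sided p-value follows the point-probability convention: the
#' hypergeometric probabilities of all tables with the observed margins
#' whose point probability does not exceed that of the observed table
#' are summed. A zero margin returns p = 1 with a `degenerate` flag.
#'
#' @param table 2 x 2 matrix (or 4-vector, row-wise) of non-negative
#'   integer counts.
#' @return A `test_result` with the odds-ratio estimate as `statistic`
#'   and a `degenerate` flag.
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, nrow = 2, byrow = TRUE)
  if (any(dim(table) != 2L)) stop_config("table", "must be 2 x 2")
  if (any(table < 0) || any(table != round(table))) {
    stop_config("table", "counts must be non-negative integers")
  }
  n <- sum(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(test_result(NA_real_, 1.0, "Fisher's exact test", n,
                       extra = list(degenerate = TRUE)))
  }
  ft <- stats::fisher.test(table)
  test_result(unname(ft$estimate), ft$p.value, "Fisher's exact test", n,
              extra = list(degenerate = FALSE))
}

#' Pearson chi-square test on an r x c table
#'
#' Pearson statistic with `(r-1)(c-1)` degrees of freedom, no continuity
#' correction. Zero-margin rows/columns are dropped with a warning, and
#' a `low_expected` flag marks expected counts below 5.
#'
#' @param table r x c matrix of non-negative counts.
#' @return A `test_result` with `expected` counts, `df` and
#'   `low_expected` flag.
#' @export
chi_square <- function(table) {
  if (!is.matrix(table)) stop_config("table", "must be a matrix")
  drop_r <- rowSums(table) == 0
  drop_c <- colSums(table) == 0
  if (any(drop_r) || any(drop_c)) {
    warning("dropping zero-margin rows/columns", call. = FALSE)
    table <- table[!drop_r, !drop_c, drop = FALSE]
  }
  if (any(dim(table) < 2L)) {
    stop_config("table", "needs at least 2 x 2 after dropping zero margins")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result(unname(ct$statistic), ct$p.value, "Chi-square test",
              sum(table),
              extra = list(expected = ct$expected,
                           df = unname(ct$parameter),
                           low_expected = any(ct$expected < 5)))
}

#' Rank-based two-sided tests
#'
#' Mann-Whitney (two independent groups), Wilcoxon signed-rank (paired)
#' or Kruskal-Wallis (two or more groups), all two-sided with
#' tie-corrected statistics. Two-group tests use exact enumeration for
#' total n of 12 or fewer (without ties) and the normal approximation
#' with continuity correction otherwise.
#'
#' @param groups List of numeric vectors.
#' @param method `"mann_whitney"`, `"kruskal_wallis"` or
#'   `"wilcoxon_signed"`.
#' @return A `test_result`.
#' @export
rank_tests <- function(groups, method = c("mann_whitney",
                                          "kruskal_wallis",
                                          "wilcoxon_signed")) {
  method <- match.arg(method)
  if (any(vapply(groups, length, 1L) == 0L)) {
    stop("empty group supplied", call. = FALSE)
  }
  n <- vapply(groups, length, 1L)
  if (method == "kruskal_wallis") {
    kt <- stats::kruskal.test(groups)
    return(test_result(unname(kt$statistic), kt$p.value,
                       "Kruskal-Wallis test", n,
                       extra = list(df = unname(kt$parameter))))
  }
  if (length(groups) != 2L) {
    stop("two groups required for two-sample rank tests", call. = FALSE)
  }
  exact <- sum(n) <= 12L
  paired <- method == "wilcoxon_signed"
  wt <- suppressWarnings(
    stats::wilcox.test(groups[[1]], groups[[2]], paired = paired,
                       exact = exact, correct = TRUE))
  test_result(unname(wt$statistic), wt$p.value,
              if (paired) "Wilcoxon signed-rank test"
              else "Mann-Whitney test", n)
}

#' Pearson correlation with a two-tailed t test
#'
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors (length >= 3, non-constant).
#' @return A `test_result` with `statistic_r` (the correlation), the t
#'   `statistic`, and `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need n >= 3 paired observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  test_result(unname(ct$statistic), ct$p.value, "Pearson correlation",
              length(x),
              extra = list(statistic_r = unname(ct$estimate)))
}

#' Object-exploration preference and discrimination indices
#'
#' Preference = `t_new / (t_new + t_fam)`; discrimination =
#' `(t_new - t_fam) / (t_new + t_fam)`. The identity
#' `discrimination = 2 x preference - 1` holds exactly.
#'
#' @param t_new,t_fam Exploration times (s, >= 0); their sum must be
#'   positive.
#' @return List with `preference` and `discrimination`.
#' @export
behavior_indices <- function(t_new, t_fam) {
  if (t_new < 0 || t_fam < 0) {
    stop_config("t_new/t_fam", "times must be non-negative")
  }
  total <- t_new + t_fam
  if (total <= 0) {
    stop("undefined index: zero total exploration time", call. = FALSE)
  }
  list(preference = t_new / total,
       discrimination = (t_new - t_fam) / total)
}

#' Assemble a cohort report
#'
#' Computes group descriptives (mean +/- SEM per measure and group, with
#' n the number of labelled independent units) and, when two or more
#' groups are present, a rank test per measure (Mann-Whitney for two
#' groups, Kruskal-Wallis otherwise).
#'
#' @param data Long-format data frame with columns `unit_id`, `group`,
#'   `measure`, `value`.
#' @return A `cohort_report` list: `descriptives` data frame
#'   (`measure`, `group`, `n`, `mean`, `sem`) and `tests` (named list of
#'   `test_result`s per measure; empty for a single group).
#' @export
build_report <- function(data) {
  req <- c("unit_id", "group", "measure", "value")
  if (!all(req %in% names(data)) || nrow(data) == 0L) {
    stop_config("data", paste("needs >= 1 row with columns",
                              paste(req, collapse = ", ")))
  }
  desc <- do.call(rbind, lapply(split(data, data[c("measure", "group")],
                                      drop = TRUE), function(d) {
    data.frame(measure = d$measure[1], group = d$group[1],
               n = nrow(d), mean = mean(d$value),
               sem = stats::sd(d$value) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(desc) <- NULL
  tests <- list()
  groups <- unique(data$group)
  if (length(groups) >= 2L) {
    for (msr in unique(data$measure)) {
      d <- data[data$measure == msr, ]
      gl <- lapply(groups, function(g) d$value[d$group == g])
      gl <- gl[vapply(gl, length, 1L) > 0]
      if (length(gl) < 2L) next
      tests[[msr]] <- rank_tests(gl, if (length(gl) == 2L) "mann_whitney"
                                 else "kruskal_wallis")
    }
  }
  structure(list(descriptives = desc, tests = tests),
            class = "cohort_report")
}
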