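# Adaptive two-group comparison: Shapiro-Wilk normality and Levene
# variance checks route each metric to Student's t, Welch's t, or the
# Mann-Whitney U test; Benjamini-Hochberg FDR for families of p-values.

#' Route a two-group comparison to a test
#'
#' Normality gates first: if either group is non-normal the Mann-Whitney U
#' test is used regardless of the variance flag; two normal groups use
#' Student's t when variances are equal and Welch's t otherwise.
#'
#' @param normal_a,normal_b logical normality flags per group.
#' @param equal_var logical equal-variance flag.
#' @return `"student_t"`, `"welch_t"` or `"mann_whitney"`.
#' @export
#' @examples
#' route_test(TRUE, TRUE, TRUE)    # student_t
#' route_test(FALSE, TRUE, TRUE)   # mann_whitney
#' route_test(TRUE, TRUE, FALSE)   # welch_t
route_test <- function(normal_a, normal_b, equal_var) {
  stopifnot(is.logical(normal_a), is.logical(normal_b), is.logical(equal_var))
  if (!normal_a || !normal_b) return("mann_whitney")
  if (equal_var) "student_t" else "welch_t"
}

shapiro_p <- function(x) {
  # constant data has no defined normality; treat as non-normal
  if (length(unique(x)) == 1L) return(0)
  stats::shapiro.test(x)$p.value
}

#' Compare two groups with the adaptive procedure
#'
#' Applies Shapiro-Wilk to each group and Levene's test (mean-centered)
#' across groups at `alpha_assumption`, routes via [route_test()], and
#' returns the routed test's two-sided p-value with group means and SEMs.
#' Missing values are dropped per group (the dropped count is reported).
#' The Mann-Whitney route uses exact enumeration when both groups have at
#' most 8 observations and no ties, and the tie-corrected normal
#' approximation otherwise.
#'
#' @param a,b numeric samples (missing values allowed).
#' @param alpha_assumption significance level for the assumption checks
#'   (default 0.05).
#' @return object of class `group_comparison`: list with `test_name`,
#'   `statistic`, `p_value`, `mean_a`, `mean_b`, `sem_a`, `sem_b`, `n_a`,
#'   `n_b`, `n_dropped`, `shapiro_p_a`, `shapiro_p_b`, `levene_p`.
#' @export
#' @examples
#' set.seed(1)
#' compare_groups(rnorm(12), rnorm(12, 1))
compare_groups <- function(a, b, alpha_assumption = 0.05) {
  n_dropped <- sum(is.na(a)) + sum(is.na(b))
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("need at least 3 non-missing values per group")
  }
  if (length(unique(a)) == 1L && length(unique(b)) == 1L && a[1] == b[1]) {
    stop("both groups are constant and identical; no comparison possible")
  }
  sw_a <- shapiro_p(a)
  sw_b <- shapiro_p(b)
  lev <- car::leveneTest(
    c(a, b), factor(rep(c("a", "b"), c(length(a), length(b)))),
    center = mean
  )
  lev_p <- lev[["Pr(>F)"]][1]
  test <- route_test(sw_a > alpha_assumption, sw_b > alpha_assumption,
                     lev_p > alpha_assumption)
  if (test == "mann_whitney") {
    exact <- max(length(a), length(b)) <= 8 &&
      !any(duplicated(c(a, b)))
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
  } else {
    ht <- stats::t.test(a, b, var.equal = (test == "student_t"))
  }
  structure(list(
    test_name = test,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    mean_a = mean(a), mean_b = mean(b),
    sem_a = stats::sd(a) / sqrt(length(a)),
    sem_b = stats::sd(b) / sqrt(length(b)),
    n_a = length(a), n_b = length(b), n_dropped = n_dropped,
    shapiro_p_a = sw_a, shapiro_p_b = sw_b, levene_p = lev_p
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  cat(sprintf("  group a: %.4g +/- %.4g (n = %d)\n", x$mean_a, x$sem_a, x$n_a))
  cat(sprintf("  group b: %.4g +/- %.4g (n = %d)\n", x$mean_b, x$sem_b, x$n_b))
  cat(sprintf("  routing: Shapiro p = %.3g / %.3g, Levene p = %.3g%s\n",
              x$shapiro_p_a, x$shapiro_p_b, x$levene_p,
              if (x$n_dropped) sprintf(", %d missing dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: on sorted p-values,
#' `q(i) = min over j >= i of p(j) * m / j`, mapped back to input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order; `q >= p`, bounded by 1.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Compare every metric of a profile table between two groups
#'
#' Runs [compare_groups()] per metric column and optionally applies
#' [bh_fdr()] across metrics.
#'
#' @param profiles data frame with a group column and metric columns.
#' @param group_col name of the grouping column (two levels).
#' @param metrics metric column names; default all numeric columns except
#'   identifiers.
#' @param fdr apply BH across metrics (default `FALSE`, matching the
#'   convention of correcting only within correlation families).
#' @param alpha_assumption passed to [compare_groups()].
#' @return data frame: one row per metric with test name, statistic, p
#'   (and q when `fdr`), group means and SEMs, and group sizes.
#' @export
compare_profiles <- function(profiles, group_col = "group", metrics = NULL,
                             fdr = FALSE, alpha_assumption = 0.05) {
  stopifnot(group_col %in% names(profiles))
  g <- factor(profiles[[group_col]])
  if (nlevels(g) != 2) stop("grouping column must have exactly two levels")
  if (is.null(metrics)) {
    metrics <- setdiff(names(profiles)[vapply(profiles, is.numeric, TRUE)],
                       c(group_col, "animal"))
  }
  rows <- lapply(metrics, function(m) {
    res <- tryCatch(
      compare_groups(profiles[[m]][g == levels(g)[1]],
                     profiles[[m]][g == levels(g)[2]],
                     alpha_assumption = alpha_assumption),
      error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(metric = m, test = NA_character_,
                        statistic = NA_real_, p = NA_real_,
                        mean_a = NA_real_, sem_a = NA_real_,
                        mean_b = NA_real_, sem_b = NA_real_,
                        n_a = NA_integer_, n_b = NA_integer_))
    }
    data.frame(metric = m, test = res$test_name, statistic = res$statistic,
               p = res$p_value, mean_a = res$mean_a, sem_a = res$sem_a,
               mean_b = res$mean_b, sem_b = res$sem_b,
               n_a = res$n_a, n_b = res$n_b)
  })
  out <- do.call(rbind, rows)
  if (fdr) out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}
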