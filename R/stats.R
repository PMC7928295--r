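as_2x2 <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) stop("a 2x2 table is required", call. = FALSE)
  if (any(x < 0) || any(x != round(x))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' Cross-product odds ratio with Woolf confidence interval
#'
#' For a 2x2 table with cells a, b (top row) and c, d (bottom row) the odds
#' ratio is (a*d)/(b*c). If any cell is zero the Haldane-Anscombe correction
#' (+0.5 to every cell) is applied before the ratio and interval are computed,
#' and the result is flagged. The 95% interval is the Woolf logit interval
#' exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' @param x A 2x2 matrix (or object coercible to one) of counts.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`, `corrected`
#'   (whether the Haldane-Anscombe correction was applied).
#' @examples
#' odds_ratio(matrix(c(242, 735, 159, 626), nrow = 2, byrow = TRUE))
#' @export
odds_ratio <- function(x) {
  x <- as_2x2(x)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("odds ratio undefined: a row or column of the 2x2 table is all zero",
         call. = FALSE)
  }
  corrected <- any(x == 0)
  if (corrected) x <- x + 0.5
  est <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  se <- sqrt(sum(1 / x))
  tibble::tibble(
    estimate = est,
    conf.low = exp(log(est) - 1.959964 * se),
    conf.high = exp(log(est) + 1.959964 * se),
    corrected = corrected
  )
}

#' Pearson chi-square test for a contingency table
#'
#' Computes the Pearson statistic sum((O - E)^2 / E) with
#' dof = (r - 1) * (c - 1) and an upper-tail chi-square p-value. For 2x2
#' tables the Yates continuity correction is available via `yates = TRUE`;
#' it is off by default.
#'
#' @param x An r x c matrix of counts (r, c >= 2).
#' @param yates Apply the Yates continuity correction (2x2 tables only)?
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `test_used`.
#' @examples
#' chi_square_test(matrix(c(20, 10, 10, 20), nrow = 2))
#' @export
chi_square_test <- function(x, yates = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("at least a 2x2 table is required", call. = FALSE)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("chi-square test undefined: a marginal total is zero", call. = FALSE)
  }
  if (yates && !all(dim(x) == 2L)) {
    stop("the Yates correction applies to 2x2 tables only", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(x, correct = yates))
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = as.integer(unname(ht$parameter)),
    p.value = unname(ht$p.value),
    test_used = if (yates) "chi_square_yates" else "chi_square"
  )
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p-value by the point-probability method: conditioning on the
#' margins, the hypergeometric probabilities of all tables whose probability
#' does not exceed that of the observed table are summed.
#'
#' @param x A 2x2 matrix of counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(2, 0, 0, 2), nrow = 2))
#' @export
fisher_exact <- function(x) {
  x <- as_2x2(x)
  a <- x[1, 1]
  r1 <- sum(x[1, ])
  r2 <- sum(x[2, ])
  c1 <- sum(x[, 1])
  if (r1 + r2 == 0) stop("empty table", call. = FALSE)
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  # relative tolerance guards ties against floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Choose between chi-square and Fisher's exact test
#'
#' Cochran's rule: Fisher's exact test when any expected cell count is below 5
#' or the grand total is below 40, the uncorrected chi-square test otherwise.
#'
#' @param x A 2x2 matrix of counts.
#' @return `"fisher_exact"` or `"chi_square"`.
#' @export
choose_test <- function(x) {
  x <- as_2x2(x)
  n <- sum(x)
  expected <- outer(rowSums(x), colSums(x)) / n
  if (n < 40 || any(expected < 5)) "fisher_exact" else "chi_square"
}

#' Compare the two rows of a 2x2 table
#'
#' The workhorse behind every stratified comparison in the package: computes
#' the cross-product odds ratio with its Woolf interval, selects chi-square or
#' Fisher's exact test by Cochran's rule (see [choose_test()]), and returns
#' everything as a single test object. P-values are two-sided.
#'
#' @param x A 2x2 matrix of counts; rows are the two groups being compared,
#'   columns are event / non-event.
#' @param yates Use the Yates-corrected chi-square when the chi-square branch
#'   is selected? Off by default.
#' @param labels Optional character vector of length 2 naming the compared
#'   groups (used in printing).
#' @return An object of class `rob_test`; see [tidy.rob_test()] for the
#'   one-row tibble form.
#' @examples
#' contingency_test(matrix(c(443, 132, 87, 45), nrow = 2, byrow = TRUE))
#' @export
contingency_test <- function(x, yates = FALSE, labels = NULL) {
  x <- as_2x2(x)
  or <- odds_ratio(x)
  test <- choose_test(x)
  if (test == "fisher_exact") {
    res <- tibble::tibble(
      statistic = NA_real_, df = NA_integer_,
      p.value = fisher_exact(x), test_used = "fisher_exact"
    )
  } else {
    res <- chi_square_test(x, yates = yates)
  }
  structure(
    list(
      table = x,
      labels = labels,
      odds_ratio = or$estimate,
      or_ci95 = c(or$conf.low, or$conf.high),
      or_corrected = or$corrected,
      statistic = res$statistic,
      df = res$df,
      p_value = res$p.value,
      test_used = res$test_used
    ),
    class = "rob_test"
  )
}

#' @export
print.rob_test <- function(x, ...) {
  cat("2x2 comparison (", x$test_used, ")\n", sep = "")
  if (!is.null(x$labels)) cat("  groups: ", paste(x$labels, collapse = " vs "), "\n", sep = "")
  cat(sprintf("  OR = %.2f (95%% CI %.2f-%.2f%s)\n", x$odds_ratio,
              x$or_ci95[1], x$or_ci95[2],
              if (x$or_corrected) ", Haldane-Anscombe corrected" else ""))
  if (!is.na(x$statistic)) {
    cat(sprintf("  chi-square = %.3f, df = %d, ", x$statistic, x$df))
  } else {
    cat("  ")
  }
  cat(sprintf("P = %.4g\n", x$p_value))
  invisible(x)
}

#' Tidy a 2x2 comparison
#'
#' @param x A `rob_test` object from [contingency_test()].
#' @param ... Unused.
#' @return A one-row tibble with `estimate` (odds ratio), `conf.low`,
#'   `conf.high`, `statistic`, `df`, `p.value`, `method` and `corrected`.
#' @method tidy rob_test
#' @export
tidy.rob_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$odds_ratio,
    conf.low = x$or_ci95[1],
    conf.high = x$or_ci95[2],
    statistic = x$statistic,
    df = x$df,
    p.value = x$p_value,
    method = x$test_used,
    corrected = x$or_corrected
  )
}

#' Glance at a 2x2 comparison
#'
#' @param x A `rob_test` object from [contingency_test()].
#' @param ... Unused.
#' @return A one-row tibble: `n` (grand total), `estimate`, `p.value`,
#'   `method`.
#' @method glance rob_test
#' @export
glance.rob_test <- function(x, ...) {
  tibble::tibble(
    n = sum(x$table),
    estimate = x$odds_ratio,
    p.value = x$p_value,
    method = x$test_used
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
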