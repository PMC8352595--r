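#' Mendelian chi-square goodness-of-fit test
#'
#' Pearson chi-square of observed genotype counts against expected
#' Mendelian proportions (default 1:2:1 for a heterozygous intercross).
#'
#' @param observed non-negative integer counts per genotype class.
#' @param ratio positive expected ratio weights, same length as
#'   `observed`.
#' @return list with `chi2`, `df` (= classes - 1), `p`, and `expected`
#'   counts.
#' @export
mendelian_chisq <- function(observed, ratio = c(1, 2, 1)) {
  if (length(observed) != length(ratio))
    stop("observed and ratio differ in length")
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed counts must be non-negative integers")
  if (any(ratio < 0) || sum(ratio) <= 0)
    stop("ratio weights must be non-negative with positive sum")
  if (any(ratio == 0 & observed > 0))
    stop("zero expected count for a class with positive observed count")
  n <- sum(observed)
  if (n <= 0) stop("need at least one observation")
  keep <- ratio > 0
  res <- suppressWarnings(
    stats::chisq.test(observed[keep], p = ratio[keep] / sum(ratio[keep]))
  )
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = n * ratio / sum(ratio))
}

as_2x2 <- function(table) {
  m <- if (is.matrix(table)) table else matrix(table, 2, 2, byrow = TRUE)
  if (!all(dim(m) == c(2, 2))) stop("need a 2x2 table")
  if (any(m < 0) || any(m != round(m)))
    stop("cells must be non-negative integers")
  if (sum(m) == 0) stop("table is empty")
  m
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-ordering rule: the sum of
#' hypergeometric probabilities, over tables with the observed margins,
#' that are no more probable than the observed table.
#'
#' @param table 2x2 matrix, or a length-4 vector in row-major order
#'   (a, b, c, d).
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as_2x2(table)
  stats::fisher.test(m)$p.value
}

#' Pearson chi-square test on a 2x2 table
#'
#' chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)), df = 1, optionally with
#' the Yates continuity correction.
#'
#' @param table 2x2 matrix, or length-4 vector (row-major a, b, c, d).
#' @param yates apply the continuity correction (default off).
#' @return list with `chi2`, `df` (= 1) and `p`.
#' @export
pearson_chisq_2x2 <- function(table, yates = FALSE) {
  m <- as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: every expected cell must be > 0")
  res <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
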