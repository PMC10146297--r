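# Method-agreement statistics for paired calcium scores: five-category risk
# classification, cross-tabulation, accuracy, linear/quadratic weighted
# kappa, reclassification analysis, Lin's concordance, Bland-Altman limits
# of agreement, Pearson correlation and paired t-test.

RISK_LABELS <- c("0", "1-10", "11-100", "101-400", ">400")
RISK_UPPER <- c(0, 10, 100, 400, Inf)

#' Cardiovascular risk category of an Agatston score
#'
#' Ordered bins \{0\}, (0, 10], (10, 100], (100, 400], (400, Inf) labelled
#' `"0", "1-10", "11-100", "101-400", ">400"`. Fractional scores are binned
#' without rounding; a score of exactly 400 is `"101-400"`.
#'
#' @param agatston non-negative Agatston score(s).
#' @return factor with the five ordered risk levels.
#' @export
#' @examples
#' classify_risk(c(0, 10.5, 400, 400.1))
classify_risk <- function(agatston) {
  if (any(agatston < 0)) {
    stop_cac("Agatston scores must be non-negative", "cac_contract_error")
  }
  idx <- findInterval(agatston, RISK_UPPER, left.open = TRUE) + 1L
  factor(RISK_LABELS[idx], levels = RISK_LABELS, ordered = TRUE)
}

#' Risk cross-classification table
#'
#' 5 x 5 count matrix of paired risk categories; rows are method A (the
#' automated CCTA scores in this package's pipeline), columns method B (the
#' CSCT reference).
#'
#' @param a,b paired Agatston scores for methods A and B.
#' @return integer matrix of class `risk_table`.
#' @export
cross_tabulate <- function(a, b) {
  if (!length(a) || length(a) != length(b)) {
    stop_cac("need non-empty paired score vectors", "cac_validation_error")
  }
  tab <- table(classify_risk(a), classify_risk(b))
  risk_table(unclass(as.matrix(tab)))
}

#' Construct a risk table from a 5 x 5 count matrix
#'
#' @param counts 5 x 5 matrix of non-negative integer counts, rows = method
#'   A category, columns = method B category.
#' @return an object of class `risk_table`.
#' @export
risk_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 5L)) stop_cac("risk table must be 5 x 5", "cac_format_error")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_cac("risk table counts must be non-negative integers", "cac_format_error")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(auto = RISK_LABELS, reference = RISK_LABELS)
  structure(counts, class = c("risk_table", "matrix", "array"))
}

#' Packaged risk cross-classification fixtures
#'
#' The two 5 x 5 matrices shipped with the package (internal and external
#' validation cohorts, N = 198 and N = 113 after failure exclusion), used by
#' the worked examples and the regression tests of the agreement statistics.
#'
#' @param which `"internal"` or `"external"`.
#' @return a [risk_table()].
#' @export
risk_table_fixture <- function(which = c("internal", "external")) {
  which <- match.arg(which)
  path <- system.file("extdata", sprintf("risk_table_%s.csv", which),
                      package = "cacscore", mustWork = TRUE)
  risk_table(as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE)))
}

#' Classification accuracy of a risk table
#'
#' @param table a [risk_table()].
#' @return proportion of subjects on the diagonal.
#' @export
accuracy <- function(table) {
  n <- sum(table)
  if (n == 0) stop_cac("empty risk table", "cac_validation_error")
  sum(diag(table)) / n
}

#' Weighted kappa for ordinal agreement
#'
#' Chance-corrected agreement `(Po_w - Pe_w) / (1 - Pe_w)` with agreement
#' weights `w_ij = 1 - |i - j| / 4` (linear, default) or
#' `1 - (i - j)^2 / 16` (quadratic); expected agreement from the row/column
#' marginal products.
#'
#' @param table a [risk_table()].
#' @param weights `"linear"` or `"quadratic"`.
#' @return kappa in [-1, 1]; `NaN` (with a warning) for a degenerate table
#'   whose marginals are concentrated in a single category.
#' @export
weighted_kappa <- function(table, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  n <- sum(table)
  if (n == 0) stop_cac("empty risk table", "cac_validation_error")
  p <- table / n
  dist <- abs(outer(0:4, 0:4, `-`))
  w <- if (weights == "linear") 1 - dist / 4 else 1 - dist^2 / 16
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (abs(1 - pe) < 1e-12) {
    warning("degenerate risk table: weighted kappa undefined", call. = FALSE)
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' Reclassification analysis
#'
#' Counts subjects placed in a different risk category by the automated
#' method (rows) than by the reference (columns), and how many of those were
#' shifted to a lower category.
#'
#' @param table a [risk_table()].
#' @return list with `reclassified`, `reclassified_fraction` (of all
#'   subjects), `downward`, `downward_fraction` (of reclassified subjects;
#'   `NaN` when nothing was reclassified).
#' @export
reclassification <- function(table) {
  n <- sum(table)
  reclassified <- n - sum(diag(table))
  lower <- lower.tri(matrix(0, 5, 5))  # row index > column index
  upper <- upper.tri(matrix(0, 5, 5))  # row index < column index: auto below reference
  downward <- sum(table[upper])
  list(
    reclassified = as.integer(reclassified),
    reclassified_fraction = reclassified / n,
    downward = as.integer(downward),
    downward_fraction = if (reclassified > 0) downward / reclassified else NaN
  )
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments, plus a 95% confidence interval from the Fisher
#' z-transform with Lin's asymptotic variance.
#'
#' @param x,y paired score vectors, n >= 3.
#' @param conf confidence level.
#' @return list with `ccc`, `lower`, `upper`.
#' @export
lin_ccc <- function(x, y, conf = 0.95) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop_cac("need paired vectors, n >= 3", "cac_validation_error")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom < 1e-24) {
    warning("both vectors constant: CCC undefined", call. = FALSE)
    return(list(ccc = NaN, lower = NaN, upper = NaN))
  }
  ccc <- 2 * sxy / denom
  r <- suppressWarnings(stats::cor(x, y))
  ci <- c(NaN, NaN)
  if (is.finite(r) && abs(r) > 1e-12 && abs(ccc) < 1) {
    u <- (mx - my) / (sx2 * sy2)^0.25
    z <- atanh(ccc)
    sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    q <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- tanh(z + c(-1, 1) * q * sqrt(max(sz2, 0)))
  } else if (abs(ccc) >= 1 - 1e-12) {
    ci <- c(ccc, ccc)
  }
  list(ccc = ccc, lower = ci[1], upper = ci[2])
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Bias is `mean(x - y)`; limits are `bias +/- 1.96 sd(x - y)` with the
#' sample (n - 1) standard deviation.
#'
#' @param x,y paired measurement vectors, n >= 3.
#' @return list with `bias`, `lower`, `upper`, `sd`.
#' @export
bland_altman <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop_cac("need paired vectors, n >= 3", "cac_validation_error")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s, sd = s)
}

#' Pearson correlation with p-value
#'
#' @param x,y paired vectors, n >= 3.
#' @return list with `r` and `p`; `r = NaN` (flagged by a warning) when
#'   either vector has zero variance.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop_cac("need paired vectors, n >= 3", "cac_validation_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(r = NaN, p = NaN))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired t-test
#'
#' @param x,y paired vectors, n >= 2.
#' @return list with `t`, `p` and `degenerate` (TRUE when the differences
#'   have zero spread, in which case `t = 0, p = 1` for identical vectors).
#' @export
paired_t_test <- function(x, y) {
  n <- length(x)
  if (n < 2L || length(y) != n) stop_cac("need paired vectors, n >= 2", "cac_validation_error")
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(t = if (all(d == 0)) 0 else sign(d[1]) * Inf, p = if (all(d == 0)) 1 else 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}

#' Full agreement report for paired scores
#'
#' Bundles every agreement statistic the validation pipeline reports:
#' Pearson r, Spearman rho, Lin's CCC with CI, Bland-Altman bias and limits,
#' linear weighted kappa, accuracy and reclassification of the five-category
#' risk classification.
#'
#' @param auto,reference paired total Agatston (or volume) scores; `auto` is
#'   the automated CCTA method, `reference` the CSCT standard.
#' @param categorical if `FALSE`, skip the risk-category statistics (useful
#'   for volume scores).
#' @return list of class `agreement_report`.
#' @export
agreement_report <- function(auto, reference, categorical = TRUE) {
  rep <- list(
    n = length(auto),
    pearson = pearson_r(auto, reference),
    spearman = suppressWarnings(stats::cor(auto, reference, method = "spearman")),
    ccc = lin_ccc(auto, reference),
    bland_altman = bland_altman(auto, reference),
    t_test = paired_t_test(auto, reference)
  )
  if (categorical) {
    tab <- cross_tabulate(auto, reference)
    rep$risk_table <- tab
    rep$accuracy <- accuracy(tab)
    rep$weighted_kappa <- weighted_kappa(tab, "linear")
    rep$reclassification <- reclassification(tab)
  }
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  Pearson r = %.3f, Spearman rho = %.3f\n", x$pearson$r, x$spearman))
  cat(sprintf("  Lin CCC = %.3f (95%% CI %.3f..%.3f)\n",
              x$ccc$ccc, x$ccc$lower, x$ccc$upper))
  cat(sprintf("  Bland-Altman bias = %.2f (LoA %.2f..%.2f)\n",
              x$bland_altman$bias, x$bland_altman$lower, x$bland_altman$upper))
  if (!is.null(x$accuracy)) {
    cat(sprintf("  risk accuracy = %.1f%%, linear weighted kappa = %.3f\n",
                100 * x$accuracy, x$weighted_kappa))
    cat(sprintf("  reclassified %d (%.1f%%), downward %d (%.1f%% of reclassified)\n",
                x$reclassification$reclassified,
                100 * x$reclassification$reclassified_fraction,
                x$reclassification$downward,
                100 * x$reclassification$downward_fraction))
  }
  invisible(x)
}
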