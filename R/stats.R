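#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around [stats::shapiro.test()] returning the W statistic
#' and p-value, used to screen feature distributions before the paired
#' t-test family.
#'
#' @param values numeric sample, 3 <= n <= 5000.
#' @return list with elements `W` and `p`.
#' @export
shapiroWilk <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("at least 3 values are required")
  if (stats::sd(values) == 0) stop("constant sample; W is undefined")
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Pairwise paired t-tests with Bonferroni correction
#'
#' Two-sided paired t-tests between every pair of conditions (e.g.
#' contraction speeds), with Bonferroni adjustment over the number of
#' pairs: `p_adjusted = min(1, p_raw * nPairs)`. Subjects must be matched
#' across conditions.
#'
#' @param values numeric matrix or data.frame, subjects x conditions
#'   (column names are the condition labels).
#' @param alpha family-wise significance level.
#' @return data.frame with one row per condition pair: `condition_a`,
#'   `condition_b`, `t`, `df`, `p_raw`, `p_adjusted`, `significant`.
#' @examples
#' m <- cbind(`60` = rnorm(14), `90` = rnorm(14), `120` = rnorm(14))
#' pairwiseTBonferroni(m)
#' @export
pairwiseTBonferroni <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop("at least 2 conditions are required")
  if (nrow(values) < 3L) stop("at least 3 matched subjects are required")
  if (anyNA(values)) stop("unequal pairing: missing values in the matrix")
  labs <- colnames(values)
  if (is.null(labs)) labs <- as.character(seq_len(ncol(values)))
  pairs <- utils::combn(ncol(values), 2L)
  out <- apply(pairs, 2L, function(pr) {
    d <- values[, pr[1L]] - values[, pr[2L]]
    if (stats::sd(d) == 0) {
      # identical paired samples: no evidence of a difference by convention
      if (all(d == 0)) {
        tt <- list(statistic = 0, parameter = length(d) - 1L, p.value = 1)
      } else stop("zero variance of paired differences; t is undefined")
    } else {
      tt <- stats::t.test(values[, pr[1L]], values[, pr[2L]], paired = TRUE)
    }
    data.frame(condition_a = labs[pr[1L]], condition_b = labs[pr[2L]],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value)
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "bonferroni")
  out$significant <- out$p_adjusted < alpha
  out
}

#' Pearson product-moment correlation
#'
#' Wrapper around [stats::cor.test()] reporting r, r-squared and the
#' two-sided p-value; used to compare point-based and trajectory-based
#' CoG estimates.
#'
#' @param x,y matched numeric samples, n >= 3.
#' @return list with elements `r`, `r2`, `p`, `n`. `r` is NA (with a
#'   message in `note`) when either sample has zero variance.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("samples must be matched")
  if (length(x) < 3L) stop("at least 3 pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_, n = length(x),
                note = "undefined: zero variance"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}
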