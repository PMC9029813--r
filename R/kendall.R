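#' Rank methods within each judging class
#'
#' Each activity class acts as a judge ranking the competing screening
#' methods by their recall in that class: higher recall receives a
#' higher rank, ties receive average ranks. Ranks start at `offset`
#' (0 by default — the convention under which published mean ranks over
#' n methods sum to n(n-1)/2; use 1 for the textbook 1..n convention;
#' Kendall's W is identical under either).
#'
#' @param recalls Numeric matrix, classes (judges) x methods (objects).
#' @param offset 0 or 1.
#' @return A `rank_matrix`: same shape as `recalls`, with an `offset`
#'   attribute.
#' @export
#' @examples
#' rank_within_judges(matrix(c(5, 7, 7, 9), 1), offset = 0)
rank_within_judges <- function(recalls, offset = 0) {
  recalls <- as.matrix(recalls)
  stopifnot(offset %in% c(0, 1), nrow(recalls) >= 1, ncol(recalls) >= 2)
  if (!is.numeric(recalls) || anyNA(recalls)) {
    stop("recall cells must be numeric and non-missing")
  }
  rk <- t(apply(recalls, 1, rank)) + (offset - 1)
  if (ncol(recalls) == 1) rk <- t(rk)
  structure(rk, offset = offset, class = c("rank_matrix", "matrix", "array"))
}

#' Kendall's coefficient of concordance
#'
#' Measures agreement among m judges (activity classes) ranking n
#' objects (screening methods). With rank totals \eqn{R_i} per object,
#' their mean \eqn{\bar R}, and \eqn{S = \sum_i (R_i - \bar R)^2},
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n)}}
#' W is 0 for no agreement and 1 for complete agreement, and is
#' invariant to the rank offset. Ties receive average ranks; by default
#' no tie-correction term is applied (set `tie_correction = TRUE` for
#' the tie-corrected denominator).
#'
#' @param x A `rank_matrix` from [rank_within_judges()], or a plain
#'   classes x methods recall matrix (ranked internally at `offset`).
#' @param offset Rank offset used when `x` still needs ranking.
#' @param tie_correction Logical; subtract the standard tie term
#'   \eqn{m \sum T_j} from the denominator.
#' @return A `kendall_result` with rank totals `R`, their mean `R_bar`,
#'   `S`, `W`, `mean_ranks` (`R / m`), the Friedman chi-square
#'   statistic, `df` and upper-tail `p`.
#' @export
#' @examples
#' t4 <- benchmark_recall_table("ds1", 1)
#' kendall_w(t4$recalls)$W
kendall_w <- function(x, offset = 0, tie_correction = FALSE) {
  if (inherits(x, "recall_table")) x <- x$recalls
  if (ncol(x) < 2) stop("need at least 2 objects (methods)")
  rk <- if (inherits(x, "rank_matrix")) x else rank_within_judges(x, offset)
  m <- nrow(rk)
  n <- ncol(rk)
  R <- colSums(rk)
  R_bar <- mean(R)
  S <- sum((R - R_bar)^2)
  denom <- m^2 * (n^3 - n)
  # tie-corrected denominator: subtract m * sum over judges of (t^3 - t)
  if (tie_correction) denom <- denom - m * sum_ties(rk)
  W <- 12 * S / denom
  chi_sq <- m * (n - 1) * W
  df <- n - 1
  structure(
    list(R = R, R_bar = R_bar, S = S, W = W, mean_ranks = R / m,
         m = m, n = n, chi_sq = chi_sq, df = df,
         p = pchisq(chi_sq, df, lower.tail = FALSE),
         tie_correction = isTRUE(tie_correction)),
    class = "kendall_result"
  )
}

sum_ties <- function(rk) {
  sum(apply(rk, 1, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  }))
}

#' @export
print.kendall_result <- function(x, ...) {
  cat(sprintf("<kendall_result> m = %d judges, n = %d objects\n", x$m, x$n))
  cat(sprintf("  W = %.2f, chi-square = %.2f (df %d), p = %.4g\n",
              x$W, x$chi_sq, x$df, x$p))
  cat("  mean ranks:",
      paste(sprintf("%s=%.2f", names(x$mean_ranks) %||%
                      seq_along(x$mean_ranks), x$mean_ranks),
            collapse = " "), "\n")
  invisible(x)
}

#' Friedman chi-square significance of a concordance result
#'
#' The large-sample significance of W: `chi-square = m (n - 1) W` on
#' `n - 1` degrees of freedom, with the upper-tail probability.
#'
#' @param result A `kendall_result` from [kendall_w()].
#' @return List with `statistic`, `df` and `p`.
#' @export
friedman_chi_square <- function(result) {
  stopifnot(inherits(result, "kendall_result"))
  list(statistic = result$chi_sq, df = result$df, p = result$p)
}
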