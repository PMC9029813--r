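#' Continuous Tanimoto similarity between count or code vectors
#'
#' For non-negative vectors `a`, `b` the canonical continuous Tanimoto
#' coefficient is
#' \deqn{S_{AB} = \frac{\sum_i a_i b_i}{\sum_i a_i^2 + \sum_i b_i^2 -
#'   \sum_i a_i b_i}}{S = sum(ab) / (sum(a^2) + sum(b^2) - sum(ab))}
#' which is 1 exactly when `a == b`. The `"as_printed"` variant replaces
#' the minus in the denominator by a plus; it is dominated by the
#' standard form and its self-similarity is 1/3 rather than 1, but it is
#' retained because some descriptions of the measure print it that way,
#' and rankings can differ between the two. Results therefore record
#' which variant produced them.
#'
#' @param a,b Non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @param variant `"standard"` (default) or `"as_printed"`.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' continuous_tanimoto(c(2, 1, 0), c(2, 1, 0))               # 1
#' continuous_tanimoto(c(1, 1, 0), c(1, 0, 1))               # 1/3
#' continuous_tanimoto(c(2, 1, 0), c(2, 1, 0), "as_printed") # 1/3
continuous_tanimoto <- function(a, b, variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  if (length(a) != length(b)) stop("vectors differ in length")
  if (any(a < 0) || any(b < 0)) stop("vectors must be non-negative")
  ab <- sum(a * b)
  aa <- sum(a * a)
  bb <- sum(b * b)
  if (aa == 0 && bb == 0) stop("similarity undefined: both vectors all-zero")
  if (variant == "standard") ab / (aa + bb - ab) else ab / (aa + bb + ab)
}

#' Binary Tanimoto similarity
#'
#' The classic coefficient `c / (a + b - c)` on presence/absence
#' fingerprints, with `c` the number of shared on-bits.
#'
#' @param a,b Vectors with entries in {0, 1}, not both all-zero.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' binary_tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
binary_tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
    stop("binary_tanimoto expects 0/1 vectors")
  }
  on_a <- sum(a)
  on_b <- sum(b)
  if (on_a == 0 && on_b == 0) stop("similarity undefined: both vectors all-zero")
  both <- sum(a * b)
  both / (on_a + on_b - both)
}

#' Similarity of one query against every row of a matrix
#'
#' Vectorized scoring used by the screening engine. All-zero database
#' rows score 0 against a nonzero query (they share nothing with it);
#' an all-zero query is an error.
#'
#' @param query Non-negative numeric vector.
#' @param x Matrix with `length(query)` columns, one molecule per row.
#' @param variant `"standard"`, `"as_printed"` or `"binary"`.
#' @return Numeric vector of similarities, one per row of `x`.
#' @export
similarity_scores <- function(query, x,
                              variant = c("standard", "as_printed", "binary")) {
  variant <- match.arg(variant)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (length(query) != ncol(x)) stop("query width does not match matrix")
  if (variant == "binary") {
    if (!all(query %in% c(0, 1)) || !all(x %in% c(0, 1))) {
      stop("binary variant expects 0/1 data")
    }
  }
  if (sum(query) == 0 && all(query == 0)) stop("all-zero query")
  ab <- as.numeric(x %*% query)
  qq <- sum(query * query)
  xx <- rowSums(x * x)
  denom <- if (variant == "as_printed") qq + xx + ab else qq + xx - ab
  ifelse(denom > 0, ab / denom, 0)
}
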