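# Differential-accessibility exact test. Conditional on the total count of
# the two libraries, the count in library A follows a binomial (no
# overdispersion) or a conditional negative-binomial law; the two-sided
# p-value doubles the smaller tail.

.exact_rate_one <- function(xa, xb, na, nb, disp) {
  xa <- round(xa)
  xb <- round(xb)
  t <- xa + xb
  if (t == 0) return(1)
  pa <- na / (na + nb)
  if (disp == 0) {
    lower <- stats::pbinom(xa, t, pa)
    upper <- stats::pbinom(xa - 1, t, pa, lower.tail = FALSE)
  } else {
    r <- 1 / disp
    k <- 0:t
    lp <- stats::dnbinom(k, size = r, mu = t * pa, log = TRUE) +
      stats::dnbinom(t - k, size = r, mu = t * (1 - pa), log = TRUE)
    lp <- lp - max(lp)
    w <- exp(lp)
    w <- w / sum(w)
    lower <- sum(w[k <= xa])
    upper <- sum(w[k >= xa])
  }
  min(1, 2 * min(lower, upper))
}

#' Conditional exact test for equality of two count rates
#'
#' Tests whether a region's count rate differs between two libraries of
#' totals `n_a` and `n_b`. With `dispersion = 0` this is the conditional
#' binomial test: given the total `x_a + x_b`, `x_a` is binomial with
#' success probability `n_a / (n_a + n_b)` under the null, and the
#' two-sided p-value doubles the smaller tail (capped at 1). With
#' `dispersion > 0` the binomial kernel is replaced by the conditional
#' negative-binomial law (size `1/dispersion`), enumerated over all
#' outcomes with the same total - the standard exact-test construction for
#' overdispersed counts. Counts are rounded to the nearest integer.
#'
#' @param x_a,x_b counts in the two libraries (vectorized).
#' @param n_a,n_b library totals (> 0).
#' @param dispersion negative-binomial dispersion (>= 0).
#' @return vector of two-sided p-values.
#' @examples
#' exact_rate_test(5, 5, 1e6, 1e6)            # 1: perfect symmetry
#' exact_rate_test(0, 10, 1e6, 1e6)           # 2 * (1/2)^10
#' @export
exact_rate_test <- function(x_a, x_b, n_a, n_b, dispersion = 0) {
  if (any(x_a < 0) || any(x_b < 0)) stop("counts must be >= 0")
  if (any(n_a <= 0) || any(n_b <= 0)) stop("library totals must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  n <- max(length(x_a), length(x_b), length(n_a), length(n_b))
  x_a <- rep_len(x_a, n)
  x_b <- rep_len(x_b, n)
  n_a <- rep_len(n_a, n)
  n_b <- rep_len(n_b, n)
  vapply(seq_len(n), function(i) {
    .exact_rate_one(x_a[i], x_b[i], n_a[i], n_b[i], dispersion)
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, in input order.
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @return adjusted values, same order and length.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
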