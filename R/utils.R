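#' Weighted quantiles
#'
#' Quantiles of a weighted sample, defined through the weighted empirical
#' cumulative distribution function: the `p`-quantile is the smallest `x`
#' whose cumulative normalised weight reaches `p`. Used for the weighted
#' baseline table, where clone weights define a pseudo-population.
#'
#' @param x Numeric vector.
#' @param w Non-negative weights, recycled to `length(x)`.
#' @param probs Probabilities in `[0, 1]`.
#' @param na.rm Drop missing values (and their weights) first.
#' @return Numeric vector of `length(probs)`.
#' @export
#' @examples
#' weighted_quantile(1:5, w = c(1, 1, 1, 1, 10), probs = 0.5)
weighted_quantile <- function(x, w = rep(1, length(x)), probs = 0.5,
                              na.rm = TRUE) {
  stopifnot(length(probs) >= 1, all(probs >= 0 & probs <= 1))
  w <- rep_len(w, length(x))
  if (na.rm) {
    keep <- !is.na(x) & !is.na(w)
    x <- x[keep]
    w <- w[keep]
  }
  if (length(x) == 0L) return(rep(NA_real_, length(probs)))
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

weighted_median <- function(x, w = rep(1, length(x)), na.rm = TRUE) {
  weighted_quantile(x, w, probs = 0.5, na.rm = na.rm)
}

# format "median [q1, q3]" strings for baseline tables
fmt_med_iqr <- function(x, w, digits = 1) {
  q <- weighted_quantile(x, w, probs = c(0.5, 0.25, 0.75))
  sprintf("%s [%s, %s]",
          format(round(q[1], digits), trim = TRUE),
          format(round(q[2], digits), trim = TRUE),
          format(round(q[3], digits), trim = TRUE))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}
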