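#' Five-number summary with quarter spreads
#'
#' Minimum, quartiles and maximum, with quartiles located by the
#' (N+1)-position rule: the p-th quantile sits at position p(N+1),
#' linearly interpolated between adjacent order statistics (the
#' `type = 6` convention of [stats::quantile()]).  The quarter spreads
#' are the successive differences of the five numbers; they are
#' nonnegative and sum exactly to the range.
#'
#' @param x numeric vector, length >= 4.
#' @return An object of class `five_number`: list with `summary` (named
#'   vector `min`, `q1`, `median`, `q3`, `max`) and `quarter_spreads`
#'   (length-4 vector of successive differences).
#' @examples
#' five_number(1:5)$summary   # quartiles 1.5, 3, 4.5
#' @export
five_number <- function(x) {
  if (!is.numeric(x) || length(x) < 4) {
    stop("`x` must be numeric with at least 4 values")
  }
  if (any(!is.finite(x))) stop("`x` contains non-finite values")
  q <- unname(stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 6))
  s <- c(min = min(x), q1 = q[1], median = q[2], q3 = q[3], max = max(x))
  structure(list(summary = s, quarter_spreads = diff(s)),
            class = "five_number")
}

#' @export
print.five_number <- function(x, ...) {
  print(round(x$summary, 4))
  cat("quarter spreads:", paste(round(x$quarter_spreads, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Quartile choropleth classification
#'
#' Assigns each region to one of four classes bounded by the
#' [five_number()] quartiles: class 1 is \eqn{[\min, Q_1]}, class k for
#' k > 1 is \eqn{(Q_{k-1}, Q_k]}.  Higher class means higher value; tied
#' values always share a class.  This is the classification used for
#' four-shade grey-scale disease maps.
#'
#' @param x numeric vector, length >= 4.
#' @return integer vector of classes in 1..4, named like `x`.
#' @examples
#' quartile_classify(c(1, 2, 3, 4, 5, 6, 7, 8))   # 1 1 2 2 3 3 4 4
#' @export
quartile_classify <- function(x) {
  fn <- five_number(x)$summary
  cl <- as.integer(1L + (x > fn["q1"]) + (x > fn["median"]) + (x > fn["q3"]))
  names(cl) <- names(x)
  cl
}
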