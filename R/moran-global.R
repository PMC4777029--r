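#' Global Moran's I
#'
#' The classical index of overall spatial autocorrelation on a lattice,
#' \deqn{I = \frac{N}{S_0}\,
#'       \frac{\sum_i\sum_j w_{ij}(x_i-\bar x)(x_j-\bar x)}
#'            {\sum_i (x_i-\bar x)^2},}
#' computed with the weights exactly as supplied (binary by default; the
#' statistic is invariant to adding a constant to `x` and to positive
#' rescaling).  Under the null of no spatial autocorrelation its
#' expectation is \eqn{-1/(N-1)}.
#'
#' @param x numeric regional variable aligned to `w$order` (a named
#'   vector is reordered by region id).
#' @param w a [weights_matrix()].
#' @return the scalar statistic.
#' @examples
#' ring <- region_lattice(cbind(as.character(1:4), as.character(c(2:4, 1))),
#'                        as.character(1:4))
#' moran_i(c(1, -1, 1, -1), weights_matrix(ring))   # -1
#' @export
moran_i <- function(x, w) {
  stopifnot(inherits(w, "weights_matrix"))
  x <- align_variable(x, w$order)
  if (w$s0 <= 0) stop("empty weights: S0 = 0")
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) stop("degenerate variance: all values identical")
  n <- length(x)
  (n / w$s0) * as.numeric(z %*% w$w %*% z) / ss
}

#' Null moments of Moran's I under the normality assumption
#'
#' Cliff-Ord moments of I when the observations are i.i.d. Gaussian:
#' \deqn{E[I] = -\frac{1}{n-1}, \qquad
#'   \mathrm{Var}(I) = \frac{n^2 S_1 - n S_2 + 3 S_0^2}{S_0^2 (n^2-1)}
#'   - E[I]^2.}
#'
#' @param w a [weights_matrix()].
#' @param n number of regions (defaults to the weights' dimension).
#' @return list with `expected` and `variance`.
#' @export
moran_null_moments <- function(w, n = length(w$order)) {
  stopifnot(inherits(w, "weights_matrix"))
  if (n <= 3) stop("null moments require n >= 4")
  if (w$s0 <= 0) stop("empty weights: S0 = 0")
  e <- -1 / (n - 1)
  v <- (n^2 * w$s1 - n * w$s2 + 3 * w$s0^2) / (w$s0^2 * (n^2 - 1)) - e^2
  list(expected = e, variance = v)
}

#' Normal-theory z test for Moran's I
#'
#' @param i observed Moran's I.
#' @param moments list with `expected` and `variance`, as returned by
#'   [moran_null_moments()].
#' @return list with `z` and the two-sided normal `p_normal`.
#' @export
moran_z_test <- function(i, moments) {
  if (!is.finite(moments$variance) || moments$variance <= 0) {
    stop("null variance must be positive")
  }
  z <- (i - moments$expected) / sqrt(moments$variance)
  list(z = z, p_normal = 2 * stats::pnorm(-abs(z)))
}

#' Permutation test for Moran's I
#'
#' Randomly reallocates the observed values over the regions `n_perm`
#' times, recomputes I for each arrangement, and returns the two-sided
#' Monte-Carlo p-value with the add-one rule,
#' \eqn{p = (1 + \#\{|I^* - E| \ge |I_{obs} - E|\})/(n_{perm} + 1)},
#' where \eqn{E = -1/(N-1)}.
#'
#' @inheritParams moran_i
#' @param n_perm number of random permutations (>= 99), default 1000.
#' @param seed optional integer seed for reproducibility.
#' @param return_sims if `TRUE`, attach the vector of permuted I values.
#' @return list with `p_perm`, `n_perm`, `seed`, and optionally `sims`.
#' @export
moran_permutation_test <- function(x, w, n_perm = 1000, seed = NULL,
                                   return_sims = FALSE) {
  stopifnot(inherits(w, "weights_matrix"))
  if (n_perm < 99) stop("n_perm must be at least 99")
  x <- align_variable(x, w$order)
  i_obs <- moran_i(x, w)
  n <- length(x)
  if (!is.null(seed)) set.seed(seed)
  z <- x - mean(x)
  ss <- sum(z^2)
  perm <- vapply(seq_len(n_perm), function(k) sample.int(n), integer(n))
  zp <- matrix(z[perm], n, n_perm)
  sims <- (n / w$s0) * colSums(zp * (w$w %*% zp)) / ss
  e <- -1 / (n - 1)
  p <- (1 + sum(abs(sims - e) >= abs(i_obs - e) - 1e-12)) / (n_perm + 1)
  out <- list(p_perm = p, n_perm = n_perm, seed = seed)
  if (return_sims) out$sims <- sims
  out
}

#' Global Moran test (normal-theory and permutation inference)
#'
#' Convenience wrapper bundling [moran_i()], [moran_null_moments()],
#' [moran_z_test()] and [moran_permutation_test()] into one result
#' record.
#'
#' @inheritParams moran_permutation_test
#' @return An object of class `global_moran`: list with fields `I`,
#'   `expected`, `variance`, `z`, `p_normal`, `p_perm`, `n_perm`,
#'   `seed`.
#' @examples
#' fx <- iraq_governorates()
#' w <- weights_matrix(fx$lattice)
#' moran_test(fx$data$ur_transformed, w, seed = 1)
#' @export
moran_test <- function(x, w, n_perm = 1000, seed = NULL) {
  x <- align_variable(x, w$order)
  i <- moran_i(x, w)
  mom <- moran_null_moments(w)
  zt <- moran_z_test(i, mom)
  pt <- moran_permutation_test(x, w, n_perm = n_perm, seed = seed)
  structure(
    list(I = i, expected = mom$expected, variance = mom$variance,
         z = zt$z, p_normal = zt$p_normal,
         p_perm = pt$p_perm, n_perm = n_perm, seed = seed),
    class = "global_moran")
}

#' @export
print.global_moran <- function(x, digits = 4, ...) {
  cat("Global Moran's I test\n")
  cat("  I        =", round(x$I, digits),
      " (null expectation", round(x$expected, digits), ")\n")
  cat("  z        =", round(x$z, digits),
      "  two-sided normal p =", round(x$p_normal, digits), "\n")
  cat("  perm p   =", round(x$p_perm, digits),
      " (", x$n_perm, "permutations )\n")
  invisible(x)
}
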