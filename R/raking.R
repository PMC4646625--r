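# One-dimensional bounded raking: rescale a row of values toward a fixed
# total while confining every value to its population-size bin.

#' Initial uniform population draws for one bin
#'
#' Farm populations within a frequency-distribution bin are initialized as
#' i.i.d. draws from U(a, b), the null distribution over the bin range.  For
#' the unbounded top bin, b is the unit's remaining unknown population.
#'
#' @param n number of farms.
#' @param a,b bin bounds, \code{a <= b}.
#' @return \code{n} real draws (uses the current RNG state).
#' @export
drawInitial <- function(n, a, b) {
  if (b < a) stop("upper bound below lower bound")
  if (n == 0L) return(numeric(0))
  stats::runif(n, a, b)
}

#' Rake one bin of farm populations to its subtotal
#'
#' Iteratively rescales a row of within-bin population values so they sum to
#' the bin's aggregate subtotal (the one-dimensional proportional-fitting
#' update), repairing values pushed outside the bin by clamping them to the
#' violated bound and nudging them 10\% of the way toward the feasible mean
#' (\code{subtotal/n}).  Iteration stops when the sum is within 0.5 animals
#' of the subtotal or after \code{maxIter} passes; a final bounded
#' largest-remainder integerization makes the sum exact while keeping every
#' value inside \code{[a, b]}.
#'
#' @param values initial real draws (see [drawInitial()]).
#' @param subtotal target integer sum.
#' @param a,b bin bounds (for the unbounded bin, \code{b} is the per-farm
#'   population cap).
#' @param tol convergence tolerance on the sum (animals).
#' @param maxIter iteration cap.
#' @return Integer vector summing exactly to \code{subtotal}, each element in
#'   \code{[a, b]}.
#' @examples
#' fitBin(drawInitial(2, 25, 49), 80, 25, 49)
#' @export
fitBin <- function(values, subtotal, a, b, tol = 0.5, maxIter = 2000L) {
  n <- length(values)
  if (n == 0L) {
    if (round(subtotal) != 0) stop("non-zero subtotal with zero farms")
    return(integer(0))
  }
  if (subtotal < n * a - 1e-9 || subtotal > n * b + 1e-9)
    stop(sprintf("infeasible subtotal %s for %d farms in [%s, %s]",
                 subtotal, n, a, b))
  if (n == 1L) return(as.integer(round(subtotal)))
  x <- as.numeric(values)
  mu <- subtotal / n
  for (k in seq_len(maxIter)) {
    s <- sum(x)
    if (abs(s - subtotal) < tol && all(x >= a - 1e-9) && all(x <= b + 1e-9)) break
    x <- if (s > 0) x * (subtotal / s) else rep(mu, n)
    low <- x < a
    high <- x > b
    if (any(low)) x[low] <- a + 0.1 * (mu - a)
    if (any(high)) x[high] <- b - 0.1 * (b - mu)
  }
  intAllocate(x, subtotal, rep(a, n), rep(b, n))
}
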