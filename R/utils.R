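# Internal numeric utilities shared by the imputation, disaggregation and
# placement code paths.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a reproducible per-unit seed
#'
#' Streams a single run seed into independent sub-seeds keyed by a string
#' (typically a unit id), so per-county results do not depend on processing
#' order.  Stable across platforms: a polynomial string hash combined with the
#' run seed modulo 2^31 - 1.
#'
#' @param seed integer run seed.
#' @param key character key.
#' @return An integer seed in [1, 2^31 - 2].
#' @examples
#' deriveSeed(1, "19001")
#' @export
deriveSeed <- function(seed, key) {
  m <- 2147483647
  h <- 0
  for (cc in utf8ToInt(as.character(key))) h <- (h * 131 + cc) %% m
  s <- ((as.numeric(seed) %% 94906265) * 22695477 + h + 1) %% m
  as.integer(if (s == 0) 1 else s)
}

# Sum-preserving integerization of a real vector under per-element integer
# bounds: round, then repair the residual one unit at a time, always moving
# the element whose current value is farthest below (or above) its real
# target -- a bounded largest-remainder scheme.
intAllocate <- function(x, total, lo, hi) {
  n <- length(x)
  total <- round(total)
  if (n == 0L) {
    if (total != 0) stop("cannot allocate a non-zero total over zero elements")
    return(integer(0))
  }
  lo <- ceiling(lo - 1e-9)
  hi <- floor(hi + 1e-9)
  if (sum(lo) > total || sum(hi) < total)
    stop(sprintf("infeasible integer allocation: total %s outside [%s, %s]",
                 total, sum(lo), sum(hi)))
  v <- pmin(pmax(round(x), lo), hi)
  d <- total - sum(v)
  while (d != 0) {
    if (d > 0) {
      idx <- which(v < hi)
      ord <- idx[order(x[idx] - v[idx], decreasing = TRUE)]
      take <- ord[seq_len(min(d, length(ord)))]
      v[take] <- v[take] + 1L
    } else {
      idx <- which(v > lo)
      ord <- idx[order(x[idx] - v[idx])]
      take <- ord[seq_len(min(-d, length(ord)))]
      v[take] <- v[take] - 1L
    }
    d <- total - sum(v)
  }
  as.integer(v)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from the Mann-Whitney rank statistic with
#' ties averaged.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 outcome labels.
#' @return AUC in [0, 1].
#' @examples
#' rankAuc(c(.1, .4, .35, .8), c(0, 0, 1, 1))
#' @export
rankAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
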