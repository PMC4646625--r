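# Verification analyses: absolute percent difference, reaggregation checks,
# and the substitution analysis of the missing-data model.

#' Absolute percent difference
#'
#' \code{100 * |estimate - reference| / reference}.  A zero reference with a
#' zero estimate is 0 by convention; a zero reference with a positive
#' estimate is undefined and returned as \code{NA} (callers exclude these
#' from means and report their count).
#'
#' @param estimate,reference non-negative numerics (vectorized).
#' @return Percent differences.
#' @examples
#' apd(97, 100)
#' @export
apd <- function(estimate, reference) {
  out <- ifelse(reference == 0,
                ifelse(estimate == 0, 0, NA_real_),
                100 * abs(estimate - reference) / reference)
  as.numeric(out)
}

.apdSummary <- function(perUnit, level, iterations = 1L) {
  vals <- perUnit$apd
  data.frame(level = level,
             mean = mean(vals, na.rm = TRUE),
             se = if (iterations > 1L) stats::sd(vals, na.rm = TRUE) / sqrt(iterations)
                  else NA_real_,
             n = sum(!is.na(vals)),
             n_undefined = sum(is.na(vals)),
             stringsAsFactors = FALSE)
}

#' Reaggregation check
#'
#' Sums fine-level values per group and scores them against coarse-level
#' reference totals with the absolute percent difference.
#'
#' @param fine named numeric values at the fine level.
#' @param coarse named numeric reference totals at the coarse level.
#' @param grouping named character mapping every fine unit to its coarse
#'   unit.
#' @param level label of the coarse level for the report.
#' @param metric report label.
#' @return A \linkS4class{VerificationReport} with one APD per coarse unit.
#' @export
reaggregationCheck <- function(fine, coarse, grouping, level = "state",
                               metric = "reaggregation") {
  miss <- setdiff(names(fine), names(grouping))
  if (length(miss)) stop("unmapped fine units: ", paste(miss, collapse = ", "))
  g <- grouping[names(fine)]
  sums <- tapply(fine, g, sum)
  ref <- coarse[names(sums)]
  if (anyNA(ref)) stop("reference totals missing for: ",
                       paste(names(sums)[is.na(ref)], collapse = ", "))
  perUnit <- data.frame(unit_id = names(sums), level = level,
                        apd = apd(as.numeric(sums), as.numeric(ref)),
                        stringsAsFactors = FALSE)
  new("VerificationReport", metric = metric, perUnit = perUnit,
      summary = .apdSummary(perUnit, level), iterations = 1L,
      seed = NA_integer_)
}

#' Reaggregate one census level against its parents
#'
#' Convenience wrapper around [reaggregationCheck()]: sums the population
#' totals of all units at \code{childLevel} and scores them against their
#' parents' published totals.
#'
#' @param table a complete \linkS4class{CensusTable}.
#' @param childLevel \code{"state"} (state-to-national) or \code{"county"}
#'   (county-to-state).
#' @return A \linkS4class{VerificationReport}.
#' @export
censusReaggregation <- function(table, childLevel = c("state", "county")) {
  childLevel <- match.arg(childLevel)
  u <- censusUnits(table)
  kids <- u[u$level == childLevel, , drop = FALSE]
  parentLevel <- if (childLevel == "state") "national" else "state"
  parents <- u[u$level == parentLevel, , drop = FALSE]
  reaggregationCheck(stats::setNames(kids$pop_total, kids$unit_id),
                     stats::setNames(parents$pop_total, parents$unit_id),
                     stats::setNames(kids$parent_id, kids$unit_id),
                     level = parentLevel,
                     metric = paste0(childLevel, "-to-", parentLevel,
                                     " reaggregation"))
}

#' Substitution analysis of the missing-data model
#'
#' Starting from a completed table treated as fully published, repeatedly
#' redacts \code{k} randomly chosen county-level population cells (bin cells
#' or totals, plus complementary-suppression partners), re-runs the full
#' imputation, and scores every re-imputed value against the original it
#' replaced.  Per-cell APDs are averaged within each state and summarized
#' across iterations, so a stable mean across redaction patterns
#' demonstrates the imputation is insensitive to which cells happen to be
#' missing.  (Recovered state and county totals are pinned exactly by the
#' published hierarchy whenever they are not redacted themselves, so the
#' informative comparison is at the cell level.)
#'
#' @param completed a redaction-free \linkS4class{CensusTable}.
#' @param k number of cells to redact per iteration.
#' @param iters number of random redaction patterns (default 100).
#' @param seed integer seed.
#' @return A \linkS4class{VerificationReport}: per-state mean APD across
#'   iterations, with the overall mean and its standard error over
#'   iterations.
#' @export
substitutionCheck <- function(completed, k, iters = 100L, seed = 1L) {
  u <- censusUnits(completed)
  schema <- censusSchema(completed)
  if (anyNA(as.matrix(u[, c(.popCols(schema), "pop_total")])))
    stop("substitution analysis needs a completed table")
  cIdx <- which(u$level == "county")
  nf <- as.matrix(u[cIdx, .nfarmCols(schema)])
  # candidate cells: county bin cells with at least one farm, and county totals
  cand <- rbind(
    do.call(rbind, lapply(seq_len(nBins(schema)), function(b)
      if (any(nf[, b] > 0))
        data.frame(row = cIdx[nf[, b] > 0], col = b) else NULL)),
    data.frame(row = cIdx, col = 0L))  # col 0 = pop_total
  states <- sort(unique(u$parent_id[cIdx]))
  perIter <- matrix(NA_real_, length(states), iters,
                    dimnames = list(states, NULL))
  grand <- numeric(iters)
  for (it in seq_len(iters)) {
    for (attempt in 1:5) {
      pick <- withSeed(deriveSeed(seed, paste0("subst:", it, ":", attempt)),
                       cand[sample.int(nrow(cand), min(k, nrow(cand))), ,
                            drop = FALSE])
      obs <- u
      for (r in seq_len(nrow(pick))) {
        i <- pick$row[r]
        b <- pick$col[r]
        if (b == 0L) obs$pop_total[i] <- NA_real_
        else obs[[.popCols(schema)[b]]][i] <- NA_real_
      }
      obs <- .complementarySuppression(obs, schema)
      imp <- tryCatch(imputeAll(censusTable(obs, schema)),
                      error = function(e) NULL)
      if (!is.null(imp)) break
      message("infeasible redaction draw; redrawing (iteration ", it, ")")
    }
    if (is.null(imp)) stop("could not draw a feasible redaction pattern")
    v <- censusUnits(imp)
    # score every value this pattern forced us to re-impute
    aVals <- numeric(0)
    aState <- character(0)
    for (i in cIdx) {
      cols <- c(.popCols(schema)[which(is.na(as.numeric(obs[i, .popCols(schema)])))],
                if (is.na(obs$pop_total[i])) "pop_total")
      for (ccol in cols) {
        aVals <- c(aVals, apd(v[[ccol]][i], u[[ccol]][i]))
        aState <- c(aState, u$parent_id[i])
      }
    }
    if (length(aVals)) {
      byState <- tapply(aVals, aState, mean, na.rm = TRUE)
      perIter[names(byState), it] <- byState
      grand[it] <- mean(aVals, na.rm = TRUE)
    } else {
      grand[it] <- 0
    }
  }
  perUnit <- data.frame(unit_id = states, level = "state",
                        apd = rowMeans(perIter, na.rm = TRUE),
                        stringsAsFactors = FALSE)
  summary <- data.frame(level = "state", mean = mean(grand),
                        se = stats::sd(grand) / sqrt(iters),
                        n = length(states), n_undefined = 0L,
                        stringsAsFactors = FALSE)
  new("VerificationReport", metric = sprintf("substitution (k=%d)", k),
      perUnit = perUnit, summary = summary, iterations = as.integer(iters),
      seed = as.integer(seed))
}
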