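# Simulation model stages 1-2: downscale each unit's complete 7-bin
# population distribution into integer populations for individual farms.

#' Disaggregate one census unit into individual farm drafts
#'
#' For each population-size bin, initial per-farm populations are drawn
#' uniformly over the bin range ([drawInitial()]) and then raked to the bin's
#' aggregate subtotal with exact bounded integerization ([fitBin()]).  The
#' unbounded top bin draws up to the unit's remaining unknown population; no
#' single farm can exceed the bin subtotal minus the minima of its peers.
#'
#' Per-bin subtotal enforcement makes every bin sum -- and hence the unit's
#' grand total -- exact for any seed; only the individual farm values vary
#' between seeds.
#'
#' @param rec one-row units data.frame with no redacted entries (i.e. after
#'   [imputeAll()]).
#' @param schema bin schema.
#' @param seed integer RNG seed.
#' @return A data.frame of farm drafts: \code{unit_id, bin, population}, with
#'   one row per farm (\code{sum(nfarms)} rows in total).
#' @examples
#' u <- censusUnits(swineCensus2012())
#' drafts <- disaggregateUnit(u[1, ], seed = 1)
#' sum(drafts$population)  # equals the published 66,026,785 total
#' @export
disaggregateUnit <- function(rec, schema = binSchema(), seed = 1L) {
  B <- nBins(schema)
  nf <- as.numeric(rec[, .nfarmCols(schema)])
  pp <- as.numeric(rec[, .popCols(schema)])
  if (anyNA(pp) || is.na(rec$pop_total))
    stop("unit ", rec$unit_id, " has redacted entries; impute first")
  withSeed(seed, {
    out <- vector("list", B)
    for (b in seq_len(B)) {
      n <- nf[b]
      if (n == 0) {
        if (pp[b] != 0) stop("unit ", rec$unit_id, ": population in an empty bin ", b)
        next
      }
      a <- binLower(schema)[b]
      up <- binUpper(schema)[b]
      if (is.infinite(up)) up <- pp[b] - (n - 1) * a  # remaining unknown population
      pops <- fitBin(drawInitial(n, a, up), pp[b], a, up)
      out[[b]] <- data.frame(unit_id = rec$unit_id, bin = b, population = pops,
                             stringsAsFactors = FALSE)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out))
      return(data.frame(unit_id = character(), bin = integer(),
                        population = integer(), stringsAsFactors = FALSE))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}
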