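# Simulation model stage 3: attach coordinates to farm drafts using the
# occurrence-probability surface, the exclusion mask, and neighborhood
# exclusion rules.

#' Exclusion neighborhood of a population-size bin
#'
#' Farms are kept apart by marking a square pixel window around each placed
#' farm unavailable: 25 pixels (5x5) for the largest (>= 1000 head) farms,
#' nine pixels (3x3) for the five intermediate classes, and no neighborhood
#' beyond the farm's own pixel for the smallest (1-24 head) class.
#'
#' @param bin bin index 1-7.
#' @return Window size in pixels (25, 9 or 1).
#' @examples
#' neighborhoodWindow(7)
#' @export
neighborhoodWindow <- function(bin) {
  stopifnot(all(bin %in% 1:7))
  ifelse(bin == 7L, 25L, ifelse(bin >= 2L, 9L, 1L))
}

.windowHalfWidth <- function(bin) (sqrt(neighborhoodWindow(bin)) - 1) / 2

#' Place farm drafts on the probability surface
#'
#' Processes one county's drafts from the largest population-size class to
#' the smallest.  For each farm a target probability is drawn from the
#' empirical presence pool; the farm is placed uniformly among the county's
#' available pixels whose occurrence probability lies within \code{delta0} of
#' the target, with the tolerance doubling until candidates exist.  The
#' farm's pixel becomes occupied and its exclusion window unavailable.
#'
#' If the county runs out of available pixels the exclusion windows are
#' relaxed to the farm's own pixel (masked and occupied pixels stay off
#' limits); if even that fails an error lists the unplaced farms.
#'
#' @param drafts farm drafts for one county ([disaggregateUnit()]).
#' @param surface a \linkS4class{ProbabilitySurface}.
#' @param pool empirical presence-probability pool
#'   ([presenceProbabilityPool()]).
#' @param seed integer RNG seed.
#' @param delta0 initial probability-matching tolerance (default 0.01).
#' @param commodity commodity label written to the records.
#' @param stateNames optional named character vector mapping county ids to
#'   state names.
#' @return List with \code{records} (data.frame \code{fips, state, lat, lon,
#'   population, commodity} plus bookkeeping columns \code{bin, row, col,
#'   prob}) and the updated \code{surface} (exclusions carried forward).
#' @export
placeFarms <- function(drafts, surface, pool, seed = 1L, delta0 = 0.01,
                       commodity = "swine", stateNames = NULL) {
  if (!nrow(drafts))
    return(list(records = .emptyRecords(), surface = surface))
  cid <- unique(drafts$unit_id)
  if (length(cid) != 1L) stop("placeFarms expects drafts for a single county")
  ci <- match(cid, surface@countyIds)
  if (is.na(ci)) stop("county ", cid, " is not on the surface")
  pix <- which(surface@county == ci)
  if (!length(pix)) stop("county ", cid, " has no pixels")
  nr <- nrow(surface@prob)
  avail <- surface@available
  occupied <- surface@occupied
  masked <- !surface@available | surface@occupied  # hard exclusions only at entry
  probPix <- surface@prob[pix]
  rng <- range(pool)
  ord <- order(-drafts$bin, -drafts$population)
  drafts <- drafts[ord, , drop = FALSE]
  n <- nrow(drafts)
  outRow <- integer(n)
  outCol <- integer(n)
  outProb <- numeric(n)
  relaxed <- FALSE
  withSeed(seed, {
    for (i in seq_len(n)) {
      okBase <- avail[pix] & !occupied[pix]
      if (!any(okBase)) {
        # relaxation ladder: drop neighborhood exclusions, keep mask/occupancy
        relaxed <- TRUE
      }
      if (relaxed) okBase <- !masked[pix] & !occupied[pix]
      if (!any(okBase))
        stop(sprintf("county %s exhausted available pixels with %d farm(s) unplaced",
                     cid, n - i + 1L))
      target <- pool[sample.int(length(pool), 1L)]
      delta <- delta0
      repeat {
        cand <- which(okBase & abs(probPix - target) <= delta)
        if (length(cand)) break
        delta <- delta * 2
        if (delta > (rng[2L] - rng[1L]) + 1) {  # covers any probability gap
          cand <- which(okBase)
          break
        }
      }
      sel <- pix[cand[sample.int(length(cand), 1L)]]
      r <- (sel - 1L) %% nr + 1L
      cc <- (sel - 1L) %/% nr + 1L
      occupied[r, cc] <- TRUE
      avail[r, cc] <- FALSE
      h <- .windowHalfWidth(drafts$bin[i])
      if (h > 0) {
        rr <- max(1L, r - h):min(nr, r + h)
        ccw <- max(1L, cc - h):min(ncol(avail), cc + h)
        avail[rr, ccw] <- FALSE
      }
      outRow[i] <- r
      outCol[i] <- cc
      outProb[i] <- surface@prob[r, cc]
    }
  })
  ll <- pixelToLatLon(surface, outRow, outCol)
  state <- if (!is.null(stateNames) && cid %in% names(stateNames))
    stateNames[[cid]] else substr(cid, 1L, 2L)
  records <- data.frame(fips = drafts$unit_id, state = state,
                        lat = ll$lat, lon = ll$lon,
                        population = drafts$population,
                        commodity = commodity, bin = drafts$bin,
                        row = outRow, col = outCol, prob = outProb,
                        stringsAsFactors = FALSE)
  surface@available <- avail
  surface@occupied <- occupied
  list(records = records, surface = surface)
}

.emptyRecords <- function() {
  data.frame(fips = character(), state = character(), lat = numeric(),
             lon = numeric(), population = integer(), commodity = character(),
             bin = integer(), row = integer(), col = integer(),
             prob = numeric(), stringsAsFactors = FALSE)
}

#' Write farm records to CSV
#'
#' Writes the standard output fields \code{fips,state,lat,lon,population,
#' commodity}, dropping internal bookkeeping columns.
#'
#' @param records farm-record data.frame from [placeFarms()] or [runFlaps()].
#' @param path output path.
#' @export
writeFarmRecords <- function(records, path) {
  utils::write.csv(records[, c("fips", "state", "lat", "lon", "population",
                               "commodity")],
                   path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full farm-location and population simulation
#'
#' End-to-end pipeline: impute every redacted census cell ([imputeAll()]),
#' disaggregate each in-scope county into individual farms
#' ([disaggregateUnit()]), and attach coordinates ([placeFarms()]).  Output
#' records carry the county FIPS code, state, coordinates in decimal
#' degrees, population and commodity regardless of the scope of the run.
#' Per-county RNG streams are derived from the run seed by unit id, so
#' results do not depend on processing order.
#'
#' @param table a \linkS4class{CensusTable} (may contain redactions).
#' @param surface a \linkS4class{ProbabilitySurface} covering the scope.
#' @param pool presence-probability pool; alternatively supply \code{model}
#'   and \code{sample} to derive it.
#' @param model,sample optional \linkS4class{AveragedModel} and
#'   presence/absence sample used to build the pool when \code{pool} is NULL.
#' @param scope \code{"national"}, \code{"state"} or \code{"county"}.
#' @param unit unit id selecting the state or county for sub-national scopes.
#' @param seed integer run seed.
#' @param commodity commodity label.
#' @return List with \code{records}, the imputed \code{table}, the farm-to-
#'   county reaggregation \code{report} (\linkS4class{VerificationReport})
#'   and the final \code{surface}.
#' @export
runFlaps <- function(table, surface, pool = NULL, model = NULL, sample = NULL,
                     scope = c("national", "state", "county"), unit = NULL,
                     seed = 1L, commodity = "swine") {
  scope <- match.arg(scope)
  if (is.null(pool)) {
    if (is.null(model) || is.null(sample))
      stop("supply either a pool or both model and sample")
    pool <- presenceProbabilityPool(model, sample)
  }
  full <- imputeAll(table)
  u <- censusUnits(full)
  counties <- u[u$level == "county", , drop = FALSE]
  if (scope == "state") {
    if (is.null(unit)) stop("state scope needs a unit id")
    counties <- counties[counties$parent_id == unit, , drop = FALSE]
  } else if (scope == "county") {
    if (is.null(unit)) stop("county scope needs a unit id")
    counties <- counties[counties$unit_id == unit, , drop = FALSE]
  }
  if (!nrow(counties)) stop("no county units in scope")
  counties <- counties[order(counties$unit_id), , drop = FALSE]
  recs <- vector("list", nrow(counties))
  for (i in seq_len(nrow(counties))) {
    cid <- counties$unit_id[i]
    drafts <- disaggregateUnit(counties[i, , drop = FALSE],
                               schema = censusSchema(full),
                               seed = deriveSeed(seed, paste0("disagg:", cid)))
    placed <- placeFarms(drafts, surface, pool,
                         seed = deriveSeed(seed, paste0("place:", cid)),
                         commodity = commodity)
    surface <- placed$surface
    recs[[i]] <- placed$records
  }
  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  fine <- tapply(records$population, records$fips, sum)
  report <- reaggregationCheck(stats::setNames(as.numeric(fine), names(fine)),
                               stats::setNames(counties$pop_total, counties$unit_id),
                               stats::setNames(counties$unit_id, counties$unit_id),
                               level = "county", metric = "farm-to-county reaggregation")
  list(records = records, table = full, report = report, surface = surface)
}
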