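# Census table I/O, per-cell population bounds, and consistency validation.

.REDACTED <- "(D)"

#' Read a hierarchical census file
#'
#' Parses a comma-separated census file with one row per administrative unit
#' and header
#' \code{unit_id,level,parent_id,nfarms_b1..nfarms_b7,pop_b1..pop_b7,pop_total}.
#' The sentinel \code{"(D)"} marks a redacted population cell (the NASS
#' disclosure-avoidance convention); internally redaction is carried as
#' \code{NA}, never as a magic number.  Identifiers are kept as zero-padded
#' strings.
#'
#' @param path file path.
#' @param schema bin schema; default [binSchema()].
#' @return A \linkS4class{CensusTable} with redaction flags preserved.
#' @seealso [writeCensus()] for the inverse; the round trip is bit-identical.
#' @export
readCensus <- function(path, schema = binSchema()) {
  B <- nBins(schema)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  need <- c("unit_id", "level", "parent_id", .nfarmCols(schema), .popCols(schema),
            "pop_total")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("census file is missing columns: ", paste(miss, collapse = ", "))
  parseInt <- function(col, allowRedacted) {
    out <- rep(NA_real_, length(col))
    red <- col == .REDACTED
    if (!allowRedacted && any(red))
      stop("redacted value in a never-redacted column (row ",
           which(red)[1L], ")")
    val <- suppressWarnings(as.numeric(gsub(",", "", col[!red], fixed = TRUE)))
    if (anyNA(val))
      stop("malformed numeric value in row ",
           which(!red)[which(is.na(val))[1L]], " of ", path)
    out[!red] <- val
    out
  }
  u <- data.frame(unit_id = raw$unit_id, level = raw$level,
                  parent_id = ifelse(raw$parent_id == "", NA_character_, raw$parent_id),
                  stringsAsFactors = FALSE)
  bad <- which(!u$level %in% .censusLevels)
  if (length(bad))
    stop("unknown level '", raw$level[bad[1L]], "' in row ", bad[1L])
  for (b in seq_len(B)) u[[.nfarmCols(schema)[b]]] <- parseInt(raw[[.nfarmCols(schema)[b]]], FALSE)
  for (b in seq_len(B)) u[[.popCols(schema)[b]]] <- parseInt(raw[[.popCols(schema)[b]]], TRUE)
  u$pop_total <- parseInt(raw$pop_total, TRUE)
  censusTable(u, schema)
}

#' Write a census file
#'
#' Inverse of [readCensus()]; redacted cells are written as \code{"(D)"}.
#'
#' @param table a \linkS4class{CensusTable}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCensus <- function(table, path) {
  u <- censusUnits(table)
  schema <- censusSchema(table)
  fmt <- function(x) ifelse(is.na(x), .REDACTED, format(x, scientific = FALSE, trim = TRUE))
  out <- data.frame(unit_id = u$unit_id, level = u$level,
                    parent_id = ifelse(is.na(u$parent_id), "", u$parent_id),
                    stringsAsFactors = FALSE)
  for (cc in .nfarmCols(schema)) out[[cc]] <- fmt(u[[cc]])
  for (cc in .popCols(schema)) out[[cc]] <- fmt(u[[cc]])
  out$pop_total <- fmt(u$pop_total)
  utils::write.csv(out, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Feasible population range of one frequency-distribution cell
#'
#' Multiplying the farm count of a bin by the minimum and maximum bin sizes
#' gives the absolute range of the (possibly redacted) population in that
#' cell.  The unbounded top bin has no intrinsic maximum, so a cap -- the
#' unit's known or imputed total population, or failing that the parent's --
#' must be supplied for it.
#'
#' @param rec one-row units data.frame (a single unit record).
#' @param b bin index.
#' @param cap population cap for the unbounded bin; ignored for bounded bins.
#' @param schema bin schema.
#' @return Named numeric \code{c(min, max)}.
#' @examples
#' u <- censusUnits(swineCensus2012())
#' cellBounds(u[1, ], 1)      # 41,688 farms of 1-24 head
#' @export
cellBounds <- function(rec, b, cap = NULL, schema = binSchema()) {
  B <- nBins(schema)
  stopifnot(b >= 1L, b <= B)
  n <- as.numeric(rec[[.nfarmCols(schema)[b]]])
  lo <- n * binLower(schema)[b]
  if (b < B || is.finite(binUpper(schema)[b])) {
    hi <- n * binUpper(schema)[b]
  } else {
    if (is.null(cap)) stop("the unbounded bin requires a population cap")
    hi <- if (n > 0) as.numeric(cap) else 0
    if (n > 0 && hi < lo)
      stop(sprintf("infeasible cap %s for %s farms of >= %s head (needs >= %s)",
                   cap, n, binLower(schema)[b], lo))
  }
  c(min = lo, max = hi)
}

#' Validate a census table
#'
#' Checks every type invariant and returns the violations found rather than
#' throwing: published population cells must lie within their [cellBounds()],
#' fully published frequency distributions must sum to their published total,
#' and published child totals (and bin subtotals) must sum to the published
#' parent figures.
#'
#' @param table a \linkS4class{CensusTable}.
#' @param capFromParent use the parent's published total as the unbounded-bin
#'   cap when the unit's own total is redacted (default TRUE).
#' @return A data.frame \code{unit_id, field, rule, message}; zero rows means
#'   the table is fully consistent.
#' @export
validateCensus <- function(table, capFromParent = TRUE) {
  u <- censusUnits(table)
  schema <- censusSchema(table)
  B <- nBins(schema)
  nf <- as.matrix(u[, .nfarmCols(schema)])
  pp <- as.matrix(u[, .popCols(schema)])
  out <- list()
  bad <- function(unit, field, rule, message)
    data.frame(unit_id = unit, field = field, rule = rule, message = message,
               stringsAsFactors = FALSE)
  capFor <- function(i) {
    if (!is.na(u$pop_total[i])) return(u$pop_total[i])
    j <- match(u$parent_id[i], u$unit_id)
    if (capFromParent && !is.na(j) && !is.na(u$pop_total[j])) return(u$pop_total[j])
    Inf
  }
  for (i in seq_len(nrow(u))) {
    for (b in seq_len(B)) {
      v <- pp[i, b]
      if (is.na(v)) next
      bb <- cellBounds(u[i, ], b, cap = capFor(i), schema = schema)
      hi <- if (b == B) Inf else bb["max"]  # cap check is advisory only for the top bin
      if (v < bb["min"] - 1e-9 || v > hi + 1e-9)
        out[[length(out) + 1L]] <- bad(u$unit_id[i], .popCols(schema)[b], "cell_bounds",
          sprintf("pop %s outside [%s, %s] for %s farms", v, bb["min"],
                  if (is.finite(hi)) hi else "Inf", nf[i, b]))
    }
    if (!is.na(u$pop_total[i]) && !anyNA(pp[i, ])) {
      s <- sum(pp[i, ])
      if (s != u$pop_total[i])
        out[[length(out) + 1L]] <- bad(u$unit_id[i], "pop_total", "row_sum",
          sprintf("bins sum to %s but pop_total is %s", s, u$pop_total[i]))
    }
  }
  # hierarchy sums (only when all participating figures are published)
  for (lev in c("state", "county")) {
    kids <- u[u$level == lev, , drop = FALSE]
    if (!nrow(kids)) next
    for (pid in unique(kids$parent_id)) {
      j <- match(pid, u$unit_id)
      if (is.na(j)) next
      k <- kids[kids$parent_id == pid, , drop = FALSE]
      if (!is.na(u$pop_total[j]) && !anyNA(k$pop_total)) {
        s <- sum(k$pop_total)
        if (s > u$pop_total[j])
          out[[length(out) + 1L]] <- bad(pid, "pop_total", "hierarchy",
            sprintf("%s children sum to %s > parent total %s", lev, s, u$pop_total[j]))
        else if (nrow(k) > 0 && s != u$pop_total[j] && .allChildrenPresent(u, pid, lev))
          out[[length(out) + 1L]] <- bad(pid, "pop_total", "hierarchy",
            sprintf("%s children sum to %s != parent total %s", lev, s, u$pop_total[j]))
      }
      kp <- as.matrix(k[, .popCols(schema)])
      for (b in seq_len(B)) {
        v <- u[j, .popCols(schema)[b]]
        if (!is.na(v) && !anyNA(kp[, b]) && .allChildrenPresent(u, pid, lev)) {
          s <- sum(kp[, b])
          if (s != v)
            out[[length(out) + 1L]] <- bad(pid, .popCols(schema)[b], "hierarchy",
              sprintf("%s children bin %d sum to %s != parent cell %s", lev, b, s, v))
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(unit_id = character(), field = character(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# A parent's children are "all present" if their farm counts reaggregate to
# the parent's; partial tables (a lone county under a state) are not held to
# exact population sums.
.allChildrenPresent <- function(u, pid, lev) {
  j <- match(pid, u$unit_id)
  kids <- u[u$level == lev & u$parent_id == pid, , drop = FALSE]
  schema <- binSchema()  # farm columns are schema-width independent here
  nfc <- grep("^nfarms_b", names(u), value = TRUE)
  sum(as.matrix(kids[, nfc])) == sum(as.numeric(u[j, nfc]))
}

#' Published 2012 national swine census aggregate
#'
#' The published 2012 U.S. Census of Agriculture national hogs-and-pigs
#' aggregate (USDA NASS, Table 19): 63,246 farms and 66,026,785 head paired
#' over the seven population-size bins, with zero redactions.
#'
#' @return A single-unit \linkS4class{CensusTable}.
#' @examples
#' swineCensus2012()
#' @export
swineCensus2012 <- function() {
  path <- system.file("extdata", "swine_census_2012_national.csv",
                      package = "flaps", mustWork = TRUE)
  readCensus(path)
}
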