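# Missing-data model: two-step hierarchical iterative proportional fitting
# (IPF) that imputes all redacted population totals and bin subtotals while
# honouring published cells and farm-count bin bounds.

#' Midpoint seed value for a redacted population cell
#'
#' Redacted cells are seeded from the midpoints of their frequency-
#' distribution bins: farms-in-bin times the bin midpoint.  The unbounded top
#' bin uses the midpoint between its lower bound and the per-unit population
#' cap, clamped into the feasible [cellBounds()].  An empty bin is forced to
#' zero.
#'
#' @param rec one-row units data.frame.
#' @param b bin index.
#' @param cap population cap for the unbounded bin.
#' @param schema bin schema.
#' @return A non-negative real seed.
#' @examples
#' u <- censusUnits(swineCensus2012())
#' seedCell(u[1, ], 1)  # 41,688 farms x 12.5 head midpoint
#' @export
seedCell <- function(rec, b, cap = NULL, schema = binSchema()) {
  B <- nBins(schema)
  n <- as.numeric(rec[[.nfarmCols(schema)[b]]])
  if (n == 0) return(0)
  if (b < B || is.finite(binUpper(schema)[b]))
    return(n * (binLower(schema)[b] + binUpper(schema)[b]) / 2)
  bb <- cellBounds(rec, b, cap = cap, schema = schema)
  s <- n * (binLower(schema)[b] + cap / n) / 2
  min(max(s, bb["min"]), bb["max"])
}

#' IPF matrix with published-cell pinning
#'
#' The working object of the missing-data model: a non-negative matrix of
#' population cells (rows = units at the finer level, columns = bins), a flag
#' per cell marking it published (hard constraint) or seeded (adjustable),
#' pre-defined row totals \code{Qi} (NA marks a row whose total is itself
#' redacted and emerges from the fit) and column totals \code{Qj}, optional
#' per-cell bounds, and the iteration cap.
#'
#' @slot p numeric matrix of cell values (published values or seeds).
#' @slot published logical matrix; \code{TRUE} cells are never altered.
#' @slot Qi numeric row totals (NA = free row).
#' @slot Qj numeric column totals.
#' @slot lo,hi numeric matrices of per-cell bounds.
#' @slot mMax iteration cap (2000 by default).
#' @slot k iterations performed by the last [ipfFit()].
#' @slot converged whether the last fit met its tolerance.
#' @export
setClass("IpfMatrix",
         representation(p = "matrix", published = "matrix", Qi = "numeric",
                        Qj = "numeric", lo = "matrix", hi = "matrix",
                        mMax = "integer", k = "integer", converged = "logical"))

setValidity("IpfMatrix", function(object) {
  d <- dim(object@p)
  if (!identical(dim(object@published), d)) return("published mask dim mismatch")
  if (!identical(dim(object@lo), d) || !identical(dim(object@hi), d))
    return("bound matrices dim mismatch")
  if (length(object@Qi) != d[1L] || length(object@Qj) != d[2L])
    return("marginal lengths must match matrix dimensions")
  if (any(object@p < 0, na.rm = TRUE)) return("cells must be non-negative")
  TRUE
})

#' Construct an IPF matrix
#'
#' @param p initial cell matrix (published values and seeds).
#' @param published logical matrix of published-cell flags (default: all
#'   seeded, i.e. plain IPF).
#' @param Qi,Qj pre-defined row and column totals (\code{Qi} may contain NA
#'   for rows whose totals are redacted).
#' @param lo,hi optional per-cell bounds (defaults 0 and \code{Inf}).
#' @param mMax iteration cap.
#' @return An \linkS4class{IpfMatrix}.
#' @export
ipfMatrix <- function(p, Qi, Qj, published = NULL, lo = NULL, hi = NULL,
                      mMax = 2000L) {
  p <- as.matrix(p)
  if (is.null(published)) published <- matrix(FALSE, nrow(p), ncol(p))
  if (is.null(lo)) lo <- matrix(0, nrow(p), ncol(p))
  if (is.null(hi)) hi <- matrix(Inf, nrow(p), ncol(p))
  new("IpfMatrix", p = p, published = published, Qi = as.numeric(Qi),
      Qj = as.numeric(Qj), lo = as.matrix(lo), hi = as.matrix(hi),
      mMax = as.integer(mMax), k = 0L, converged = FALSE)
}

setMethod("show", "IpfMatrix", function(object) {
  cat("IpfMatrix:", nrow(object@p), "x", ncol(object@p), "cells;",
      sum(object@published), "published;",
      if (object@k > 0L) sprintf("fit k=%d converged=%s", object@k, object@converged)
      else "unfitted", "\n")
})

#' Fit an IPF matrix to its marginal totals
#'
#' Alternately rescales rows to \code{Qi} and columns to \code{Qj} until the
#' largest marginal discrepancy falls to \code{tol} or \code{mMax} iterations
#' elapse.  Published cells are hard constraints: each rescaling applies only
#' to the seeded cells of a row or column, which absorb the discrepancy
#' proportionally (with all cells seeded this reduces to the classical IPF
#' update).  Seeded cells are clamped into their bounds after every pass.
#' Rows with \code{NA} totals are constrained only through their columns.
#'
#' @param M an \linkS4class{IpfMatrix}.
#' @param tol convergence tolerance on marginal discrepancies; 0.5 animals by
#'   default (exact zero is unattainable in floating point for integer data).
#' @return The fitted \linkS4class{IpfMatrix} with \code{k} and
#'   \code{converged} filled in.
#' @examples
#' M <- ipfMatrix(matrix(1, 2, 2), Qi = c(2, 2), Qj = c(2, 2))
#' ipfFit(M)@k
#' @export
ipfFit <- function(M, tol = 0.5) {
  p <- M@p
  pub <- M@published
  sd <- !pub
  Qi <- M@Qi
  Qj <- M@Qj
  lo <- M@lo
  hi <- M@hi
  known <- !is.na(Qi)
  if (all(known)) {
    if (abs(sum(Qi) - sum(Qj)) > max(tol, 1e-6 * sum(Qj)))
      stop(sprintf("inconsistent marginals: sum(Qi)=%s, sum(Qj)=%s",
                   sum(Qi), sum(Qj)))
  }
  # upfront feasibility of each constrained row against its seeded capacity
  for (i in which(known)) {
    resid <- Qi[i] - sum(p[i, pub[i, ]])
    sl <- sum(lo[i, sd[i, ]])
    sh <- sum(hi[i, sd[i, ]])
    if (resid < sl - tol || resid > sh + tol)
      stop(sprintf("row %d infeasible: residual %s outside seeded capacity [%s, %s]",
                   i, resid, sl, sh))
    if (abs(resid) > tol && !any(sd[i, ] & hi[i, ] > 0))
      stop(sprintf("row %d is discrepant but has no seeded cell", i))
  }
  converged <- FALSE
  k <- 0L
  for (k in seq_len(M@mMax)) {
    # Eq 1: rescale each constrained row's seeded cells to the row total
    for (i in which(known)) {
      s <- sum(p[i, sd[i, ]])
      resid <- Qi[i] - sum(p[i, pub[i, ]])
      if (s > 0) p[i, sd[i, ]] <- p[i, sd[i, ]] * (max(resid, 0) / s)
    }
    p[sd] <- pmin(pmax(p[sd], lo[sd]), hi[sd])
    # Eq 2: rescale each column's seeded cells to the column total
    for (j in seq_along(Qj)) {
      s <- sum(p[sd[, j], j])
      resid <- Qj[j] - sum(p[pub[, j], j])
      if (s > 0) p[sd[, j], j] <- p[sd[, j], j] * (max(resid, 0) / s)
    }
    p[sd] <- pmin(pmax(p[sd], lo[sd]), hi[sd])
    disc <- max(c(abs(rowSums(p)[known] - Qi[known]), abs(colSums(p) - Qj), 0))
    if (disc <= tol) {
      converged <- TRUE
      break
    }
  }
  M@p <- p
  M@k <- k
  M@converged <- converged
  M
}

# Per-cell population bounds for a block of units, refined by interval
# propagation.  Row passes use published row totals (a redacted cell can be
# no smaller than the total minus the maxima of its siblings, and no larger
# than the total minus their minima); column passes use published
# column/parent cells the same way.  Alternating to a fixpoint captures
# forced values that cascade through the block (e.g. a lone redacted cell in
# a published column pins its row, which pins another column).
.unitBoundsMatrix <- function(kids, schema, capDefault, colTargets = NULL) {
  B <- nBins(schema)
  n <- nrow(kids)
  nf <- as.matrix(kids[, .nfarmCols(schema)])
  pp <- as.matrix(kids[, .popCols(schema)])
  pub <- !is.na(pp)
  Qi <- kids$pop_total
  lo <- nf * matrix(binLower(schema), n, B, byrow = TRUE)
  hi <- nf * matrix(binUpper(schema), n, B, byrow = TRUE)
  cap <- ifelse(!is.na(Qi), Qi, capDefault) - rowSums(lo[, -B, drop = FALSE])
  cap <- pmax(cap, lo[, B])
  hi[, B] <- ifelse(nf[, B] > 0, cap, 0)
  lo[pub] <- pp[pub]
  hi[pub] <- pp[pub]
  for (pass in 1:6) {
    loOld <- lo
    hiOld <- hi
    for (i in which(!is.na(Qi))) {
      for (b in seq_len(B)) {
        lo[i, b] <- max(lo[i, b], Qi[i] - sum(hi[i, -b]))
        hi[i, b] <- min(hi[i, b], Qi[i] - sum(lo[i, -b]))
      }
      if (any(lo[i, ] > hi[i, ] + 1e-9))
        stop("unit ", kids$unit_id[i],
             ": published cells are inconsistent with the published total")
    }
    if (!is.null(colTargets) && n > 1L) {
      for (b in which(!is.na(colTargets))) {
        for (i in seq_len(n)) {
          lo[i, b] <- max(lo[i, b], colTargets[b] - sum(hi[-i, b]))
          hi[i, b] <- min(hi[i, b], colTargets[b] - sum(lo[-i, b]))
        }
        if (any(lo[, b] > hi[, b] + 1e-9))
          stop("bin ", b, ": published cells are inconsistent with the ",
               "published column subtotal")
      }
    }
    if (identical(lo, loOld) && identical(hi, hiOld)) break
  }
  list(lo = lo, hi = hi, pub = pub)
}

# Impute one parent's block of children: build the IPF matrix, fit, then
# integerize so row and column sums are exact.  extraLo/extraHi optionally
# tighten the seeded-cell bounds with constraints aggregated from the level
# below (used when imputing states so county-level structure is honoured).
.imputeParentBlock <- function(kids, parent, schema, tol, mMax,
                               extraLo = NULL, extraHi = NULL) {
  B <- nBins(schema)
  n <- nrow(kids)
  nf <- as.matrix(kids[, .nfarmCols(schema)])
  pp <- as.matrix(kids[, .popCols(schema)])
  Qi <- kids$pop_total
  Qj <- as.numeric(parent[, .popCols(schema)])
  if (anyNA(Qj) || is.na(parent$pop_total))
    stop("parent unit ", parent$unit_id, " is incomplete")
  known <- !is.na(Qi)

  bm <- .unitBoundsMatrix(kids, schema, capDefault = parent$pop_total,
                          colTargets = Qj)
  lo <- bm$lo
  hi <- bm$hi
  pub <- bm$pub
  if (!is.null(extraLo)) {
    sd0 <- !pub
    lo[sd0] <- pmax(lo[sd0], extraLo[sd0])
    hi[sd0] <- pmin(hi[sd0], extraHi[sd0])
    bad <- sd0 & (lo > hi + 1e-9)
    # fall back to the looser bound if lower-level aggregation conflicts
    lo[bad] <- bm$lo[bad]
    hi[bad] <- bm$hi[bad]
  }
  capRow <- hi[, B]

  p <- pp
  for (i in seq_len(n)) {
    for (b in which(!pub[i, ])) {
      s <- seedCell(kids[i, ], b, cap = max(capRow[i], 1), schema = schema)
      p[i, b] <- min(max(s, lo[i, b]), hi[i, b])
    }
  }

  M <- ipfFit(ipfMatrix(p, Qi = Qi, Qj = Qj, published = pub, lo = lo, hi = hi,
                        mMax = mMax), tol = tol)

  # integerize: constrained rows by bounded largest remainder over seeded
  # cells (row sums exact), free rows by plain rounding
  v <- matrix(0L, n, B)
  v[pub] <- as.integer(pp[pub])
  for (i in seq_len(n)) {
    sdc <- which(!pub[i, ])
    if (!length(sdc)) next
    if (known[i]) {
      v[i, sdc] <- intAllocate(M@p[i, sdc], Qi[i] - sum(pp[i, pub[i, ]]),
                               lo[i, sdc], hi[i, sdc])
    } else {
      v[i, sdc] <- as.integer(pmin(pmax(round(M@p[i, sdc]), ceiling(lo[i, sdc] - 1e-9)),
                                   floor(hi[i, sdc] + 1e-9)))
    }
  }
  fix <- .repairColumns(v, pub, lo, hi, Qj, freeRow = !known)
  v <- fix$v
  tot <- ifelse(known, Qi, rowSums(v))
  list(pop = v, total = as.numeric(tot),
       log = data.frame(parent_id = parent$unit_id, k = M@k,
                        converged = M@converged && fix$ok,
                        discrepancy = max(c(abs(rowSums(v)[known] - Qi[known]),
                                            abs(colSums(v) - Qj), 0)),
                        stringsAsFactors = FALSE))
}

# Controlled rounding: make integer column sums match Qj exactly without
# breaking exact row sums.  A unit moves from a surplus column to a deficit
# column along a chain of within-row transfers (a breadth-first search over
# columns finds the chain); free rows (redacted totals) can absorb single
# adjustments directly.
.repairColumns <- function(v, pub, lo, hi, Qj, freeRow) {
  loI <- ceiling(lo - 1e-9)
  hiI <- floor(hi + 1e-9)
  B <- ncol(v)
  # one within-row unit transfer from column a to column b
  canMove <- function(a, b)
    which(!pub[, a] & v[, a] > loI[, a] & !pub[, b] & v[, b] < hiI[, b])
  # move one unit from column jm to column jp through a chain of row moves
  chainMove <- function(jm, jp) {
    prev <- rep(NA_integer_, B)
    prevRow <- rep(NA_integer_, B)
    seen <- jm
    queue <- jm
    while (length(queue)) {
      a <- queue[1L]
      queue <- queue[-1L]
      for (b in setdiff(seq_len(B), seen)) {
        rows <- canMove(a, b)
        if (length(rows)) {
          prev[b] <- a
          prevRow[b] <- rows[1L]
          if (b == jp) {
            # unwind the chain
            while (!is.na(prev[b])) {
              i <- prevRow[b]
              a2 <- prev[b]
              v[i, b] <<- v[i, b] + 1L
              v[i, a2] <<- v[i, a2] - 1L
              b <- a2
            }
            return(TRUE)
          }
          seen <- c(seen, b)
          queue <- c(queue, b)
        }
      }
    }
    FALSE
  }
  guard <- 0L
  repeat {
    d <- round(Qj - colSums(v))
    net <- sum(d)
    if (all(d == 0) || guard > 100000L) break
    guard <- guard + 1L
    moved <- FALSE
    if (net > 0) {
      # grand total short: bump a free-row (redacted-total) cell, preferring
      # deficit columns
      for (j in order(d, decreasing = TRUE)) {
        ri <- which(freeRow & !pub[, j] & v[, j] < hiI[, j])
        if (length(ri)) {
          v[ri[1L], j] <- v[ri[1L], j] + 1L
          moved <- TRUE
          break
        }
      }
    } else if (net < 0) {
      for (j in order(d)) {
        ri <- which(freeRow & !pub[, j] & v[, j] > loI[, j])
        if (length(ri)) {
          v[ri[1L], j] <- v[ri[1L], j] - 1L
          moved <- TRUE
          break
        }
      }
    } else {
      jp <- which.max(d)
      jm <- which.min(d)
      moved <- chainMove(jm, jp)
      if (!moved) {
        # no row-sum-preserving chain: let free rows absorb the shift
        ri <- which(freeRow & !pub[, jp] & v[, jp] < hiI[, jp])
        if (length(ri)) {
          v[ri[1L], jp] <- v[ri[1L], jp] + 1L
          moved <- TRUE
        } else {
          ri <- which(freeRow & !pub[, jm] & v[, jm] > loI[, jm])
          if (length(ri)) {
            v[ri[1L], jm] <- v[ri[1L], jm] - 1L
            moved <- TRUE
          }
        }
      }
    }
    if (!moved) break
  }
  list(v = v, ok = all(round(Qj - colSums(v)) == 0))
}

#' Impute one hierarchical level
#'
#' Builds one pinned IPF matrix per parent unit (rows = its children, columns
#' = population-size bins; row totals from child population totals, seeded
#' where redacted; column totals from the parent's complete bin subtotals),
#' fits it, clamps every imputed cell into its [cellBounds()], and writes
#' back integer values whose row and column sums are exact.
#'
#' @param table a \linkS4class{CensusTable} whose parent level is complete.
#' @param childLevel \code{"state"} or \code{"county"}.
#' @param tol marginal tolerance in animals (default 0.5).
#' @param mMax IPF iteration cap (default 2000).
#' @return The table with the child level fully imputed; a convergence log
#'   (\code{parent_id, k, converged, discrepancy}) is attached as attribute
#'   \code{"convergenceLog"}.
#' @export
imputeLevel <- function(table, childLevel = c("state", "county"), tol = 0.5,
                        mMax = 2000L) {
  childLevel <- match.arg(childLevel)
  u <- censusUnits(table)
  schema <- censusSchema(table)
  parentLevel <- if (childLevel == "state") "national" else "state"
  logs <- list()
  for (pid in u$unit_id[u$level == parentLevel]) {
    idx <- which(u$level == childLevel & u$parent_id == pid)
    if (!length(idx)) next
    extra <- NULL
    if (childLevel == "state") {
      # aggregate county-level refined cell bounds into per-state bin bounds
      # so the state fit stays feasible for the county fits that follow
      natTotal <- u$pop_total[match(pid, u$unit_id)]
      kids <- u[idx, , drop = FALSE]
      exLo <- exHi <- matrix(NA_real_, length(idx), nBins(schema))
      for (r in seq_along(idx)) {
        cidx <- which(u$level == "county" & u$parent_id == kids$unit_id[r])
        if (!length(cidx)) {
          exLo[r, ] <- 0
          exHi[r, ] <- Inf
          next
        }
        capDef <- if (!is.na(kids$pop_total[r])) kids$pop_total[r] else natTotal
        cb <- .unitBoundsMatrix(u[cidx, , drop = FALSE], schema,
                                capDefault = capDef,
                                colTargets = as.numeric(kids[r, .popCols(schema)]))
        exLo[r, ] <- colSums(cb$lo)
        exHi[r, ] <- colSums(cb$hi)
      }
      extra <- list(lo = exLo, hi = exHi)
    }
    res <- .imputeParentBlock(u[idx, , drop = FALSE],
                              u[match(pid, u$unit_id), , drop = FALSE],
                              schema, tol, mMax,
                              extraLo = extra$lo, extraHi = extra$hi)
    u[idx, .popCols(schema)] <- res$pop
    u$pop_total[idx] <- res$total
    logs[[pid]] <- res$log
  }
  out <- censusTable(u, schema)
  attr(out, "convergenceLog") <- if (length(logs)) do.call(rbind, logs) else NULL
  out
}

#' Impute every redacted cell in a census table
#'
#' Two-step hierarchical imputation: missing state-level totals and subtotals
#' are estimated first against the national distribution, and the resulting
#' complete (but simulated) state-level frequency distributions are then
#' applied as marginals to estimate missing county-level data.
#'
#' @inheritParams imputeLevel
#' @return A complete \linkS4class{CensusTable} (zero redacted entries) with
#'   the combined convergence log attached as attribute
#'   \code{"convergenceLog"}.
#' @examples
#' syn <- makeCensus(synthConfig(nStates = 2, countiesPerState = 3))
#' imputeAll(syn$observed)
#' @export
imputeAll <- function(table, tol = 0.5, mMax = 2000L) {
  nat <- censusUnits(table)
  nat <- nat[nat$level == "national", , drop = FALSE]
  if (nrow(nat) && (anyNA(nat$pop_total) ||
                    anyNA(as.matrix(nat[, .popCols(censusSchema(table))]))))
    stop("national totals must be published")
  t1 <- imputeLevel(table, "state", tol = tol, mMax = mMax)
  t2 <- imputeLevel(t1, "county", tol = tol, mMax = mMax)
  attr(t2, "convergenceLog") <- rbind(attr(t1, "convergenceLog"),
                                      attr(t2, "convergenceLog"))
  t2
}
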