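#' @import methods
NULL

#' Population-size bin schema
#'
#' An ordered set of population-size classes over which agricultural-census
#' frequency distributions are reported.  The default schema is the seven-bin
#' hogs-and-pigs layout used by the U.S. Census of Agriculture: 1-24, 25-49,
#' 50-99, 100-199, 200-499, 500-999 and an unbounded >= 1000 class.
#'
#' @slot lower numeric vector of inclusive lower bounds.
#' @slot upper numeric vector of inclusive upper bounds; the last entry is
#'   \code{Inf} (the unbounded top class).
#' @export
setClass("BinSchema", representation(lower = "numeric", upper = "numeric"))

setValidity("BinSchema", function(object) {
  lo <- object@lower
  up <- object@upper
  if (length(lo) != length(up)) return("lower and upper must have equal length")
  if (length(lo) < 1L) return("schema needs at least one bin")
  if (any(lo > up)) return("bin lower bounds exceed upper bounds")
  if (!all(is.infinite(up) == (seq_along(up) == length(up))))
    return("exactly the last bin must be unbounded")
  if (length(lo) > 1L) {
    if (any(diff(lo) <= 0)) return("bins must be ascending")
    if (any(lo[-1L] != up[-length(up)] + 1)) return("bins must be contiguous and disjoint")
  }
  TRUE
})

#' Construct a bin schema
#'
#' @param lower,upper inclusive bin bounds; the last upper bound must be
#'   \code{Inf}.  Defaults give the seven-bin hogs-and-pigs layout.
#' @return A \linkS4class{BinSchema}.
#' @examples
#' binSchema()
#' @export
binSchema <- function(lower = c(1, 25, 50, 100, 200, 500, 1000),
                      upper = c(24, 49, 99, 199, 499, 999, Inf)) {
  new("BinSchema", lower = as.numeric(lower), upper = as.numeric(upper))
}

#' @describeIn binSchema number of bins.
#' @param schema a \linkS4class{BinSchema}.
#' @export
nBins <- function(schema) length(schema@lower)

#' @describeIn binSchema inclusive lower bounds.
#' @export
binLower <- function(schema) schema@lower

#' @describeIn binSchema inclusive upper bounds (last is \code{Inf}).
#' @export
binUpper <- function(schema) schema@upper

setMethod("show", "BinSchema", function(object) {
  up <- ifelse(is.infinite(object@upper), ">=", format(object@upper))
  lab <- ifelse(is.infinite(object@upper),
                paste0(">=", format(object@lower)),
                paste0(object@lower, "-", object@upper))
  cat("BinSchema with", nBins(object), "classes:", paste(lab, collapse = ", "), "\n")
})

.censusLevels <- c("national", "state", "county")

.nfarmCols <- function(schema) paste0("nfarms_b", seq_len(nBins(schema)))
.popCols <- function(schema) paste0("pop_b", seq_len(nBins(schema)))

#' Hierarchical census table
#'
#' A collection of national/state/county administrative units, each carrying a
#' paired frequency distribution: the number of farms per population-size bin
#' (never redacted) and the aggregate animal population per bin plus a grand
#' total (either published integers or redacted, stored as \code{NA}).
#'
#' @slot units a \code{data.frame} with columns \code{unit_id}, \code{level},
#'   \code{parent_id}, \code{nfarms_b1..nfarms_bB}, \code{pop_b1..pop_bB} and
#'   \code{pop_total}.  Redacted population cells are \code{NA}; farm counts
#'   are always concrete.
#' @slot schema the \linkS4class{BinSchema} the bins refer to.
#' @seealso [readCensus()], [validateCensus()], [imputeAll()]
#' @export
setClass("CensusTable", representation(units = "data.frame", schema = "BinSchema"))

setValidity("CensusTable", function(object) {
  u <- object@units
  schema <- object@schema
  need <- c("unit_id", "level", "parent_id", .nfarmCols(schema), .popCols(schema), "pop_total")
  miss <- setdiff(need, names(u))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(u$unit_id)) return("duplicate unit_id")
  if (!all(u$level %in% .censusLevels))
    return(paste("unknown level:", paste(setdiff(u$level, .censusLevels), collapse = ", ")))
  nf <- as.matrix(u[, .nfarmCols(schema)])
  if (anyNA(nf) || any(nf < 0)) return("farm counts must be concrete and non-negative")
  # referential integrity: every non-national unit must point at an existing
  # unit one level up
  for (i in seq_len(nrow(u))) {
    lev <- u$level[i]
    if (lev == "national") next
    want <- if (lev == "state") "national" else "state"
    j <- match(u$parent_id[i], u$unit_id)
    if (is.na(j) || u$level[j] != want)
      return(paste0("unit ", u$unit_id[i], " (", lev, ") has no ", want,
                    " parent '", u$parent_id[i], "'"))
  }
  TRUE
})

#' Construct a census table
#'
#' @param units units data.frame (see \linkS4class{CensusTable}).
#' @param schema bin schema; default [binSchema()].
#' @return A validated \linkS4class{CensusTable}.
#' @export
censusTable <- function(units, schema = binSchema()) {
  units$unit_id <- as.character(units$unit_id)
  units$level <- as.character(units$level)
  units$parent_id <- as.character(units$parent_id)
  rownames(units) <- NULL
  new("CensusTable", units = units, schema = schema)
}

#' @describeIn censusTable the units data.frame.
#' @param table a \linkS4class{CensusTable}.
#' @export
censusUnits <- function(table) table@units

#' @describeIn censusTable the bin schema.
#' @export
censusSchema <- function(table) table@schema

setMethod("show", "CensusTable", function(object) {
  u <- object@units
  nred <- sum(is.na(as.matrix(u[, c(.popCols(object@schema), "pop_total")])))
  cat("CensusTable:", sum(u$level == "national"), "national,",
      sum(u$level == "state"), "state,", sum(u$level == "county"), "county units;",
      nred, "redacted population cells\n")
})

#' Model-averaged logistic occurrence model
#'
#' Coefficients of a farm-occurrence logistic regression averaged over a set
#' of supported candidate models (Akaike weights), together with the
#' functional form (linear or quadratic) of each covariate.
#'
#' @slot beta named numeric coefficients including \code{"(Intercept)"}.
#' @slot forms named character vector, \code{"linear"} or \code{"quadratic"}
#'   per covariate; a quadratic form means the squared covariate enters the
#'   linear predictor (no paired linear term).
#' @seealso [modelAverage()], [builtinSwineModel()], [predictSurface()]
#' @export
setClass("AveragedModel", representation(beta = "numeric", forms = "character"))

setValidity("AveragedModel", function(object) {
  if (!"(Intercept)" %in% names(object@beta)) return("beta must include '(Intercept)'")
  terms <- setdiff(names(object@beta), "(Intercept)")
  if (!setequal(terms, names(object@forms))) return("forms must name every non-intercept term")
  if (!all(object@forms %in% c("linear", "quadratic"))) return("forms must be linear/quadratic")
  if (anyNA(object@beta)) return("coefficients must be finite")
  TRUE
})

#' Construct an averaged occurrence model
#'
#' @param beta named coefficients including \code{"(Intercept)"}.
#' @param forms named character vector (\code{"linear"}/\code{"quadratic"}) for
#'   each non-intercept term.
#' @return An \linkS4class{AveragedModel}.
#' @export
averagedModel <- function(beta, forms) {
  new("AveragedModel", beta = beta, forms = forms)
}

setMethod("show", "AveragedModel", function(object) {
  terms <- setdiff(names(object@beta), "(Intercept)")
  lab <- ifelse(object@forms[terms] == "quadratic", paste0(terms, "^2"), terms)
  cat("AveragedModel: logit(y) =",
      paste(sprintf("%+.3g*%s", object@beta[terms], lab), collapse = " "),
      sprintf("%+.3g\n", object@beta["(Intercept)"]))
})

#' Occurrence probability surface
#'
#' A gridded farm-occurrence probability raster (nominally 100 m pixels), the
#' availability state of each pixel (masked pixels and pixels excluded by
#' previously placed farms are unavailable), a geotransform mapping pixels to
#' geographic coordinates, and a per-pixel county index.
#'
#' @slot prob numeric matrix of occurrence probabilities in [0, 1].
#' @slot available logical matrix; \code{FALSE} = masked or excluded.
#' @slot occupied logical matrix; \code{TRUE} = a farm sits on the pixel.
#' @slot geotransform named numeric \code{c(xll, yll, cellsize)} (lower-left
#'   corner and square cell size, decimal degrees).
#' @slot county integer matrix indexing into \code{countyIds} (0 = no county).
#' @slot countyIds character vector of county unit ids.
#' @seealso [predictSurface()], [placeFarms()]
#' @export
setClass("ProbabilitySurface",
         representation(prob = "matrix", available = "matrix",
                        occupied = "matrix", geotransform = "numeric",
                        county = "matrix", countyIds = "character"))

setValidity("ProbabilitySurface", function(object) {
  d <- dim(object@prob)
  if (!identical(dim(object@available), d) || !identical(dim(object@county), d) ||
      !identical(dim(object@occupied), d))
    return("prob, available, occupied and county must share dimensions")
  p <- object@prob
  if (any(p < 0 | p > 1, na.rm = TRUE)) return("probabilities must lie in [0, 1]")
  gt <- object@geotransform
  if (length(gt) != 3L || any(is.na(gt)) || gt[3L] <= 0)
    return("geotransform must be c(xll, yll, cellsize) with cellsize > 0")
  ci <- object@county
  if (any(ci < 0 | ci > length(object@countyIds), na.rm = TRUE))
    return("county indices out of range")
  TRUE
})

#' Construct a probability surface
#'
#' @param prob probability matrix in [0, 1].
#' @param available logical availability matrix (default: all pixels).
#' @param geotransform \code{c(xll, yll, cellsize)}; default is an
#'   identity-like transform with 0.001-degree (~100 m) cells anchored at
#'   (-100, 35).
#' @param county integer matrix of county indices (0 = none); default assigns
#'   every pixel to a single county.
#' @param countyIds character ids matching the county indices.
#' @return A \linkS4class{ProbabilitySurface}.
#' @export
probabilitySurface <- function(prob,
                               available = NULL,
                               geotransform = c(xll = -100, yll = 35, cellsize = 0.001),
                               county = NULL,
                               countyIds = "00001") {
  if (is.null(available)) available <- matrix(TRUE, nrow(prob), ncol(prob))
  if (is.null(county)) county <- matrix(1L, nrow(prob), ncol(prob))
  storage.mode(county) <- "integer"
  new("ProbabilitySurface", prob = prob, available = available,
      occupied = matrix(FALSE, nrow(prob), ncol(prob)),
      geotransform = stats::setNames(as.numeric(geotransform), c("xll", "yll", "cellsize")),
      county = county, countyIds = countyIds)
}

setMethod("show", "ProbabilitySurface", function(object) {
  cat("ProbabilitySurface:", nrow(object@prob), "x", ncol(object@prob),
      "pixels;", sum(object@available), "available;",
      length(object@countyIds), "counties; cellsize",
      object@geotransform["cellsize"], "\n")
})

#' Verification report
#'
#' Absolute-percent-difference (APD) summaries from a reaggregation or
#' substitution verification analysis.
#'
#' @slot metric short label of the analysis.
#' @slot perUnit data.frame \code{unit_id, level, apd} (NA = undefined APD).
#' @slot summary data.frame \code{level, mean, se, n, n_undefined}; the
#'   standard error is computed over iterations where the analysis is
#'   iterated, otherwise reported as \code{NA}.
#' @slot iterations number of Monte-Carlo iterations behind the summary.
#' @slot seed RNG seed used (NA if the analysis is deterministic).
#' @export
setClass("VerificationReport",
         representation(metric = "character", perUnit = "data.frame",
                        summary = "data.frame", iterations = "integer",
                        seed = "integer"))

setValidity("VerificationReport", function(object) {
  if (!all(c("unit_id", "level", "apd") %in% names(object@perUnit)))
    return("perUnit needs unit_id, level, apd")
  if (any(object@perUnit$apd < 0, na.rm = TRUE)) return("APD must be non-negative")
  TRUE
})

setMethod("show", "VerificationReport", function(object) {
  cat("VerificationReport [", object@metric, "], ",
      object@iterations, " iteration(s)\n", sep = "")
  print(object@summary, row.names = FALSE)
})
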