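# Synthetic-data generators: census tables, landscapes and presence/absence
# samples with known ground truth, so every pipeline stage is testable
# without the real census extract or covariate layers.

#' Synthetic-scenario configuration
#'
#' Defaults emulate the study system: per-county farm counts follow the
#' national seven-bin shape (most farms small, most animals on the largest
#' farms) at roughly 20 farms per county; population totals of counties with
#' fewer than 16 farms are redacted, along with bin cells backed by one or
#' two farms and complementary-suppression partners, which yields roughly
#' 19\% of county totals redacted; the landscape carries the ten occurrence
#' covariates as smooth random fields on ranges where the built-in swine
#' equation produces realistic occurrence probabilities; and the
#' presence/absence sampling targets the observed prevalence of 0.14.
#'
#' @param nStates,countiesPerState hierarchy size.
#' @param farmLambda Poisson mean farm count per county and bin (length 7).
#' @param bin7PopRange uniform range of true farm populations in the
#'   unbounded bin.
#' @param redactThreshold county population totals are redacted when the
#'   county has fewer than this many farms.
#' @param binRedactMax bin cells backed by 1..binRedactMax farms are
#'   redacted.
#' @param rows,cols landscape grid size.
#' @param trueBeta,trueForms true occurrence model (defaults: the built-in
#'   swine equation).
#' @param covariateRanges named list of \code{c(min, max)} scaling for each
#'   covariate field.
#' @param maskFraction fraction of pixels masked (urban/water analog).
#' @param prevalence target presence prevalence of the sample.
#' @param sampleSize presence/absence sample size.
#' @param seed default RNG seed for the generators.
#' @return A list of class \code{"SynthConfig"}.
#' @export
synthConfig <- function(nStates = 6L, countiesPerState = 8L,
                        farmLambda = 20 * c(41688, 3435, 2161, 1469, 2115,
                                            1977, 10401) / 63246,
                        bin7PopRange = c(1000, 20000),
                        redactThreshold = 16L, binRedactMax = 2L,
                        rows = 80L, cols = 80L,
                        trueBeta = NULL, trueForms = NULL,
                        covariateRanges = NULL,
                        maskFraction = 0.1, prevalence = 0.14,
                        sampleSize = 10000L, seed = 42L) {
  if (is.null(trueBeta)) {
    m <- builtinSwineModel()
    trueBeta <- coef(m)
    trueForms <- m@forms
  }
  if (is.null(covariateRanges))
    covariateRanges <- list(dOpen = c(0, 600), dCrop = c(0, 2000),
                            Temp = c(5, 20), dRoads = c(0, 1000),
                            Slope = c(0, 8), Precip = c(300, 1500),
                            dForest = c(0, 3000), dUrban = c(0, 20000),
                            dWetland = c(0, 5000), dBarren = c(0, 20000))
  stopifnot(length(farmLambda) == 7L, all(farmLambda >= 0),
            prevalence > 0, prevalence < 1)
  structure(list(nStates = as.integer(nStates),
                 countiesPerState = as.integer(countiesPerState),
                 farmLambda = farmLambda, bin7PopRange = bin7PopRange,
                 redactThreshold = as.integer(redactThreshold),
                 binRedactMax = as.integer(binRedactMax),
                 rows = as.integer(rows), cols = as.integer(cols),
                 trueBeta = trueBeta, trueForms = trueForms,
                 covariateRanges = covariateRanges,
                 maskFraction = maskFraction, prevalence = prevalence,
                 sampleSize = as.integer(sampleSize),
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

.stateId <- function(s) sprintf("%02d", s)
.countyId <- function(s, c) sprintf("%02d%03d", s, c)

#' Generate a synthetic census hierarchy
#'
#' Simulates per-county farm counts and within-bin farm populations,
#' aggregates them upward so the hierarchy is exactly consistent, then
#' applies NASS-style disclosure rules to produce the observed (redacted)
#' version: bin cells backed by very few farms and the totals of small
#' counties are withheld, and when a lone redaction would be recoverable
#' from its published siblings the smallest sibling is withheld too
#' (complementary suppression).
#'
#' @param cfg a [synthConfig()].
#' @param seed RNG seed (default \code{cfg$seed}).
#' @return List with \code{truth} (complete \linkS4class{CensusTable}) and
#'   \code{observed} (same table with redactions).
#' @export
makeCensus <- function(cfg = synthConfig(), seed = cfg$seed) {
  schema <- binSchema()
  B <- nBins(schema)
  lo <- binLower(schema)
  up <- binUpper(schema)
  withSeed(seed, {
    rows <- list()
    for (s in seq_len(cfg$nStates)) {
      for (cc in seq_len(cfg$countiesPerState)) {
        nf <- stats::rpois(B, cfg$farmLambda)
        pop <- numeric(B)
        for (b in seq_len(B)) {
          if (nf[b] == 0) next
          pop[b] <- if (b < B)
            sum(sample(lo[b]:up[b], nf[b], replace = TRUE))
          else
            sum(round(stats::runif(nf[b], cfg$bin7PopRange[1L],
                                   cfg$bin7PopRange[2L])))
        }
        rows[[length(rows) + 1L]] <-
          c(list(unit_id = .countyId(s, cc), level = "county",
                 parent_id = .stateId(s)),
            as.list(nf), as.list(pop), list(pop_total = sum(pop)))
      }
    }
    cols <- c("unit_id", "level", "parent_id", .nfarmCols(schema),
              .popCols(schema), "pop_total")
    u <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(stats::setNames(r, cols), stringsAsFactors = FALSE)))
    # aggregate states and the national unit
    agg <- function(ids, id, level, parent) {
      k <- u[u$unit_id %in% ids, , drop = FALSE]
      out <- data.frame(unit_id = id, level = level, parent_id = parent,
                        stringsAsFactors = FALSE)
      for (ccol in c(.nfarmCols(schema), .popCols(schema), "pop_total"))
        out[[ccol]] <- sum(k[[ccol]])
      out
    }
    st <- do.call(rbind, lapply(seq_len(cfg$nStates), function(s)
      agg(u$unit_id[u$parent_id == .stateId(s)], .stateId(s), "state", "00")))
    u <- rbind(u, st,
               local({
                 nat <- agg(st$unit_id, "00", "national", NA_character_)
                 # national aggregates over states directly
                 for (ccol in c(.nfarmCols(schema), .popCols(schema), "pop_total"))
                   nat[[ccol]] <- sum(st[[ccol]])
                 nat
               }))
    truth <- censusTable(u, schema)
    observed <- censusTable(.redactUnits(u, schema, cfg), schema)
    list(truth = truth, observed = observed)
  })
}

# Disclosure rules applied to a complete units data.frame.
.redactUnits <- function(u, schema, cfg) {
  B <- nBins(schema)
  nfc <- .nfarmCols(schema)
  ppc <- .popCols(schema)
  for (i in which(u$level %in% c("county", "state"))) {
    nf <- as.numeric(u[i, nfc])
    for (b in seq_len(B))
      if (nf[b] >= 1 && nf[b] <= cfg$binRedactMax) u[[ppc[b]]][i] <- NA_real_
    if (u$level[i] == "county" && sum(nf) < cfg$redactThreshold)
      u$pop_total[i] <- NA_real_
    if (u$level[i] == "state" && sum(nf) < cfg$redactThreshold)
      u$pop_total[i] <- NA_real_
  }
  .complementarySuppression(u, schema)
}

# A lone redacted cell is recoverable from its published siblings, so the
# smallest published sibling is also withheld.
.complementarySuppression <- function(u, schema, maxPass = 4L) {
  B <- nBins(schema)
  ppc <- .popCols(schema)
  for (pass in seq_len(maxPass)) {
    changed <- FALSE
    # within each unit's bins: one redacted bin + published total is forced
    for (i in which(u$level %in% c("county", "state"))) {
      pv <- as.numeric(u[i, ppc])
      red <- which(is.na(pv))
      if (length(red) == 1L && !is.na(u$pop_total[i])) {
        pub <- which(!is.na(pv) & pv > 0)
        if (length(pub)) {
          j <- pub[which.min(pv[pub])]
          u[[ppc[j]]][i] <- NA_real_
          changed <- TRUE
        } else {
          u$pop_total[i] <- NA_real_
          changed <- TRUE
        }
      }
    }
    # within each parent's children: one redacted total is forced
    for (lev in c("county", "state")) {
      kidIdx <- which(u$level == lev)
      for (pid in unique(u$parent_id[kidIdx])) {
        j <- match(pid, u$unit_id)
        if (is.na(j) || is.na(u$pop_total[j])) next
        k <- kidIdx[u$parent_id[kidIdx] == pid]
        red <- k[is.na(u$pop_total[k])]
        if (length(red) == 1L) {
          pub <- k[!is.na(u$pop_total[k])]
          if (length(pub)) {
            u$pop_total[pub[which.min(u$pop_total[pub])]] <- NA_real_
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  u
}

# Seeded smooth random field in [0, 1]: a low-frequency cosine mixture
# f(r, c) = sum_k a_k cos(2 pi (u_k r / R + v_k c / C) + phi_k), min-max
# normalized.
.smoothField <- function(rows, cols, K = 6L) {
  r <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  f <- matrix(0, rows, cols)
  for (k in seq_len(K)) {
    u <- stats::runif(1, 0.5, 3)
    v <- stats::runif(1, 0.5, 3)
    a <- stats::runif(1, 0.5, 1) / k
    phi <- stats::runif(1, 0, 2 * pi)
    f <- f + a * cos(2 * pi * (u * r / rows + v * cc / cols) + phi)
  }
  (f - min(f)) / (max(f) - min(f))
}

#' Generate a synthetic landscape
#'
#' Builds smooth random fields for the ten occurrence covariates on the
#' configured grid, a boolean exclusion mask from a thresholded extra field,
#' a county tiling matching the synthetic census geography, and the true
#' occurrence-probability surface (inverse logit of the configured true
#' coefficients).
#'
#' @inheritParams makeCensus
#' @return List with \code{stack} (named covariate matrices), \code{mask}
#'   (logical matrix, TRUE = excluded), \code{surface} (the true
#'   \linkS4class{ProbabilitySurface}), \code{county}/\code{countyIds} and
#'   \code{geotransform}.
#' @export
makeLandscape <- function(cfg = synthConfig(), seed = cfg$seed + 1L) {
  covs <- names(cfg$covariateRanges)
  withSeed(seed, {
    stack <- lapply(covs, function(v) {
      rg <- cfg$covariateRanges[[v]]
      rg[1L] + (rg[2L] - rg[1L]) * .smoothField(cfg$rows, cfg$cols)
    })
    names(stack) <- covs
    maskField <- .smoothField(cfg$rows, cfg$cols)
    mask <- maskField > stats::quantile(maskField, 1 - cfg$maskFraction)
    # rectangular county tiling: states are row bands, counties split columns
    nC <- cfg$nStates * cfg$countiesPerState
    countyIds <- as.vector(vapply(seq_len(cfg$nStates), function(s)
      vapply(seq_len(cfg$countiesPerState), function(cc) .countyId(s, cc),
             character(1)), character(cfg$countiesPerState)))
    band <- pmin(1L + (seq_len(cfg$rows) - 1L) %/% ceiling(cfg$rows / cfg$nStates),
                 cfg$nStates)
    strip <- pmin(1L + (seq_len(cfg$cols) - 1L) %/% ceiling(cfg$cols / cfg$countiesPerState),
                  cfg$countiesPerState)
    county <- matrix(0L, cfg$rows, cfg$cols)
    for (r in seq_len(cfg$rows))
      county[r, ] <- (band[r] - 1L) * cfg$countiesPerState + strip
    gt <- c(xll = -100, yll = 35, cellsize = 0.001)
    m <- averagedModel(cfg$trueBeta, cfg$trueForms)
    surface <- predictSurface(m, stack, mask = mask, geotransform = gt,
                              county = county, countyIds = countyIds)
    list(stack = stack, mask = mask, surface = surface, county = county,
         countyIds = countyIds, geotransform = gt)
  })
}

#' Sample presence/absence points over a synthetic landscape
#'
#' Allocates sample points to counties proportionally to their published
#' farm counts (the weighted sampling design), draws point locations
#' uniformly among each county's unmasked pixels, labels each point
#' Bernoulli(true occurrence probability), and continues sampling until the
#' target prevalence quota is filled, recording the covariate values at
#' every point.
#'
#' @inheritParams makeCensus
#' @param landscape output of [makeLandscape()].
#' @param census a \linkS4class{CensusTable} providing county farm counts
#'   (the observed table works: farm counts are never redacted).
#' @param n sample size (default \code{cfg$sampleSize}).
#' @return Data.frame with columns \code{y}, the ten covariates, and
#'   \code{county}.
#' @export
samplePA <- function(cfg, landscape, census, n = cfg$sampleSize,
                     seed = cfg$seed + 2L) {
  u <- censusUnits(census)
  schema <- censusSchema(census)
  counties <- u[u$level == "county", , drop = FALSE]
  farms <- rowSums(as.matrix(counties[, .nfarmCols(schema)]))
  wt <- stats::setNames(farms / sum(farms), counties$unit_id)
  surf <- landscape$surface
  trueP <- surf@prob
  ok <- !landscape$mask
  pixByCounty <- lapply(stats::setNames(seq_along(landscape$countyIds),
                                        landscape$countyIds),
                        function(ci) which(landscape$county == ci & ok))
  pixByCounty <- pixByCounty[names(wt)[names(wt) %in% names(pixByCounty)]]
  pixByCounty <- pixByCounty[lengths(pixByCounty) > 0L]
  wt <- wt[names(pixByCounty)]
  wt <- wt / sum(wt)
  n1 <- round(n * cfg$prevalence)
  n0 <- n - n1
  covs <- names(landscape$stack)
  withSeed(seed, {
    got1 <- 0L
    got0 <- 0L
    pixSel <- integer(n)
    ySel <- integer(n)
    cidSel <- character(n)
    filled <- 0L
    guard <- 0L
    # sample in chunks: draw county-weighted points, label against the true
    # surface, keep what the prevalence quota still needs
    while ((got1 < n1 || got0 < n0) && guard < 400L) {
      guard <- guard + 1L
      m <- max(n, 1000L)
      cid <- sample(names(wt), m, replace = TRUE, prob = wt)
      p <- vapply(cid, function(ci) {
        pix <- pixByCounty[[ci]]
        pix[sample.int(length(pix), 1L)]
      }, integer(1))
      y <- stats::rbinom(m, 1L, trueP[p])
      for (i in seq_len(m)) {
        if (y[i] == 1L && got1 >= n1) next
        if (y[i] == 0L && got0 >= n0) next
        if (y[i] == 1L) got1 <- got1 + 1L else got0 <- got0 + 1L
        filled <- filled + 1L
        pixSel[filled] <- p[i]
        ySel[filled] <- y[i]
        cidSel[filled] <- cid[i]
        if (got1 >= n1 && got0 >= n0) break
      }
    }
    if (got1 < n1 || got0 < n0)
      warning(sprintf("prevalence quota not met: %d/%d presences, %d/%d absences",
                      got1, n1, got0, n0))
    keep <- seq_len(filled)
    out <- data.frame(y = ySel[keep], stringsAsFactors = FALSE)
    for (v in covs) out[[v]] <- landscape$stack[[v]][pixSel[keep]]
    out$county <- cidSel[keep]
    out[sample.int(nrow(out)), , drop = FALSE] -> out
    rownames(out) <- NULL
    out
  })
}

#' Simulate presence/absence data in covariate space
#'
#' Draws i.i.d. standard-normal covariates and Bernoulli labels from a known
#' logistic model -- the minimal ground-truth generator for exercising model
#' selection, averaging and cross-validation without a landscape.
#'
#' @param n sample size.
#' @param beta named true coefficients including \code{"(Intercept)"}.
#' @param forms named forms per covariate (default all linear).
#' @param extraCovariates names of additional pure-noise covariates.
#' @param seed RNG seed.
#' @return Data.frame with \code{y} and one column per covariate.
#' @export
simulatePASample <- function(n, beta, forms = NULL, extraCovariates = character(0),
                             seed = 1L) {
  terms <- setdiff(names(beta), "(Intercept)")
  if (is.null(forms)) forms <- stats::setNames(rep("linear", length(terms)), terms)
  withSeed(seed, {
    covs <- c(terms, extraCovariates)
    X <- as.data.frame(stats::setNames(
      lapply(covs, function(v) stats::rnorm(n)), covs))
    eta <- rep(beta[["(Intercept)"]], n)
    for (v in terms) eta <- eta + beta[[v]] * .designColumn(X, v, forms[[v]])
    X$y <- stats::rbinom(n, 1L, stats::plogis(eta))
    X[, c("y", covs)]
  })
}
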