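# Distribution model: logistic farm-occurrence models with Spearman
# collinearity screening, per-covariate form choice, all-subsets AIC ranking,
# and multi-model (Akaike-weight) coefficient averaging.

.paCovariates <- function(s, covariates = NULL) {
  if (is.null(covariates)) covariates <- setdiff(names(s), c("y", "county"))
  if (!all(covariates %in% names(s)))
    stop("unknown covariates: ", paste(setdiff(covariates, names(s)), collapse = ", "))
  covariates
}

.designColumn <- function(s, v, form) {
  x <- as.numeric(s[[v]])
  if (identical(form, "quadratic")) x^2 else x
}

# Fast logistic fit on a prebuilt design matrix; returns NULL on failure.
# A fit that exhausts its iterations but has finite coefficients (complete
# separation drives estimates to the boundary) is kept and flagged.
.fitLogit <- function(X, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                    control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients) ||
      any(!is.finite(fit$coefficients)))
    return(NULL)
  p <- fit$rank
  ll <- (2 * p - fit$aic) / 2
  list(coef = fit$coefficients, logLik = ll, aic = fit$aic,
       converged = isTRUE(fit$converged))
}

#' Screen collinear covariates
#'
#' Computes pairwise Spearman rank correlations and, for every pair with
#' \code{|r| >= threshold}, drops exactly one member.  The caller's
#' preference order decides which member survives (e.g. preferring distance
#' to roads over distance to development, and slope over ruggedness);
#' covariates named earlier in \code{prefer} are retained.
#'
#' @param s presence/absence sample: data.frame with column \code{y} (0/1)
#'   and one column per covariate (an optional \code{county} column is
#'   ignored).
#' @param threshold absolute Spearman correlation above which a pair is
#'   considered collinear (default 0.7).
#' @param prefer character vector of covariates to retain preferentially.
#' @return A list with \code{retained} (character) and \code{dropped}
#'   (data.frame \code{dropped, kept, r}).
#' @export
screenCollinearity <- function(s, threshold = 0.7, prefer = NULL) {
  covs <- .paCovariates(s)
  if (length(covs) < 2L) stop("need at least two covariates")
  X <- as.matrix(s[, covs])
  if (any(apply(X, 2, function(v) length(unique(v)) == 1L)))
    stop("constant covariate: correlation undefined")
  r <- stats::cor(X, method = "spearman")
  ord <- c(intersect(prefer, covs), setdiff(covs, prefer))
  retained <- character(0)
  dropped <- list()
  for (v in ord) {
    hit <- retained[abs(r[v, retained]) >= threshold]
    if (length(hit)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(dropped = v, kept = hit[1L], r = r[v, hit[1L]],
                   stringsAsFactors = FALSE)
    } else {
      retained <- c(retained, v)
    }
  }
  list(retained = retained[order(match(retained, covs))],
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(dropped = character(), kept = character(),
                                 r = numeric(), stringsAsFactors = FALSE))
}

#' Choose linear or quadratic form for a covariate
#'
#' Fits the two single-covariate logistic regressions \code{y ~ x} and
#' \code{y ~ x^2} and returns the form with the lower AIC (ties go to
#' linear).  Complete separation is flagged with a warning but a form is
#' still returned.
#'
#' @inheritParams screenCollinearity
#' @param cov covariate name.
#' @return \code{"linear"} or \code{"quadratic"}.
#' @export
chooseForm <- function(s, cov) {
  y <- as.numeric(s$y)
  x <- as.numeric(s[[cov]])
  n <- length(y)
  lin <- .fitLogit(cbind(1, x), y)
  quad <- .fitLogit(cbind(1, x^2), y)
  if (is.null(lin) || is.null(quad)) stop("logistic fit failed for ", cov)
  if (!lin$converged || !quad$converged)
    warning("possible separation for covariate ", cov)
  if (quad$aic < lin$aic) "quadratic" else "linear"
}

#' Fit all subsets of a global logistic model
#'
#' Fits every subset of the supplied covariates (including the intercept-only
#' model), each covariate entering with its linear or quadratic form, and
#' ranks the candidates by AIC difference from the best model.
#'
#' @inheritParams screenCollinearity
#' @param covariates covariate names of the global model (at most 15).
#' @param forms named character vector of forms; by default chosen per
#'   covariate with [chooseForm()].
#' @return A list of candidate models sorted by AIC, each a list with
#'   \code{terms}, \code{forms}, \code{coef} (named, including
#'   \code{"(Intercept)"}), \code{logLik}, \code{aic}, \code{delta}.
#'   Non-convergent subsets are skipped with a message.
#' @export
allSubsets <- function(s, covariates = NULL, forms = NULL) {
  covs <- .paCovariates(s, covariates)
  if (length(covs) > 15L) stop("more than 15 covariates (2^15 subset cap)")
  if (is.null(forms))
    forms <- vapply(covs, function(v) chooseForm(s, v), character(1))
  forms <- forms[covs]
  y <- as.numeric(s$y)
  X <- vapply(covs, function(v) .designColumn(s, v, forms[[v]]),
              numeric(nrow(s)))
  models <- list()
  for (mask in 0:(2^length(covs) - 1L)) {
    sel <- covs[bitwAnd(mask, bitwShiftL(1L, seq_along(covs) - 1L)) != 0L]
    fit <- .fitLogit(cbind(1, X[, sel, drop = FALSE]), y)
    if (is.null(fit)) {
      message("skipping failed subset {", paste(sel, collapse = ","), "}")
      next
    }
    if (!fit$converged)
      message("possible separation in subset {", paste(sel, collapse = ","),
              "}; model kept")
    cf <- stats::setNames(fit$coef, c("(Intercept)", sel))
    models[[length(models) + 1L]] <-
      list(terms = sel, forms = forms[sel], coef = cf,
           logLik = fit$logLik, aic = fit$aic, delta = NA_real_)
  }
  if (!length(models)) stop("no candidate model converged")
  aics <- vapply(models, `[[`, numeric(1), "aic")
  models <- models[order(aics)]
  best <- min(aics)
  lapply(models, function(m) {
    m$delta <- m$aic - best
    m
  })
}

#' Average coefficients over supported candidate models
#'
#' Multi-model inference over all candidates within an AIC window of the best
#' model (conventionally \code{delta <= 2}): Akaike weights
#' \code{w_i = exp(-delta_i / 2)} normalized over the window set, with
#' full-model (shrinkage) averaging -- a coefficient counts as 0 in models
#' where the term is absent.  The intercept is averaged with the same
#' weights.
#'
#' @param models candidate list from [allSubsets()].
#' @param window AIC-difference window (default 2); 0 reduces to the single
#'   best model.
#' @return An \linkS4class{AveragedModel}.
#' @export
modelAverage <- function(models, window = 2) {
  deltas <- vapply(models, `[[`, numeric(1), "delta")
  sel <- models[deltas <= window + 1e-12]
  if (!length(sel)) stop("no candidate model within the AIC window")
  w <- exp(-vapply(sel, `[[`, numeric(1), "delta") / 2)
  w <- w / sum(w)
  terms <- unique(unlist(lapply(sel, `[[`, "terms")))
  beta <- stats::setNames(numeric(length(terms) + 1L), c("(Intercept)", terms))
  for (i in seq_along(sel)) {
    cf <- sel[[i]]$coef
    beta[names(cf)] <- beta[names(cf)] + w[i] * cf
  }
  forms <- stats::setNames(character(length(terms)), terms)
  for (m in sel) forms[m$terms] <- m$forms
  if (length(terms) == 0L) forms <- stats::setNames(character(0), character(0))
  averagedModel(beta, forms)
}

#' Built-in national swine occurrence model
#'
#' The published model-averaged logistic equation for swine-farm occurrence
#' in the conterminous U.S.: distances to open areas, cropland and roads and
#' mean annual temperature enter linearly; slope, precipitation and distances
#' to forest, high-intensity urban areas, wetlands and barren land enter as
#' squared terms.  Distances are in meters, temperature in degrees C, slope
#' in degrees, precipitation in mm.
#'
#' @return An \linkS4class{AveragedModel}.
#' @examples
#' m <- builtinSwineModel()
#' plogis(coef(m)["(Intercept)"])  # occurrence probability with all covariates 0
#' @export
builtinSwineModel <- function() {
  beta <- c("(Intercept)" = -5.63e-2,
            dOpen = -5.66e-3, dCrop = -4.12e-4, Temp = -8.51e-3,
            dRoads = -1.48e-3, Slope = -2.62e-2, Precip = 3.29e-7,
            dForest = -4.84e-9, dUrban = -2.95e-10, dWetland = -1.28e-9,
            dBarren = -2.58e-10)
  forms <- c(dOpen = "linear", dCrop = "linear", Temp = "linear",
             dRoads = "linear", Slope = "quadratic", Precip = "quadratic",
             dForest = "quadratic", dUrban = "quadratic",
             dWetland = "quadratic", dBarren = "quadratic")
  averagedModel(beta, forms)
}

#' @describeIn builtinSwineModel coefficients of an averaged model.
#' @param object an \linkS4class{AveragedModel}.
#' @param ... ignored.
#' @export
setMethod("coef", "AveragedModel", function(object, ...) object@beta)

#' Predict from an averaged occurrence model
#'
#' @param object an \linkS4class{AveragedModel}.
#' @param newdata data.frame (or named list of equal-length vectors) holding
#'   every model covariate on its natural scale (squaring for quadratic terms
#'   is applied internally).
#' @param type \code{"response"} (probability, default) or \code{"link"}
#'   (logit).
#' @return Numeric vector of predictions.
#' @export
setMethod("predict", "AveragedModel",
          function(object, newdata, type = c("response", "link")) {
  type <- match.arg(type)
  terms <- setdiff(names(object@beta), "(Intercept)")
  miss <- setdiff(terms, names(newdata))
  if (length(miss)) stop("newdata lacks covariates: ", paste(miss, collapse = ", "))
  n <- if (is.data.frame(newdata)) nrow(newdata)
       else if (length(terms)) length(newdata[[terms[1L]]]) else 1L
  eta <- rep(object@beta[["(Intercept)"]], n)
  for (v in terms)
    eta <- eta + object@beta[[v]] * .designColumn(newdata, v, object@forms[[v]])
  if (type == "link") eta else stats::plogis(eta)
})

#' Empirical pool of presence-point probabilities
#'
#' The fitted occurrence probabilities at the presence locations only.
#' Sampling placement targets from this pool reflects that farms do not
#' always occur in the locations with the highest predicted probabilities.
#'
#' @param m an \linkS4class{AveragedModel}.
#' @param s presence/absence sample.
#' @return Numeric vector of presence-point probabilities.
#' @export
presenceProbabilityPool <- function(m, s) {
  pres <- s[s$y == 1, , drop = FALSE]
  if (!nrow(pres)) stop("sample contains no presence points")
  as.numeric(predict(m, pres, type = "response"))
}

# Stratified fold assignment helper with a single-class guard.
.foldAssign <- function(n, folds, seed, y) {
  attempt <- 0L
  repeat {
    f <- withSeed(seed + attempt, sample(rep_len(seq_len(folds), n)))
    ok <- all(vapply(seq_len(folds), function(k)
      length(unique(y[f == k])) == 2L && length(unique(y[f != k])) == 2L,
      logical(1)))
    if (ok) return(f)
    attempt <- attempt + 1L
    if (attempt > 25L) stop("could not build folds with both classes present")
    message("refolding with a new seed: single-class fold")
  }
}

#' k-fold cross-validated AUC of the selection + averaging pipeline
#'
#' Repeats the full pipeline (form choice, all-subsets AIC ranking, model
#' averaging) on each training split of a k-fold partition (80:20 by default
#' with 5 folds), scores the holdout with the averaged model, and reports the
#' rank-based AUC per fold and its mean.
#'
#' @inheritParams allSubsets
#' @param folds number of folds (default 5).
#' @param window AIC window for [modelAverage()].
#' @param seed RNG seed for the fold shuffle (recorded in the output).
#' @return List with \code{mean}, \code{perFold}, \code{folds}, \code{seed}.
#' @export
kfoldAuc <- function(s, covariates = NULL, forms = NULL, folds = 5L,
                     window = 2, seed = 1L) {
  covs <- .paCovariates(s, covariates)
  y <- as.numeric(s$y)
  f <- .foldAssign(nrow(s), folds, seed, y)
  per <- numeric(folds)
  for (k in seq_len(folds)) {
    train <- s[f != k, , drop = FALSE]
    test <- s[f == k, , drop = FALSE]
    m <- modelAverage(allSubsets(train, covs, forms), window = window)
    per[k] <- rankAuc(predict(m, test, type = "response"), test$y)
  }
  list(mean = mean(per), perFold = per, folds = folds, seed = seed)
}

#' Permutation variable importance across cross-validation folds
#'
#' For each fold, scores the holdout with the model, then permutes one
#' covariate at a time in the holdout and records the AUC drop.  Reported
#' per run with mean and standard error across runs.
#'
#' @inheritParams kfoldAuc
#' @param m optional \linkS4class{AveragedModel}; when NULL the pipeline is
#'   refit on each training split.
#' @return List with \code{runs} (covariate x fold matrix of AUC drops),
#'   \code{mean}, \code{se} (named by covariate, ranked by mean), and
#'   \code{seed}.
#' @export
variableImportance <- function(s, m = NULL, covariates = NULL, forms = NULL,
                               folds = 5L, window = 2, seed = 1L) {
  covs <- if (is.null(m)) .paCovariates(s, covariates)
          else setdiff(names(coef(m)), "(Intercept)")
  y <- as.numeric(s$y)
  f <- .foldAssign(nrow(s), folds, seed, y)
  runs <- matrix(0, length(covs), folds, dimnames = list(covs, NULL))
  for (k in seq_len(folds)) {
    test <- s[f == k, , drop = FALSE]
    mk <- if (is.null(m)) {
      modelAverage(allSubsets(s[f != k, , drop = FALSE], covs, forms),
                   window = window)
    } else m
    base <- rankAuc(predict(mk, test, type = "response"), test$y)
    for (v in intersect(covs, setdiff(names(coef(mk)), "(Intercept)"))) {
      perm <- test
      perm[[v]] <- withSeed(deriveSeed(seed, paste0("perm:", k, ":", v)),
                            sample(perm[[v]]))
      runs[v, k] <- base - rankAuc(predict(mk, perm, type = "response"), test$y)
    }
  }
  mu <- rowMeans(runs)
  se <- apply(runs, 1, stats::sd) / sqrt(folds)
  ord <- order(mu, decreasing = TRUE)
  list(runs = runs[ord, , drop = FALSE], mean = mu[ord], se = se[ord],
       seed = seed)
}
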