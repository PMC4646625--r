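test_that("screenCollinearity drops one member of each correlated pair by preference", {
  set.seed(1)
  n <- 2000
  a <- rnorm(n)
  s <- data.frame(y = rbinom(n, 1, 0.5), a = a, b = a, c = rnorm(n))
  out <- screenCollinearity(s)
  expect_setequal(out$retained, c("a", "c"))
  expect_equal(out$dropped$dropped, "b")

  # preference order decides the survivor
  out2 <- screenCollinearity(s, prefer = c("b"))
  expect_true("b" %in% out2$retained)
  expect_false("a" %in% out2$retained)

  # independent noise covariates all survive
  s3 <- data.frame(y = rbinom(n, 1, 0.5), x1 = rnorm(n), x2 = rnorm(n),
                   x3 = rnorm(n))
  expect_equal(sort(screenCollinearity(s3)$retained), c("x1", "x2", "x3"))

  s4 <- data.frame(y = rbinom(10, 1, 0.5), x1 = rep(1, 10), x2 = rnorm(10))
  expect_error(screenCollinearity(s4), "constant")
})

test_that("chooseForm picks the generating functional form", {
  lin <- simulatePASample(2000, c("(Intercept)" = -0.3, x = 1.2), seed = 2)
  expect_equal(chooseForm(lin, "x"), "linear")
  quad <- simulatePASample(2000, c("(Intercept)" = -0.8, x = 1.0),
                           forms = c(x = "quadratic"), seed = 3)
  expect_equal(chooseForm(quad, "x"), "quadratic")
})

test_that("allSubsets enumerates ranked candidates with the AIC identity", {
  s <- simulatePASample(500, c("(Intercept)" = 0, x = 0.8), seed = 4)
  mods <- allSubsets(s)
  expect_length(mods, 2L)  # intercept-only and {x}
  deltas <- vapply(mods, `[[`, numeric(1), "delta")
  expect_equal(deltas[1], 0)
  expect_true(all(diff(vapply(mods, `[[`, numeric(1), "aic")) >= 0))
  for (m in mods)
    expect_equal(m$aic, -2 * m$logLik + 2 * (length(m$terms) + 1))
})

test_that("strong true effects are selected over noise covariates", {
  s <- simulatePASample(4000, c("(Intercept)" = -0.4, x1 = 1.0, x2 = -0.8,
                                x3 = 0.6),
                        extraCovariates = c("n1", "n2"), seed = 5)
  mods <- allSubsets(s)
  expect_true(all(c("x1", "x2", "x3") %in% mods[[1]]$terms))
})

test_that("no signal keeps the intercept-only model within the support window", {
  s <- simulatePASample(2000, c("(Intercept)" = 0, z = 0), seed = 6)
  mods <- allSubsets(s)
  nullDelta <- vapply(mods, function(m)
    if (length(m$terms) == 0L) m$delta else NA_real_, numeric(1))
  expect_lte(min(nullDelta, na.rm = TRUE), 2)
})

test_that("modelAverage weights by Akaike weight with zeros for absent terms", {
  m1 <- list(terms = "a", forms = c(a = "linear"),
             coef = c("(Intercept)" = 0.5, a = 2), logLik = -10, aic = 22,
             delta = 0)
  m2 <- list(terms = character(0), forms = character(0),
             coef = c("(Intercept)" = 0.3), logLik = -11, aic = 22, delta = 0)
  avg <- modelAverage(list(m1, m2))
  expect_equal(unname(coef(avg)["a"]), 1)        # equal weights, 2 and 0
  expect_equal(unname(coef(avg)["(Intercept)"]), 0.4)

  # single model in the window passes through unchanged
  avg1 <- modelAverage(list(m1, modifyList(m2, list(delta = 5))))
  expect_equal(coef(avg1), m1$coef)

  # window -> 0 reduces to the best model
  m3 <- modifyList(m2, list(delta = 1.5, aic = 23.5))
  avg0 <- modelAverage(list(m1, m3), window = 0)
  expect_equal(coef(avg0), m1$coef)

  expect_error(modelAverage(list(modifyList(m1, list(delta = 3)))), "window")
})

test_that("the built-in swine equation reproduces its printed behaviour", {
  m <- builtinSwineModel()
  terms <- setdiff(names(coef(m)), "(Intercept)")
  expect_length(terms, 10L)
  zero <- as.data.frame(as.list(stats::setNames(rep(0, 10), terms)))
  expect_equal(predict(m, zero, type = "link"), -0.0563)
  expect_equal(predict(m, zero), 1 / (1 + exp(0.0563)), tolerance = 1e-12)

  # distance to open areas enters negatively: occurrence decreases
  grid <- zero[rep(1, 5), ]
  grid$dOpen <- seq(0, 400, length.out = 5)
  expect_true(all(diff(predict(m, grid)) < 0))

  # precipitation enters as a positive quadratic: occurrence increases
  grid <- zero[rep(1, 5), ]
  grid$Precip <- seq(0, 1500, length.out = 5)
  expect_true(all(diff(predict(m, grid)) > 0))
})

test_that("predictSurface equals the closed-form inverse logit per pixel", {
  m <- builtinSwineModel()
  terms <- setdiff(names(coef(m)), "(Intercept)")
  set.seed(8)
  stack <- stats::setNames(lapply(terms, function(v) matrix(runif(12, 0, 10), 3, 4)),
                           terms)
  surf <- predictSurface(m, stack)
  beta <- coef(m)
  eta <- matrix(beta[["(Intercept)"]], 3, 4)
  for (v in terms) {
    x <- stack[[v]]
    if (m@forms[[v]] == "quadratic") x <- x^2
    eta <- eta + beta[[v]] * x
  }
  expect_lt(max(abs(surf@prob - stats::plogis(eta))), 1e-12)

  # constant rasters give a constant surface equal to the scalar prediction
  cstack <- stats::setNames(lapply(terms, function(v) matrix(2, 2, 2)), terms)
  csurf <- predictSurface(m, cstack)
  one <- as.data.frame(as.list(stats::setNames(rep(2, 10), terms)))
  expect_equal(unique(as.numeric(csurf@prob)), unname(predict(m, one)))

  # fully masked surface has no available pixels
  msurf <- predictSurface(m, cstack, mask = matrix(TRUE, 2, 2))
  expect_equal(sum(msurf@available), 0L)

  badstack <- cstack
  badstack$dOpen <- matrix(2, 3, 3)
  expect_error(predictSurface(m, badstack), "shape")
  expect_error(predictSurface(m, cstack[-1]), "lacks")
})

test_that("rank AUC agrees with the ROC-curve reference implementation", {
  set.seed(9)
  for (i in 1:5) {
    y <- rbinom(200, 1, 0.4)
    sc <- rnorm(200) + y
    expect_equal(rankAuc(sc, y),
                 as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))))
  }
})

test_that("cross-validated AUC is perfect on separable data", {
  set.seed(10)
  x <- rnorm(400)
  s <- data.frame(y = as.integer(x > 0), x = x)
  k <- suppressMessages(suppressWarnings(kfoldAuc(s, seed = 1)))
  expect_equal(k$perFold, rep(1, 5))
})

test_that("permutation importance ranks the dominant covariate first", {
  s <- simulatePASample(3000, c("(Intercept)" = -0.2, big = 1.5, small = 0.3),
                        extraCovariates = "noise", seed = 11)
  vi <- variableImportance(s, covariates = c("big", "small", "noise"), seed = 1)
  expect_equal(names(vi$mean)[1], "big")
  expect_lt(vi$mean["noise"], 0.02)  # near-zero effect, near-zero importance
  expect_equal(dim(vi$runs), c(3L, 5L))

  # with a supplied single-covariate model that covariate ranks first
  m <- averagedModel(c("(Intercept)" = -0.2, big = 1.5), c(big = "linear"))
  vi2 <- variableImportance(s, m = m, seed = 1)
  expect_equal(names(vi2$mean)[1], "big")
})

test_that("presence pool is exactly the presence-point predictions", {
  s <- simulatePASample(800, c("(Intercept)" = -0.5, x = 1), seed = 12)
  m <- averagedModel(c("(Intercept)" = -0.5, x = 1), c(x = "linear"))
  pool <- presenceProbabilityPool(m, s)
  expect_equal(pool, as.numeric(predict(m, s[s$y == 1, ])))
  expect_gt(mean(pool), mean(predict(m, s[s$y == 0, ])))
  expect_error(presenceProbabilityPool(m, s[s$y == 0, ]), "presence")
})
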