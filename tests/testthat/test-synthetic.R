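test_that("truth tables are always fully consistent", {
  for (s in c(1, 7, 13)) {
    syn <- makeCensus(synthConfig(), seed = s)
    expect_equal(nrow(validateCensus(syn$truth)), 0L)
    expect_false(anyNA(censusUnits(syn$truth)$pop_total))
  }
})

test_that("disclosure rules hit the configured county-total redaction rate", {
  fracs <- vapply(1:10, function(s) {
    u <- censusUnits(makeCensus(synthConfig(), seed = s)$observed)
    cu <- u[u$level == "county", ]
    mean(is.na(cu$pop_total))
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.19), 0.03)
})

test_that("redaction thresholds at the extremes behave degenerately", {
  cfg0 <- synthConfig(redactThreshold = 0L, binRedactMax = 0L)
  syn0 <- makeCensus(cfg0, seed = 2)
  expect_equal(censusUnits(syn0$observed), censusUnits(syn0$truth))

  cfgAll <- synthConfig(redactThreshold = 1000000L)
  synAll <- makeCensus(cfgAll, seed = 2)
  u <- censusUnits(synAll$observed)
  expect_true(all(is.na(u$pop_total[u$level != "national"])))
  expect_false(anyNA(u$pop_total[u$level == "national"]))
})

test_that("lone redactions always get a complementary-suppression partner", {
  for (s in 1:6) {
    u <- censusUnits(makeCensus(synthConfig(), seed = s)$observed)
    # no unit with a published total has exactly one redacted bin cell
    pp <- as.matrix(u[, paste0("pop_b", 1:7)])
    lone <- rowSums(is.na(pp)) == 1L & !is.na(u$pop_total) &
      rowSums(!is.na(pp) & pp > 0) > 0
    expect_false(any(lone[u$level != "national"]))
    # no parent with a published total has exactly one redacted child total
    for (lev in c("county", "state")) {
      kids <- u[u$level == lev, ]
      for (pid in unique(kids$parent_id)) {
        if (is.na(u$pop_total[match(pid, u$unit_id)])) next
        k <- kids[kids$parent_id == pid, ]
        if (sum(is.na(k$pop_total)) == 1L)
          expect_equal(sum(!is.na(k$pop_total)), 0L)
      }
    }
  }
})

test_that("landscapes honour their generating model", {
  # zero coefficients give a flat 0.5 surface
  beta0 <- c("(Intercept)" = 0, stats::setNames(rep(0, 10),
             names(synthConfig()$covariateRanges)))
  cfg <- synthConfig(nStates = 1, countiesPerState = 2, rows = 20, cols = 20,
                     trueBeta = beta0,
                     trueForms = synthConfig()$trueForms)
  ls <- makeLandscape(cfg, seed = 3)
  expect_equal(unique(as.numeric(ls$surface@prob)), 0.5)

  # zero-width covariate ranges collapse to the intercept probability
  cfg2 <- synthConfig(nStates = 1, countiesPerState = 2, rows = 20, cols = 20,
                      covariateRanges = lapply(synthConfig()$covariateRanges,
                                               function(r) c(0, 0)))
  ls2 <- makeLandscape(cfg2, seed = 4)
  expect_equal(unique(round(as.numeric(ls2$surface@prob), 4)), 0.4859)

  # mask fraction zero leaves everything available
  cfg3 <- synthConfig(nStates = 1, countiesPerState = 1, rows = 15, cols = 15,
                      maskFraction = 0)
  ls3 <- makeLandscape(cfg3, seed = 5)
  expect_true(all(ls3$surface@available))

  # county tiling covers the grid with the census county ids
  expect_setequal(unique(as.integer(ls$county)), 1:2)
})

test_that("presence/absence sampling hits the target prevalence", {
  cfg <- synthConfig(nStates = 2, countiesPerState = 3, rows = 60, cols = 60)
  syn <- makeCensus(cfg, seed = 6)
  ls <- makeLandscape(cfg, seed = 7)
  pa <- samplePA(cfg, ls, syn$observed, n = 10000, seed = 8)
  expect_equal(nrow(pa), 10000L)
  expect_lt(abs(mean(pa$y) - 0.14), 0.01)
  expect_true(all(names(cfg$covariateRanges) %in% names(pa)))
  # covariates recorded at points stay within their configured ranges
  for (v in names(cfg$covariateRanges)) {
    rg <- cfg$covariateRanges[[v]]
    expect_true(all(pa[[v]] >= rg[1] & pa[[v]] <= rg[2]))
  }
})

test_that("a saturated true surface yields only presences", {
  beta1 <- c("(Intercept)" = 50, stats::setNames(rep(0, 10),
             names(synthConfig()$covariateRanges)))
  cfg <- synthConfig(nStates = 1, countiesPerState = 1, rows = 15, cols = 15,
                     trueBeta = beta1, trueForms = synthConfig()$trueForms,
                     prevalence = 0.5)
  syn <- makeCensus(cfg, seed = 9)
  ls <- makeLandscape(cfg, seed = 10)
  expect_warning(pa <- samplePA(cfg, ls, syn$observed, n = 100, seed = 11),
                 "quota")
  expect_true(all(pa$y == 1))
})

test_that("covariate-space simulation reproduces its logistic model", {
  s <- simulatePASample(20000, c("(Intercept)" = -1, x = 0), seed = 12)
  expect_lt(abs(mean(s$y) - stats::plogis(-1)), 0.01)
})
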