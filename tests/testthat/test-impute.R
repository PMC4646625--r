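test_that("seedCell uses bin midpoints, the top-bin cap midpoint, and zero for empty bins", {
  u <- censusUnits(swineCensus2012())
  expect_equal(seedCell(u[1, ], 1), 41688 * 12.5)  # 521,100
  rec <- censusUnits(tinyCensus())
  rec <- rec[rec$unit_id == "01001", ]
  expect_equal(seedCell(rec, 4), 0)  # no farms in bin 4
  expect_equal(seedCell(rec, 7, cap = 5000), 3000)  # midpoint of (1000, 5000)
  # clamped into the feasible range when the cap midpoint falls below it
  rec2 <- rec
  rec2$nfarms_b7 <- 3
  expect_equal(seedCell(rec2, 7, cap = 3100),
               min(max(3 * (1000 + 3100 / 3) / 2, 3000), 3100))
})

test_that("ipfFit leaves a consistent matrix unchanged and converges immediately", {
  M <- ipfFit(ipfMatrix(matrix(1, 2, 2), Qi = c(2, 2), Qj = c(2, 2)))
  expect_equal(M@p, matrix(1, 2, 2))
  expect_equal(M@k, 1L)
  expect_true(M@converged)
})

test_that("ipfFit matches the brute-force alternating-rescale oracle on all-seeded matrices", {
  set.seed(42)
  for (i in 1:20) {
    nr <- sample(2:6, 1)
    nc <- sample(2:7, 1)
    p <- matrix(runif(nr * nc, 0.2, 5), nr, nc)
    target <- matrix(runif(nr * nc, 0.5, 5), nr, nc)
    Qi <- rowSums(target)
    Qj <- colSums(target)
    f <- ipfFit(ipfMatrix(p, Qi, Qj, mMax = 50000L), tol = 1e-11)
    expect_true(f@converged)
    expect_lt(max(abs(f@p - ipfOracle(p, Qi, Qj))), 1e-9)
  }
})

test_that("a lone redacted cell in a row with a known total is forced in one pass", {
  p <- matrix(c(10, 999, 30, 40), 1, 4)  # 999 is the seed of the redacted cell
  pub <- matrix(c(TRUE, FALSE, TRUE, TRUE), 1, 4)
  M <- ipfFit(ipfMatrix(p, Qi = 100, Qj = c(10, 20, 30, 40), published = pub))
  expect_equal(M@p[1, 2], 20)
  expect_true(M@converged)
})

test_that("ipfFit rejects inconsistent or infeasible configurations", {
  expect_error(ipfFit(ipfMatrix(matrix(1, 2, 2), Qi = c(5, 5), Qj = c(2, 2))),
               "inconsistent")
  # discrepant row with every cell published
  p <- matrix(c(1, 1), 1, 2)
  pub <- matrix(TRUE, 1, 2)
  expect_error(ipfFit(ipfMatrix(p, Qi = 10, Qj = c(5, 5), published = pub)),
               "row 1")
})

test_that("imputeLevel is a no-op on published data and recovers forced residuals", {
  tab <- tinyCensus()
  out <- imputeLevel(tab, "county")
  expect_equal(censusUnits(out), censusUnits(tab))

  # one county fully redacted: its total is the state total minus the others
  red <- redactUnit(tab, "02002",
                    c(paste0("pop_b", c(1, 2, 7)), "pop_total"))
  out <- imputeLevel(red, "county")
  u <- censusUnits(out)
  expect_equal(u$pop_total[u$unit_id == "02002"], 12205 - 150)
  expect_equal(u$pop_b7[u$unit_id == "02002"], 12000)
})

test_that("imputeAll completes randomized redacted tables consistently", {
  for (s in 1:5) {
    syn <- makeCensus(synthConfig(), seed = s)
    imp <- imputeAll(syn$observed)
    u <- censusUnits(imp)
    expect_false(anyNA(u$pop_total))
    expect_false(anyNA(popMatrix(imp)))
    expect_equal(nrow(validateCensus(imp)), 0L)
    # every imputed cell lies within its bin bounds
    obs <- censusUnits(syn$observed)
    for (i in seq_len(nrow(u))) {
      for (b in which(is.na(as.numeric(obs[i, paste0("pop_b", 1:7)])))) {
        bb <- cellBounds(u[i, ], b, cap = u$pop_total[i])
        expect_gte(u[[paste0("pop_b", b)]][i], bb["min"])
        expect_lte(u[[paste0("pop_b", b)]][i], bb["max"])
      }
    }
    # hierarchy sums exact
    st <- u[u$level == "state", ]
    expect_equal(sum(st$pop_total), u$pop_total[u$level == "national"])
    for (sid in st$unit_id)
      expect_equal(sum(u$pop_total[u$level == "county" & u$parent_id == sid]),
                   st$pop_total[st$unit_id == sid])
  }
})

test_that("imputeAll leaves a redaction-free table untouched", {
  tab <- tinyCensus()
  expect_equal(censusUnits(imputeAll(tab)), censusUnits(tab))
})

test_that("published cells exceeding their parent total raise an infeasibility error", {
  u <- censusUnits(tinyCensus())
  # inflate a published county cell beyond what the state column can hold
  u$pop_b1[u$unit_id == "01002"] <- 45   # state column b1 is 30 total
  u$pop_total[u$unit_id == "01002"] <- 45
  u$pop_b1[u$unit_id == "01001"] <- NA_real_
  u$pop_total[u$unit_id == "01001"] <- NA_real_
  expect_error(imputeAll(censusTable(u)), "inconsistent|infeasible")
})

test_that("imputation is deterministic", {
  syn <- makeCensus(synthConfig(), seed = 3)
  expect_identical(censusUnits(imputeAll(syn$observed)),
                   censusUnits(imputeAll(syn$observed)))
})
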