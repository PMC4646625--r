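test_that("the published 2012 national aggregate parses with its printed figures", {
  tab <- swineCensus2012()
  u <- censusUnits(tab)
  expect_equal(nrow(u), 1L)
  expect_equal(u$level, "national")
  expect_equal(as.numeric(u[1, paste0("nfarms_b", 1:7)]),
               c(41688, 3435, 2161, 1469, 2115, 1977, 10401))
  expect_equal(as.numeric(u[1, paste0("pop_b", 1:7)]),
               c(244250, 116808, 146967, 201460, 683977, 1384921, 63248402))
  expect_equal(u$pop_total, 66026785)
  expect_equal(nrow(validateCensus(tab)), 0L)
})

test_that("read -> write -> read round-trips bit-identically including sentinels", {
  tab <- redactUnit(tinyCensus(), "01001", c("pop_b2", "pop_total"))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  writeCensus(tab, f1)
  expect_true(any(grepl("(D)", readLines(f1), fixed = TRUE)))
  tab2 <- readCensus(f1)
  writeCensus(tab2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(is.na(censusUnits(tab2)$pop_b2[match("01001", censusUnits(tab2)$unit_id)]))
})

test_that("structural parse errors name the offending row", {
  tab <- tinyCensus()
  f <- tempfile(fileext = ".csv")

  # orphan: county whose state is absent
  u <- censusUnits(tab)
  writeCensus(censusTable(u), f)
  lines <- readLines(f)
  writeLines(lines[!grepl("^01,", lines)], f)
  expect_error(readCensus(f), "parent")

  # unknown level
  writeLines(sub("^01,state", "01,province", lines), f)
  expect_error(readCensus(f), "level")

  # malformed numeric
  writeLines(sub("^01002,county,01,1", "01002,county,01,one", lines), f)
  expect_error(readCensus(f), "malformed")

  # redaction sentinel in a farm-count column is never allowed
  writeLines(sub("^01002,county,01,1", "01002,county,01,(D)", lines), f)
  expect_error(readCensus(f), "redacted")
})

test_that("cellBounds multiplies farm counts by bin sizes and caps the top bin", {
  u <- censusUnits(swineCensus2012())
  expect_equal(cellBounds(u[1, ], 1), c(min = 41688, max = 1000512))
  rec <- censusUnits(tinyCensus())
  rec <- rec[rec$unit_id == "01001", ]
  expect_equal(unname(cellBounds(rec, 2)), c(25, 49))  # one farm in bin 2
  rec2 <- rec
  rec2$nfarms_b2 <- 2
  expect_equal(unname(cellBounds(rec2, 2)), c(50, 98))  # two farms of 25-49
  # bin 7 needs a cap, and the cap must be feasible
  expect_equal(unname(cellBounds(rec, 7, cap = 50000)), c(1000, 50000))
  expect_error(cellBounds(rec, 7), "cap")
  expect_error(cellBounds(rec, 7, cap = 500), "infeasible")
})

test_that("cellBounds is monotone in the farm count", {
  rec <- censusUnits(tinyCensus())[4, ]
  prev <- c(0, 0)
  for (n in c(1, 2, 5, 50)) {
    rec$nfarms_b3 <- n
    bb <- cellBounds(rec, 3)
    expect_gte(bb["min"], prev[1])
    expect_gte(bb["max"], prev[2])
    prev <- bb
  }
})

test_that("validateCensus returns violations instead of throwing", {
  expect_equal(nrow(validateCensus(tinyCensus())), 0L)

  # published cell below its bound
  u <- censusUnits(tinyCensus())
  u$pop_b3[u$unit_id == "02001"] <- 80  # 2 farms of 50-99 need >= 100
  v <- validateCensus(censusTable(u))
  expect_true(any(v$rule == "cell_bounds" & v$unit_id == "02001"))

  # states not summing to the national total
  u <- censusUnits(tinyCensus())
  u$pop_total[u$unit_id == "00"] <- u$pop_total[u$unit_id == "00"] + 50
  v <- validateCensus(censusTable(u))
  expect_true(any(v$rule == "hierarchy" & v$unit_id == "00"))

  # row whose bins disagree with its published total
  u <- censusUnits(tinyCensus())
  u$pop_total[u$unit_id == "01002"] <- 12
  v <- validateCensus(censusTable(u))
  expect_true(any(v$rule == "row_sum" & v$unit_id == "01002"))
})
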