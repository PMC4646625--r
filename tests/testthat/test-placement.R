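test_that("exclusion windows follow the population-size class", {
  expect_equal(neighborhoodWindow(7), 25L)
  expect_equal(neighborhoodWindow(4), 9L)
  expect_equal(neighborhoodWindow(2), 9L)
  expect_equal(neighborhoodWindow(1), 1L)
  expect_error(neighborhoodWindow(8))
})

test_that("coordinates round-trip through the geotransform", {
  surf <- probabilitySurface(matrix(0.5, 10, 12))
  px <- expand.grid(row = c(1L, 5L, 10L), col = c(1L, 7L, 12L))
  ll <- pixelToLatLon(surf, px$row, px$col)
  back <- latLonToPixel(surf, ll$lat, ll$lon)
  expect_equal(back$row, px$row)
  expect_equal(back$col, px$col)
})

test_that("a lone available pixel receives the farm", {
  prob <- matrix(0.5, 3, 3)
  avail <- matrix(FALSE, 3, 3)
  avail[2, 3] <- TRUE
  surf <- probabilitySurface(prob, available = avail, countyIds = "01001")
  drafts <- data.frame(unit_id = "01001", bin = 1L, population = 10L)
  res <- placeFarms(drafts, surf, pool = 0.5, seed = 1)
  expect_equal(res$records$row, 2L)
  expect_equal(res$records$col, 3L)
  expect_false(res$surface@available[2, 3])
})

test_that("large-farm windows exclude later placements unless relaxation triggers", {
  surf <- probabilitySurface(matrix(0.5, 5, 5), countyIds = "01001")
  drafts <- data.frame(unit_id = "01001", bin = c(7L, 7L),
                       population = c(5000L, 2000L))
  # the first 5x5 window blankets the county; the second farm places only
  # through the relaxation ladder, on a different pixel
  res <- placeFarms(drafts, surf, pool = 0.5, seed = 3)
  expect_equal(nrow(res$records), 2L)
  expect_false(identical(res$records[1, c("row", "col")],
                         res$records[2, c("row", "col")]))
})

test_that("windows are respected when space allows", {
  set.seed(4)
  surf <- probabilitySurface(matrix(runif(900, 0.2, 0.8), 30, 30),
                             countyIds = "01001")
  drafts <- data.frame(unit_id = "01001", bin = rep(c(7L, 4L), c(4, 10)),
                       population = rep(c(3000L, 150L), c(4, 10)))
  r <- placeFarms(drafts, surf, pool = runif(50, 0.2, 0.8), seed = 5)$records
  cheb <- as.matrix(stats::dist(r[, c("row", "col")], method = "maximum"))
  diag(cheb) <- Inf
  b7 <- which(r$bin == 7)
  expect_true(all(cheb[b7, ] > 2))          # nothing within a 5x5 of a large farm
  expect_true(all(cheb > 0))                # no shared pixels
  expect_true(all(cheb[r$bin == 4, r$bin == 4] > 1))  # 3x3 among intermediates
})

test_that("an exhausted county reports its unplaced farms", {
  avail <- matrix(FALSE, 2, 2)
  avail[1, 1] <- TRUE
  surf <- probabilitySurface(matrix(0.5, 2, 2), available = avail,
                             countyIds = "01001")
  drafts <- data.frame(unit_id = "01001", bin = c(1L, 1L),
                       population = c(5L, 5L))
  expect_error(placeFarms(drafts, surf, pool = 0.5, seed = 1),
               "unplaced")
})

test_that("runFlaps ties the stages together and stays reproducible", {
  cfg <- synthConfig(nStates = 2, countiesPerState = 2, rows = 60, cols = 60)
  syn <- makeCensus(cfg, seed = 21)
  ls <- makeLandscape(cfg, seed = 22)
  pa <- samplePA(cfg, ls, syn$observed, n = 800, seed = 23)
  pool <- presenceProbabilityPool(builtinSwineModel(), pa)

  run <- runFlaps(syn$observed, ls$surface, pool = pool, scope = "national",
                  seed = 9)
  u <- censusUnits(run$table)
  counties <- u[u$level == "county", ]
  expect_equal(nrow(run$records),
               sum(as.matrix(counties[, paste0("nfarms_b", 1:7)])))
  expect_equal(sum(run$records$population), sum(counties$pop_total))
  expect_equal(run$report@summary$mean, 0)  # farm-to-county APD is exact

  # single-county scope
  cid <- counties$unit_id[1]
  run1 <- runFlaps(syn$observed, ls$surface, pool = pool, scope = "county",
                   unit = cid, seed = 9)
  expect_equal(nrow(run1$records),
               sum(as.numeric(counties[counties$unit_id == cid,
                                       paste0("nfarms_b", 1:7)])))
  # county streams derive from the run seed, not processing order
  sub <- run$records[run$records$fips == cid, , drop = FALSE]
  rownames(sub) <- NULL
  expect_equal(run1$records, sub)

  run2 <- runFlaps(syn$observed, ls$surface, pool = pool, scope = "national",
                   seed = 9)
  expect_identical(run$records, run2$records)

  expect_error(runFlaps(syn$observed, ls$surface), "pool")
})

test_that("farm records serialize with the standard field list", {
  r <- data.frame(fips = "01001", state = "01", lat = 35.1, lon = -99.9,
                  population = 12L, commodity = "swine", bin = 1L,
                  row = 1L, col = 1L, prob = 0.4)
  f <- tempfile(fileext = ".csv")
  writeFarmRecords(r, f)
  expect_equal(readLines(f)[1], "fips,state,lat,lon,population,commodity")
})
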