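# Small fully consistent census hierarchy built in code: one national unit,
# two states, four counties, with populations chosen inside their bin bounds
# and sums exact at every level.
tinyCensus <- function() {
  mk <- function(id, level, parent, nf, pp) {
    out <- data.frame(unit_id = id, level = level, parent_id = parent,
                      stringsAsFactors = FALSE)
    for (b in 1:7) out[[paste0("nfarms_b", b)]] <- nf[b]
    for (b in 1:7) out[[paste0("pop_b", b)]] <- pp[b]
    out$pop_total <- sum(pp)
    out
  }
  u <- rbind(
    mk("00", "national", NA, c(4, 2, 2, 0, 0, 0, 3), c(45, 70, 150, 0, 0, 0, 17000)),
    mk("01", "state", "00", c(3, 1, 0, 0, 0, 0, 1), c(30, 30, 0, 0, 0, 0, 5000)),
    mk("02", "state", "00", c(1, 1, 2, 0, 0, 0, 2), c(15, 40, 150, 0, 0, 0, 12000)),
    mk("01001", "county", "01", c(2, 1, 0, 0, 0, 0, 1), c(20, 30, 0, 0, 0, 0, 5000)),
    mk("01002", "county", "01", c(1, 0, 0, 0, 0, 0, 0), c(10, 0, 0, 0, 0, 0, 0)),
    mk("02001", "county", "02", c(0, 0, 2, 0, 0, 0, 0), c(0, 0, 150, 0, 0, 0, 0)),
    mk("02002", "county", "02", c(1, 1, 0, 0, 0, 0, 2), c(15, 40, 0, 0, 0, 0, 12000)))
  censusTable(u)
}

# Redact one or more population fields of a unit ("pop_b3" or "pop_total").
redactUnit <- function(table, unit_id, fields) {
  u <- censusUnits(table)
  i <- match(unit_id, u$unit_id)
  for (f in fields) u[[f]][i] <- NA_real_
  censusTable(u, censusSchema(table))
}

popMatrix <- function(table, level = NULL) {
  u <- censusUnits(table)
  if (!is.null(level)) u <- u[u$level == level, , drop = FALSE]
  as.matrix(u[, paste0("pop_b", 1:7)])
}
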