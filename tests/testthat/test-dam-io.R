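test_that("a tiny hand-written DAM2 file round-trips counts on channel 1", {
  path <- withr::local_tempfile(fileext = ".txt")
  rows <- sapply(0:2, function(i) {
    counts <- rep(0L, 32); counts[1] <- i
    paste(c(i + 1, "01 Jan 24", sprintf("08:%02d:00", i), 1, 0, 0, 0, 0, 0, 0,
            counts), collapse = "\t")
  })
  writeLines(rows, path)
  mon <- read_dam_monitor(path)
  expect_equal(mon$ch01, 0:2)
  expect_true(all(mon$valid))
  expect_equal(as.numeric(diff(mon$datetime), units = "mins"), c(1, 1))
})

test_that("write -> read -> bin is the identity on counts (3 seeds)", {
  for (seed in c(1, 20, 300)) {
    set.seed(seed)
    n <- 1000
    series <- lapply(1:3, function(j)
      activity_series(rpois(n, 4), 1, t0_utc(), fly_id = paste0("f", j)))
    path <- withr::local_tempfile(fileext = ".txt")
    write_dam_monitor(series, path)
    mon <- read_dam_monitor(path)
    for (j in 1:3) {
      back <- bin_counts(mon, j, bin_width = 1)
      expect_identical(back$counts, series[[j]]$counts)
      expect_equal(back$t0, series[[j]]$t0)
    }
    # light flags and timestamps survive too
    expect_equal(mon$light_sensor, rep(0L, n))
  }
})

test_that("malformed rows are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".txt")
  good <- paste(c(1, "01 Jan 24", "08:00:00", 1, 0, 0, 0, 0, 0, 0, rep(0, 32)),
                collapse = "\t")
  bad <- paste(c(2, "01 Jan 24", "08:01:00", 1, 0, 0, 0, 0, 0, rep(0, 32)),
               collapse = "\t")  # 41 columns
  writeLines(c(good, bad), path)
  expect_error(read_dam_monitor(path), "line 2")
})

test_that("bad status codes are flagged, not dropped; disorder is an error", {
  path <- withr::local_tempfile(fileext = ".txt")
  mk <- function(i, time, status) paste(c(i, "01 Jan 24", time, status,
                                          0, 0, 0, 0, 0, 0, rep(1, 32)),
                                        collapse = "\t")
  writeLines(c(mk(1, "08:00:00", 1), mk(2, "08:01:00", 51)), path)
  mon <- read_dam_monitor(path)
  expect_equal(mon$valid, c(TRUE, FALSE))
  expect_equal(nrow(mon), 2L)
  writeLines(c(mk(1, "08:01:00", 1), mk(2, "08:00:00", 1)), path)
  expect_error(read_dam_monitor(path), "ordering")
})

test_that("bin_counts conserves totals for every tested bin width", {
  set.seed(7)
  n <- 720  # 12 h of minutes
  x <- rpois(n, 2)
  series <- activity_series(x, 1, t0_utc())
  path <- withr::local_tempfile(fileext = ".txt")
  write_dam_monitor(list(series), path)
  mon <- read_dam_monitor(path)
  for (bw in c(1, 5, 30, 60)) {
    b <- bin_counts(mon, 1, bin_width = bw)
    expect_equal(sum(b$counts), sum(x), info = paste("bin width", bw))
    expect_equal(length(b$counts), n / bw)
  }
  # 30 one-minute counts of 1 -> a single bin of 30
  series1 <- activity_series(rep(1, 30), 1, t0_utc())
  write_dam_monitor(list(series1), path)
  expect_equal(bin_counts(read_dam_monitor(path), 1, 30)$counts, 30)
  # all-zero channel stays all-zero with the right length
  b0 <- bin_counts(mon, 2, bin_width = 30)
  expect_equal(b0$counts, rep(0, 24))
})

test_that("gaps are an error unless zero-filling is requested", {
  series <- activity_series(rep(2, 60), 1, t0_utc())
  path <- withr::local_tempfile(fileext = ".txt")
  write_dam_monitor(list(series), path)
  lines <- readLines(path)
  writeLines(lines[-30], path)  # remove one minute
  mon <- read_dam_monitor(path)
  expect_error(bin_counts(mon, 1, 30), "gap")
  filled <- bin_counts(mon, 1, 30, fill_gaps = TRUE)
  expect_equal(sum(filled$counts), 2 * 59)
})

test_that("annotate_regime assigns zt, light and segment per the regime", {
  reg <- std_regime()
  n <- (reg$n_ld_days + reg$n_dd_days) * 48
  s <- make_series(rep(0L, n), reg)
  # bin at 09:00 on LD day 1 -> zt = 1, light L
  i <- which(abs(s$zt - 1) < 1e-9 & s$day == 1)[1]
  expect_equal(s$light[i], "L")
  expect_equal(s$segment[i], "LD")
  # 30-min bins cannot hit 07:59; check the 07:30 bin (zt = 23.5) is dark
  j <- which(abs(s$zt - 23.5) < 1e-9 & s$day == 1)[1]
  expect_equal(s$light[j], "D")
  # first DD bin: zt = 0, dark, segment DD
  k <- which(s$segment == "DD")[1]
  expect_equal(s$zt[k], 0)
  expect_equal(s$light[k], "D")
  expect_true(all(s$light[s$segment == "DD"] == "D"))
  # exactly 50% L bins within the LD segment of a 12:12 cycle
  ld <- s$segment == "LD"
  expect_equal(mean(s$light[ld] == "L"), 0.5)
})

test_that("a series shorter than the declared regime is a coverage error", {
  reg <- std_regime()
  s <- activity_series(rep(0L, 100), 30, t0_utc())
  expect_error(annotate_regime(s, reg), "coverage")
})

test_that("fractional-hour zt is exact at 1-min bins", {
  reg <- std_regime(1, 0)
  s <- activity_series(rep(0L, 24 * 60), 1, t0_utc(8) - 60)  # starts 07:59
  s <- annotate_regime(s, photo_regime(8, 20, 1, 0, 1, 0))
  expect_equal(s$zt[1], 23 + 59 / 60, tolerance = 1e-12)
  expect_equal(s$light[1], "D")
})
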