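test_that("peak ticks are 1-based with earliest-tie resolution", {
  expect_equal(peak_tick(c(0, 2, 5, 3)), 3)
  expect_equal(peak_tick(c(5, 5, 1)), 1)
  expect_equal(peak_tick(rep(2, 10)), 1)
  expect_error(peak_tick(numeric(0)), "empty")
})

test_that("minutes per tick reproduces the serum IgM worked example", {
  cal <- minutes_per_tick(159, 8.5)
  expect_equal(round(cal$ticks_per_day, 1), 18.7)
  expect_equal(cal$minutes_per_tick_rounded, 77)
  expect_equal(cal$minutes_per_tick, 1440 * 8.5 / 159)
})

test_that("minutes per tick handles simple anchors and bad input", {
  expect_equal(minutes_per_tick(1440, 1)$minutes_per_tick, 1)
  expect_equal(minutes_per_tick(100, 1)$minutes_per_tick, 14.4)
  expect_error(minutes_per_tick(0, 1), "positive")
  expect_error(minutes_per_tick(100, -2), "positive")
})

test_that("tick-to-day conversion matches the published mapping", {
  expect_equal(ticks_to_days(1440, 60), 60)
  expect_equal(ticks_to_days(96.75, 64), 4.3)
  expect_error(ticks_to_days(0, 64), "positive")
})

test_that("the two conversions are exact inverses", {
  set.seed(3)
  for (i in 1:25) {
    pk <- runif(1, 10, 2000)
    d <- runif(1, 0.5, 30)
    mpt <- minutes_per_tick(pk, d)$minutes_per_tick
    expect_equal(ticks_to_days(pk, mpt), d, tolerance = 1e-12)
  }
})

test_that("display rounding is half away from zero", {
  expect_equal(minutes_per_tick(2880, 3)$minutes_per_tick, 1.5)
  expect_equal(minutes_per_tick(2880, 3)$minutes_per_tick_rounded, 2)
})

test_that("calibrate() finds hallmark peaks in census signal columns", {
  ticks <- 1:400
  census <- data.frame(
    sig_Ab5_z3 = stats::dnorm(ticks, mean = 159, sd = 30),
    sig_Ab1_z3 = stats::dnorm(ticks, mean = 240, sd = 40),
    sig_Ab2_z3 = stats::dnorm(ticks, mean = 260, sd = 40))
  hm <- data.frame(name = c("serum_IgM", "serum_IgG"), zone_id = 3L,
                   signals = c("Ab5", "Ab1,Ab2"), human_day = c(8.5, 28))
  cal <- calibrate(census, hm)
  expect_equal(cal$peak_tick[1], 159)
  expect_equal(cal$minutes_per_tick_rounded[1], 77)
  # averaged IgG signals peak between the two component peaks
  expect_gt(cal$peak_tick[2], 240); expect_lt(cal$peak_tick[2], 260)
  expect_equal(attr(cal, "mean_minutes_per_tick"),
               mean(cal$minutes_per_tick))
  expect_error(calibrate(census[, 1, drop = FALSE], hm), "lacks columns")
  # averaging across replicate censuses changes nothing for identical input
  cal2 <- calibrate(list(census, census), hm)
  expect_equal(cal2$peak_tick, cal$peak_tick)
})

test_that("the shipped hallmark registry only fixes the serum IgM day", {
  hm <- hallmarks()
  expect_equal(hm$human_day[hm$name == "serum_IgM"], 8.5)
  expect_true(all(is.na(hm$human_day[hm$name != "serum_IgM"])))
})
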