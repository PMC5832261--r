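test_that("constant and periodic laws produce the prescribed cycle lengths and times", {
  s <- constant_schedule(350, 3)
  expect_equal(s$CL_ms, rep(350, 3))
  expect_equal(s$stim_time_ms, c(350, 700, 1050))
  expect_equal(nrow(constant_schedule(350, 1)), 1)

  p <- periodic_schedule(350, 35, 2.4, 5)
  expect_equal(p$CL_ms, 350 + 35 * sin(2.4 * (1:5)))
  expect_equal(p$CL_ms[1], 350 + 35 * sin(2.4))  # ~373.64 ms
  expect_equal(p$CL_ms[1], 373.64, tolerance = 1e-4)

  # omega = 0 and clv = 0 degenerate to constant pacing
  expect_equal(periodic_schedule(350, 35, 0, 4)$CL_ms, rep(350, 4))
  expect_equal(periodic_schedule(350, 0, 2.4, 4)$CL_ms, rep(350, 4))

  # integer period: the CL sequence repeats
  w <- 2 * pi / 8
  p8 <- periodic_schedule(400, 40, w, 24)
  expect_equal(p8$CL_ms[1:8], p8$CL_ms[9:16])

  a <- alternating_schedule(350, 35, 4)
  expect_equal(a$CL_ms, c(315, 385, 315, 385))
  expect_equal(alternating_schedule(350, 0, 3)$CL_ms, rep(350, 3))
})

test_that("stimulus times are the cumulative cycle-length sums for every law", {
  scheds <- list(
    constant_schedule(350, 20),
    periodic_schedule(350, 35, 2.4, 20),
    random_schedule(350, 35, 20, 7),
    alternating_schedule(350, 35, 20)
  )
  for (s in scheds) {
    expect_equal(diff(s$stim_time_ms), s$CL_ms[-1])
    expect_equal(s$stim_time_ms[1], s$CL_ms[1])
    expect_true(all(diff(s$stim_time_ms) > 0))
  }
})

test_that("random schedules are bounded, uniform, seeded, and reject clv >= CL*", {
  s1 <- random_schedule(350, 35, 10000, seed = 11)
  expect_true(all(s1$CL_ms >= 315 & s1$CL_ms <= 385))
  expect_lt(abs(mean(s1$CL_ms) - 350), 1)
  ks <- suppressWarnings(stats::ks.test(s1$CL_ms, "punif", 315, 385))
  expect_gt(ks$p.value, 0.01)
  s2 <- random_schedule(350, 35, 10000, seed = 11)
  expect_identical(s1$CL_ms, s2$CL_ms)
  s3 <- random_schedule(350, 35, 10000, seed = 12)
  expect_false(identical(s1$CL_ms, s3$CL_ms))
  expect_equal(random_schedule(350, 0, 5, seed = 1)$CL_ms, rep(350, 5))
  expect_error(random_schedule(350, 350, 5, seed = 1), "clv")
  expect_error(periodic_schedule(350, 400, 2.4, 5), "clv")
})

test_that("drop_beat disables one stimulus without moving the pacing clock", {
  s <- constant_schedule(350, 20)
  d <- drop_beat(s, 10)
  expect_false(d$stim_enabled[10])
  expect_equal(d$stim_time_ms, s$stim_time_ms)
  # enabled-stimulus gap around the dropped beat is 700 ms
  on <- d$stim_time_ms[d$stim_enabled]
  expect_equal(max(diff(on)), 700)
  expect_equal(drop_beat(d, 10, enable = TRUE), s)
  expect_equal(drop_beat(drop_beat(s, 10), 10), drop_beat(s, 10))
  expect_error(drop_beat(s, 0), "range")
  expect_error(drop_beat(s, 21), "range")
})

test_that("switch schedules concatenate a constant run-in with a dynamic phase", {
  dyn <- periodic_schedule(350, 35, 2.4, 60)
  sw <- switch_schedule(350, 17000, dyn)
  m <- schedule_meta(sw)
  expect_equal(m$switch_index, 49)  # floor(17000 / 350) = 48 constant beats
  expect_equal(sw$CL_ms[1:48], rep(350, 48))
  expect_equal(sw$CL_ms[49:108], dyn$CL_ms)
  expect_equal(diff(sw$stim_time_ms), sw$CL_ms[-1])
  # degenerate dynamic phase: indistinguishable from one constant schedule
  sw0 <- switch_schedule(350, 3500, periodic_schedule(350, 0, 2.4, 10))
  expect_equal(sw0$CL_ms, rep(350, 20))
})

test_that("schedules round-trip through CSV and JSON", {
  s <- drop_beat(periodic_schedule(350, 35, 2.4, 12), 5)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(s, csv)
  back <- read_schedule_csv(csv)
  expect_equal(back$CL_ms, s$CL_ms)
  expect_equal(back$stim_enabled, s$stim_enabled)

  js <- withr::local_tempfile(fileext = ".json")
  write_schedule_json(s, js)
  bj <- read_schedule_json(js)
  expect_equal(bj$CL_ms, s$CL_ms)
  expect_equal(bj$stim_enabled, s$stim_enabled)
  expect_equal(schedule_meta(bj)$omega, 2.4)
  expect_equal(schedule_meta(bj)$law, "periodic")
})

test_that("periodic |dCL| changes follow the closed-form sine-difference law", {
  w <- 2.4; clv <- 35
  s <- periodic_schedule(350, clv, w, 2000)
  emp <- abs(diff(s$CL_ms))
  n <- 2:2000
  expected <- abs(clv * (sin(w * n) - sin(w * (n - 1))))
  expect_equal(emp, expected, tolerance = 1e-12)
  # amplitude bound: |dCL| <= 2 clv |sin(w/2)|
  expect_lte(max(emp), 2 * clv * abs(sin(w / 2)) + 1e-9)
})
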