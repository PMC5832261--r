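test_that("constant pacing converges to a steady state with exact DI bookkeeping", {
  c0 <- fix_cond350()
  expect_lt(c0$steady["sd"], 0.5)
  tr <- c0$train
  ok <- tr$captured & !is.na(tr$APD_ms)
  expect_true(all(tr$captured))
  expect_equal(tr$DI_ms[ok], tr$CL_ms[ok] - tr$APD_ms[ok])
  expect_true(all(diff(tr$upstroke_ms) > 0))
})

test_that("snapshot restore replays beats exactly and restarts are bitwise identical", {
  f <- fix_control()
  tr <- resume_train(f$p, fix_cond350()$state, rep(350, 6), f$stim,
                     record_states = TRUE)
  states <- beat_states(tr)
  # replay from the snapshot before beat 4 reproduces beats 4..6
  re <- resume_train(f$p, states[4, ], c(rep(350, 3)), f$stim)
  expect_equal(re$APD_ms, tr$APD_ms[4:6], tolerance = 1e-9)
  expect_lt(max(abs(re$APD_ms - tr$APD_ms[4:6])), 0.1)
  # repeated restores start from identical states
  s1 <- snapshot(tr, 4); s2 <- snapshot(tr, 4)
  expect_identical(as.numeric(s1), as.numeric(s2))
  # identical inputs => identical trains
  re2 <- resume_train(f$p, states[4, ], c(rep(350, 3)), f$stim)
  expect_identical(re$APD_ms, re2$APD_ms)
})

test_that("restore_and_stimulate brackets the reference APD for nearby cycle lengths", {
  f <- fix_control()
  st <- fix_cond350()$state
  apd0 <- restore_and_stimulate(st, 350, f$p, f$stim)
  apd_minus <- restore_and_stimulate(st, 330, f$p, f$stim)
  apd_plus <- restore_and_stimulate(st, 370, f$p, f$stim)
  expect_equal(apd0, fix_cond350()$steady["APD"], ignore_attr = TRUE,
               tolerance = 5e-3)
  expect_lt(apd_minus, apd0)
  expect_gt(apd_plus, apd0)
})

test_that("measure_apd recovers exact geometry from a synthetic trace", {
  # instant rise at t = 10 to +40 mV, then a linear fall to -80 mV at
  # t = 310 (slope -0.4 mV/ms): the -60 mV crossing is 100 mV below the
  # peak, at t = 260, so APD = 260 - upstroke
  t <- seq(0, 400, by = 0.5)
  v <- ifelse(t < 10, -80, ifelse(t <= 310, 40 - (t - 10) * 120 / 300, -80))
  m <- measure_apd(data.frame(t, v), stim_time = 8)
  expect_true(m$captured)
  expect_equal(m$APD, 260 - m$upstroke_time, tolerance = 1e-6)
  expect_equal(m$APD, 250.25, tolerance = 0.01)
  # sub-threshold deflection: capture-failure sentinel
  v2 <- ifelse(t < 10, -80, -80 + 30 * exp(-(t - 10) / 5))
  m2 <- measure_apd(data.frame(t, v2), stim_time = 8)
  expect_false(m2$captured)
  expect_true(is.na(m2$APD))
})

test_that("in-engine APD agrees with the pure-R trace measurement", {
  f <- fix_control()
  tr <- resume_train(f$p, fix_cond350()$state, rep(350, 2), f$stim,
                     record_traces = TRUE, trace_dt = 0.1)
  trace <- attr(tr, "trace")
  m <- measure_apd(trace[, c("t_ms", "Vm_mV")], stim_time = 0,
                   next_stim_time = 350)
  expect_equal(m$APD, tr$APD_ms[1], tolerance = 2e-3)
  expect_equal(m$upstroke_time, tr$upstroke_ms[1], tolerance = 0.05)
})

test_that("classic ER sweep passes through the steady state and keeps its bookkeeping", {
  f <- fix_control()
  er <- memo("er_control", classic_er(f$p, 350, half_width = 35, step = 5,
                                      state = fix_cond350()$state,
                                      stim = f$stim))
  # the CL* test point lies on the rate-dependence value at CL*
  i <- which(er$vs_CL$x_ms == 350)
  expect_equal(er$vs_CL$APD_ms[i], fix_cond350()$steady["APD"],
               ignore_attr = TRUE, tolerance = 5e-3)
  # point-wise DI = CL - APD(conditioning beat); the conditioning APD is the
  # same in every sweep run, so the sorted x-axes map onto each other
  expect_equal(er$vs_DI$x_ms, er$vs_CL$x_ms - er$apd_cond, tolerance = 1e-6)
  # slope at the conditioning point is the control value ~0.5
  expect_equal(er_local_slope(er$vs_CL, 350), 0.5, tolerance = 0.12)
})

test_that("rate-dependence curve is monotone and saturates at long cycle lengths", {
  f <- fix_control()
  rd <- memo("rd_coarse", rd_curve(f$p, cl_values = c(350, 500, 700, 1000, 1300, 1400),
                                   n_cond = 80, n_avg = 10,
                                   initial_state = fix_cond350()$state,
                                   stim = f$stim))
  expect_false(any(rd$flagged))
  expect_true(all(diff(rd$APD_ms) > 0))
  # plateau: marginal APD gain per ms of CL vanishes at the long end
  last_gain <- diff(rd$APD_ms)[5] / diff(rd$x_ms)[5]
  first_gain <- diff(rd$APD_ms)[1] / diff(rd$x_ms)[1]
  expect_lt(last_gain, first_gain / 3)
  expect_lt(last_gain * 20, 1)  # < 1 ms over one 20 ms grid step
})

test_that("uncaptured stimuli are recorded as capture failures, not errors", {
  f <- fix_control()
  # pacing far into refractoriness: second stimulus at 80 ms cannot capture
  tr <- resume_train(f$p, fix_cond350()$state, c(80, 400), f$stim,
                     tail_ms = 200)
  expect_true(tr$captured[1])
  expect_false(tr$captured[2])
  expect_true(is.na(tr$APD_ms[2]))
})

test_that("dynamic ER family collapses for a constant schedule", {
  f <- fix_control()
  # beats late in the short train, past the settling of the initial
  # diastolic pause the first scheduled cycle introduces
  fam <- dynamic_er_family(f$p, constant_schedule(350, 12), half_width = 20,
                           step = 20, beats = c(9, 11),
                           initial_state = fix_cond350()$state, stim = f$stim)
  expect_length(fam, 2)
  # all family members coincide: vertical spread at matched x below 1 ms
  a1 <- fam[[1]]$vs_CL$APD_ms
  a2 <- fam[[2]]$vs_CL$APD_ms
  expect_lt(max(abs(a1 - a2)), 1)
})
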