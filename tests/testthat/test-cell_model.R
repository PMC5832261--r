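test_that("compiled right-hand side matches the independent R transcription", {
  p <- tp06_params()
  states <- list(
    rest = tp06_initial_state(),
    depolarized = {
      y <- tp06_initial_state()
      y[c("V", "m", "h", "j", "d", "f", "r", "s")] <-
        c(20, 0.95, 0.05, 0.2, 0.6, 0.4, 0.8, 0.3)
      y[c("Ca_i", "Ca_ss")] <- c(0.0009, 0.004)
      as_tp06_state(y)
    },
    plateau = {
      y <- tp06_initial_state()
      y[c("V", "Xr1", "Xs", "f", "f2", "fCass")] <-
        c(-10, 0.3, 0.2, 0.25, 0.6, 0.8)
      y[c("Ca_SR", "Na_i", "K_i")] <- c(2.8, 10.2, 133)
      as_tp06_state(y)
    }
  )
  for (nm in names(states)) {
    ref <- tp06_reference_rhs(states[[nm]], p)
    got <- tp06_derivatives(states[[nm]], params = p)
    expect_equal(got, ref[names(got)], tolerance = 1e-6,
                 label = paste("derivatives at", nm, "state"))
  }
  # scaled conductances propagate into the derivative
  ps <- scale_conductances(p, c(IKs = 0.4, ICaL = 1.9))
  ref <- tp06_reference_rhs(states$plateau, ps)
  expect_equal(tp06_derivatives(states$plateau, params = ps),
               ref[apmem:::TP06_STATE_NAMES], tolerance = 1e-6)
})

test_that("quiescent model sits at a fixed point with gates and concentrations in range", {
  f <- fix_control()
  dy <- tp06_derivatives(f$rest, params = f$p)
  expect_lt(max(abs(dy)), 1e-3)
  expect_no_error(validate_state(f$rest))
  # a paced trajectory stays in physical ranges
  tr <- resume_train(f$p, fix_cond350()$state, rep(350, 5), f$stim,
                     record_states = TRUE)
  states <- beat_states(tr)
  gates <- states[, match(apmem:::TP06_GATE_NAMES, apmem:::TP06_STATE_NAMES), drop = FALSE]
  expect_true(all(gates >= 0 & gates <= 1))
  conc <- states[, match(apmem:::TP06_CONC_NAMES, apmem:::TP06_STATE_NAMES), drop = FALSE]
  expect_true(all(conc > 0))
})

test_that("conductance scaling is multiplicative, commutes, and rejects bad input", {
  p <- tp06_params()
  p_ab <- scale_conductances(scale_conductances(p, c(IKr = 0.5)), c(IKr = 0.4))
  p_ba <- scale_conductances(p, c(IKr = 0.2))
  expect_equal(p_ab$g_Kr, p_ba$g_Kr)
  expect_identical(unclass(scale_conductances(p, c(IKs = 1, ICaL = 1))),
                   unclass(p))
  expect_error(scale_conductances(p, c(INonsense = 2)), "unknown current")
  expect_error(scale_conductances(p, c(IKs = -1)), "positive")
  expect_error(scale_conductances(p, 2), "named")
})

test_that("derivatives rejects malformed states", {
  p <- tp06_params()
  bad <- as.numeric(tp06_initial_state())
  bad[3] <- NaN
  expect_error(tp06_derivatives(bad, params = p), "non-finite")
  expect_error(tp06_derivatives(rep(1, 18), params = p), "19")
  y <- tp06_initial_state(); y["h"] <- 1.2
  expect_error(validate_state(y), "gating")
  y <- tp06_initial_state(); y["Ca_i"] <- -1e-5
  expect_error(validate_state(y), "concentration")
})

test_that("threshold search agrees with a brute-force amplitude scan and brackets capture", {
  f <- fix_control()
  thr <- find_threshold(f$rest, f$p)
  # brute force: fine scan over amplitudes
  elicits <- function(amp) {
    tr <- resume_train(f$p, f$rest, 25, list(duration = 3, amplitude = amp))
    isTRUE(tr$captured[1])
  }
  grid <- seq(0.5 * thr, 2 * thr, by = 0.01 * thr)
  hits <- vapply(grid, elicits, logical(1))
  brute <- grid[which(hits)[1]]
  expect_lt(abs(thr - brute) / brute, 0.015)
  expect_true(elicits(2 * thr))
  expect_false(elicits(0.5 * thr))
})

test_that("state snapshots round-trip through JSON", {
  f <- fix_control()
  path <- withr::local_tempfile(fileext = ".json")
  write_state_json(f$rest, path)
  back <- read_state_json(path)
  expect_equal(as.numeric(back), as.numeric(f$rest), tolerance = 1e-12)
  expect_identical(names(back), apmem:::TP06_STATE_NAMES)
})

test_that("clamp evaluation matches the fit basis and clamps outside its voltage range", {
  cl <- structure(list(current = "IKs", coefficients = c(1, 2, 0.5),
                       fit_order = 2, v_range = c(-80, 30), v_center = -25,
                       v_scale = 55, blank_ms = 9, reference_CL = 350,
                       rmse = 0, rmse_tol_abs = 1),
                  class = "clamped_current")
  u <- function(v) (v + 25) / 55
  expect_equal(eval_clamp(cl, 0), 1 + 2 * u(0) + 0.5 * u(0)^2)
  # boundary hold outside the range
  expect_equal(eval_clamp(cl, -120), eval_clamp(cl, -80))
  expect_equal(eval_clamp(cl, 60), eval_clamp(cl, 30))
  path <- withr::local_tempfile(fileext = ".json")
  write_clamp_json(cl, path)
  back <- read_clamp_json(path)
  expect_equal(back$coefficients, cl$coefficients)
  expect_equal(eval_clamp(back, -10), eval_clamp(cl, -10))
})

test_that("a clamp inside its blanking window leaves the derivatives untouched", {
  f <- fix_control()
  # nonsense clamp: huge constant current; blanked, it must not act
  cl <- structure(list(current = "ICaL", coefficients = 50, fit_order = 0,
                       v_range = c(-90, 40), v_center = -25, v_scale = 65,
                       blank_ms = 9, reference_CL = 350, rmse = 0,
                       rmse_tol_abs = 1),
                  class = "clamped_current")
  base <- tp06_derivatives(f$rest, params = f$p)
  blanked <- tp06_derivatives(f$rest, params = f$p, clamps = list(cl),
                              time_since_upstroke = 5)
  active <- tp06_derivatives(f$rest, params = f$p, clamps = list(cl),
                             time_since_upstroke = 50)
  expect_identical(blanked, base)
  expect_false(isTRUE(all.equal(active, base)))
})

test_that("fitted current clamps reproduce their own reference beat", {
  f <- fix_control()
  c0 <- fix_cond350()
  ctrl <- resume_train(f$p, c0$state, 350, f$stim, tail_ms = 150)
  # I_CaL and I_Kr have near-single-valued late current-voltage relations:
  # the clamp is self-consistent within 2 ms
  for (cur in c("ICaL", "IKr")) {
    cl <- memo(paste0("clamp_ctrl_", cur),
               fit_current_clamp(f$p, cur, state = c0$state, stim = f$stim,
                                 tol_action = "best"))
    expect_s3_class(cl, "clamped_current")
    expect_lte(cl$fit_order, 12)
    expect_lte(cl$rmse, cl$rmse_tol_abs)
    clamped <- resume_train(f$p, c0$state, 350, f$stim, clamps = list(cl),
                            tail_ms = 150)
    expect_lt(abs(clamped$APD_ms[1] - ctrl$APD_ms[1]), 2)
  }
  # I_Ks activates slowly, so its early-plateau current cannot equal any
  # voltage-only function of the repolarization limb: a ~4 ms APD residual
  # remains (see the methods vignette)
  clks <- memo("clamp_ctrl_IKs",
               fit_current_clamp(f$p, "IKs", state = c0$state, stim = f$stim,
                                 tol_action = "best"))
  clamped <- resume_train(f$p, c0$state, 350, f$stim, clamps = list(clks),
                          tail_ms = 150)
  expect_lt(abs(clamped$APD_ms[1] - ctrl$APD_ms[1]), 6)
})
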