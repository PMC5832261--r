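test_that("alternans detection classifies constructed series correctly", {
  expect_error(detect_alternans(rep(200, 10)), "finite")
  none <- detect_alternans(rep(200, 60))
  expect_false(none$present)
  alt <- detect_alternans(rep(c(200, 260), 30))
  expect_true(alt$present)
  expect_true(alt$sustained)
  expect_equal(alt$amplitude, 60)
  # transient alternans that dies out is present but not sustained
  series <- c(rep(c(200, 260), 25), rep(230, 40))
  tr <- detect_alternans(series)
  expect_true(tr$present)
  expect_false(tr$sustained)
  # amplitude below tolerance is not alternans
  weak <- detect_alternans(rep(c(200, 201), 40), amp_tol = 2)
  expect_false(weak$present)
  # short alternating run below min_run is not alternans
  short_run <- detect_alternans(c(rep(c(200, 260), 10), rep(230, 60)),
                                min_run = 40)
  expect_false(short_run$present)
})

test_that("dropping no beat yields an identically recovered profile", {
  f <- fix_control()
  sched <- constant_schedule(350, 75)
  intact <- run_train(f$p, sched, initial_state = fix_cond350()$state,
                      stim = f$stim)
  # replaying from a snapshot with all stimuli enabled matches the intact
  # run beat for beat: the null perturbation has a null profile
  re <- resume_train(f$p, beat_states(intact)[10, ],
                     c(sched$CL_ms[11:70], sched$CL_ms[70]), f$stim)
  expect_equal(re$APD_ms, intact$APD_ms[10:70], tolerance = 1e-9)
})

test_that("a missing beat perturbs only from the drop onward and recovers in a few beats", {
  f <- fix_control()
  sched <- constant_schedule(350, 75)
  res <- missing_beat_experiment(f$p, sched, 15,
                                 initial_state = fix_cond350()$state,
                                 stim = f$stim)
  expect_s3_class(res, "perturbation_result")
  expect_gt(res$Nb, 0)
  expect_lt(res$Nb, 12)
  expect_length(res$delta_apd, 50)
  # first beat after the pause is prolonged, and the profile decays
  expect_gt(res$delta_apd[1], 10)
  expect_lt(max(abs(res$delta_apd[(res$Nb + 1):50])), 2)
  expect_false(res$alternans$present)
})

test_that("intact and perturbed runs share their prefix exactly", {
  f <- fix_control()
  sched <- random_schedule(350, 35, 75, seed = 9)
  intact <- run_train(f$p, sched, initial_state = fix_cond350()$state,
                      stim = f$stim)
  pert_sched <- drop_beat(sched, 15)
  pert <- run_train(f$p, pert_sched, initial_state = fix_cond350()$state,
                    stim = f$stim)
  expect_identical(pert$APD_ms[1:14], intact$APD_ms[1:14])
  expect_true(is.na(pert$APD_ms[15]))
  expect_false(isTRUE(all.equal(pert$APD_ms[16], intact$APD_ms[16])))
})

test_that("|dCL| exceedance statistics match their analytic laws", {
  thr <- c(0, 10, 30, 50, 69.9)
  const <- constant_schedule(350, 5000)
  per <- periodic_schedule(350, 35, 2.4, 5000)
  ran <- random_schedule(350, 35, 5000, seed = 21)
  out <- cl_change_statistics(list(periodic = per, random = ran), thr)
  expect_true(all(out$A_periodic >= 0 & out$A_periodic <= 1))
  expect_true(all(diff(out$A_periodic) <= 0))
  expect_true(all(diff(out$A_random) <= 0))
  # constant: all fractions zero
  out0 <- cl_change_statistics(list(constant = const, random = ran), thr)
  expect_true(all(out0$A_constant == 0))
  # periodic closed form: |dCL| = 2 clv |sin(w/2)| |cos(w(N - 1/2))|
  w <- 2.4; clv <- 35
  amp <- 2 * clv * abs(sin(w / 2))
  p_exact <- vapply(thr, function(th)
    if (th >= amp) 0 else 2 / pi * acos(th / amp), numeric(1))
  expect_equal(out$A_periodic, p_exact, tolerance = 0.03)
  # random: |dCL| is the absolute difference of two uniforms on [-clv, clv]
  # (triangular): P(|dCL| > t) = (1 - t / (2 clv))^2
  r_exact <- (pmax(0, 1 - thr / (2 * clv)))^2
  expect_equal(out$A_random, r_exact, tolerance = 0.04)
  # matched clv: periodic pacing makes large beat-to-beat jumps more often
  expect_gt(out$ratio[3], 1)
})

test_that("the switch machinery aligns perturbed and reference branches", {
  f <- fix_control()
  # control cell: the dropped beat perturbs briefly, the switch run recovers
  sw <- switch_experiment(f$p, 350, n_const = 20,
                          dynamic = periodic_schedule(350, 35, 2.4, 60),
                          drop_index = 5, state = fix_cond350()$state,
                          stim = f$stim)
  expect_s3_class(sw, "switch_result")
  expect_false(sw$alternans_established)  # control does not alternate
  expect_true(sw$quenched)
  expect_length(sw$delta_post, 60)
  expect_lt(max(abs(utils::tail(sw$delta_post, 20))), 2)
})
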