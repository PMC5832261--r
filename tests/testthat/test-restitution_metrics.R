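test_that("space of states pairs each APD with the preceding interval in both modes", {
  sp <- surrogate_params(gamma = 0)
  sched <- periodic_schedule(350, 35, 2.4, 50)
  tr <- surrogate_train(sp, sched)
  s_cl <- space_of_states(tr, "vs_CL")
  s_di <- space_of_states(tr, "vs_DI")
  expect_equal(nrow(s_cl), sum(tr$captured) - 1)
  k <- s_cl$beat
  expect_equal(s_cl$x_ms, tr$CL_ms[k - 1])
  expect_equal(s_cl$APD_ms, tr$APD_ms[k])
  # bookkeeping identity between the two representations
  expect_equal(s_di$x_ms, s_cl$x_ms - tr$APD_ms[k - 1])
  expect_equal(s_di$APD_ms, s_cl$APD_ms)
})

test_that("constant pacing collapses the space to one point with zero shift", {
  tr <- fixture_suite(n_beats = 120)$constant
  s_cl <- space_of_states(tr, "vs_CL")
  s_di <- space_of_states(tr, "vs_DI")
  keep <- s_cl$beat > 30  # discard the conditioning transient
  expect_lt(diff(range(s_cl$APD_ms[keep])), 0.5)
  expect_lt(diff(range(s_di$x_ms[keep])), 0.5)
  expect_equal(as.numeric(shift(s_cl)), 0)
  expect_equal(as.numeric(shift(s_di)), 0)
})

test_that("shift and major-axis slope recover exact ellipse geometry", {
  ax <- 30; ay <- 9; th <- pi / 8
  sp <- make_ellipse_space(ax = ax, ay = ay, theta = th)
  got <- shift(sp, reference_x = 350)
  expect_equal(as.numeric(got), ellipse_vertical_width(ax, ay, th),
               tolerance = 1e-3)
  expect_equal(attr(got, "method"), "branches")
  # principal axis of a long thin ellipse tends to its geometric major axis
  slim <- make_ellipse_space(ax = 60, ay = 1, theta = th)
  expect_equal(as.numeric(major_axis_slope(slim)), tan(th), tolerance = 1e-3)
})

test_that("slopes of exact lines are recovered to machine precision", {
  x <- seq(300, 400, by = 2)
  line <- data.frame(beat = seq_along(x) + 1, x_ms = x,
                     APD_ms = 0.5 * x + 40,
                     direction = rep(c(1, -1), length.out = length(x)))
  line <- structure(line, mode = "vs_DI", meta = list(law = "random"),
                    class = c("space_of_states", "data.frame"))
  expect_equal(as.numeric(der_slope(line)), 0.5, tolerance = 1e-12)
  expect_equal(as.numeric(major_axis_slope(line)), 0.5, tolerance = 1e-9)
  expect_equal(max_local_slope(line), 0.5, tolerance = 1e-9)
})

test_that("der_slope refuses hysteresis loops and points the caller at the major axis", {
  sp <- make_ellipse_space(ax = 30, ay = 12)
  expect_error(der_slope(sp), "major_axis_slope")
})

test_that("mono-exponential fits recover known parameters", {
  x <- seq(0, 100, length.out = 50)
  y <- 40 * exp(-x / 18) + 5
  fit <- fit_monoexponential(x, y)
  expect_equal(fit$a, 40, tolerance = 1e-6)
  expect_equal(fit$tau, 18, tolerance = 1e-6)
  expect_equal(fit$c, 5, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
  # 1% noise: tau within 5%
  yn <- y * (1 + withr::with_seed(5, stats::rnorm(50, 0, 0.01)))
  fitn <- fit_monoexponential(x, yn)
  expect_lt(abs(fitn$tau - 18) / 18, 0.05)
  # constant data: amplitude ~0, offset ~mean
  fc <- fit_monoexponential(x, rep(7, 50))
  expect_lt(abs(fc$a), 1e-6)
  expect_equal(fc$c, 7, tolerance = 1e-6)
})

test_that("relaxation beat count is zero for a null step and for infinite tolerance", {
  f <- fix_control()
  expect_equal(er_to_rd_beats(f$p, 350, 350), 0)
  expect_equal(apmem:::recovery_index(c(5, 3, 1, 0.5, 0.2), tol = Inf,
                                      sustain = 3), 0)
  expect_equal(apmem:::recovery_index(c(5, 3, 1, 0.5, 0.2), tol = 2,
                                      sustain = 3), 2)
  expect_true(is.na(apmem:::recovery_index(c(5, 3, 4), tol = 2, sustain = 2)))
})

test_that("restitution relaxes into rate dependence faster at longer conditioning CLs", {
  f <- fix_control()
  nb <- memo("er_to_rd_nb", vapply(c(350, 600, 900), function(cl)
    as.numeric(er_to_rd_beats(f$p, cl, cl + 20, n_cond = 150, n_follow = 50,
                              stim = f$stim)), numeric(1)))
  expect_true(all(diff(nb) <= 0))
  expect_gt(nb[1], nb[3])
})
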