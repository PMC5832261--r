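# Shared heavy fixtures, computed once per test session. Conditioned states
# are reused across test files; everything is deterministic (fixed stimulus,
# fixed dt, no RNG).

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

# control model, settled rest state, stimulus at 1.5x threshold
fix_control <- function() memo("control", {
  p <- tp06_params()
  rest <- settle_to_rest(p)
  stim <- stimulus_spec(p, rest)
  list(p = p, rest = rest, stim = stim)
})

# control conditioned 300 beats at CL 350 (end-of-cycle snapshot + steady APD)
fix_cond350 <- function() memo("cond350", {
  f <- fix_control()
  tr <- condition_at(f$p, 350, 300, initial_state = f$rest, stim = f$stim)
  list(state = final_state(tr), steady = steady_apd(tr), train = tr)
})

# conductance-modified model conditioned at 350: change applied acutely to
# the control-conditioned state, then 300 further beats
fix_scaled350 <- function(scale) {
  key <- paste0("scaled350_", paste(names(scale), scale, collapse = "_"))
  memo(key, {
    f <- fix_control()
    c0 <- fix_cond350()
    p <- tp06_params(scale = scale)
    tr <- resume_train(p, c0$state, rep(350, 300), f$stim)
    list(p = p, state = final_state(tr), steady = steady_apd(tr))
  })
}

# 200-beat periodic train (CL* 350, clv 35) from a conditioned state
fix_periodic <- function(omega, scale = NULL) {
  key <- paste0("per_", omega, "_", paste(names(scale), scale, collapse = "_"))
  memo(key, {
    f <- fix_control()
    src <- if (is.null(scale)) list(p = f$p, state = fix_cond350()$state)
           else fix_scaled350(scale)
    sched <- periodic_schedule(350, 35, omega, 200)
    tr <- resume_train(src$p, src$state, sched$CL_ms, f$stim)
    attr(tr, "meta") <- schedule_meta(sched)
    tr
  })
}

# a synthetic elliptical space of states with known geometry
make_ellipse_space <- function(center = c(350, 230), ax = 30, ay = 12,
                               theta = pi / 7, n = 400) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-1]
  x0 <- ax * cos(phi); y0 <- ay * sin(phi)
  x <- center[1] + x0 * cos(theta) - y0 * sin(theta)
  y <- center[2] + x0 * sin(theta) + y0 * cos(theta)
  sp <- data.frame(beat = seq_len(n) + 1, x_ms = x, APD_ms = y,
                   direction = sign(c(NA, diff(x))))
  sp$direction[1] <- 0
  structure(sp, mode = "vs_CL", meta = list(law = "periodic", CL_star = center[1]),
            class = c("space_of_states", "data.frame"))
}

# analytic vertical half-width of the rotated ellipse at its center x:
# full width = 2 * ay' where the vertical chord through the center has
# length 2*sqrt(...) -- derived from the implicit quadratic of the ellipse
ellipse_vertical_width <- function(ax, ay, theta) {
  # implicit form A x^2 + B x y + C y^2 = 1 (centered);
  # at x = 0 the chord is y = +/- 1/sqrt(C)
  A <- cos(theta)^2 / ax^2 + sin(theta)^2 / ay^2
  C <- sin(theta)^2 / ax^2 + cos(theta)^2 / ay^2
  B <- 2 * sin(theta) * cos(theta) * (1 / ax^2 - 1 / ay^2)
  # vertical extremes at x = 0: solve C y^2 = 1 minus cross term effect;
  # the chord through x = 0: C y^2 + B * 0 * y + A * 0 = 1
  2 / sqrt(C)
}

# analytic major-axis slope of the rotated ellipse
ellipse_major_slope <- function(theta) tan(theta)
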