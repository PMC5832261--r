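# Configuration-driven experiment runner and the registry of the study's
# figure protocols. Configs are plain lists, YAML or JSON; outputs are CSV
# (with a commented header carrying the resolved config) and JSON.

#' Registry of figure-protocol configurations
#'
#' Ready-made experiment configurations reproducing the study protocols:
#' spaces of states under random/periodic pacing, Shift grids over omega,
#' missing-beat perturbations under the three pacing laws, and the
#' constant-to-dynamic switch. All use the fast conditioning profile
#' (300 beats); set `full = TRUE` in the config for 1000-beat conditioning.
#'
#' @return named list of config lists accepted by [run_experiment()].
#' @export
experiment_registry <- function() {
  list(
    fig3 = list(
      protocol = "der", label = "space of states, fast periodic pacing",
      pacing = list(law = "periodic", CL_star = 350, clv = 35, omega = 2.4,
                    n_beats = 200)
    ),
    fig3_random = list(
      protocol = "der", label = "space of states, random pacing",
      pacing = list(law = "random", CL_star = 350, clv = 35, n_beats = 400,
                    seed = 1)
    ),
    fig5 = list(
      protocol = "shift_grid", label = "Shift_CL/Shift_DI over omega (scaled grid)",
      CL_star = 350, clv = 35, omega = seq(0.4, 2.4, by = 0.4), n_beats = 200
    ),
    fig8 = list(
      protocol = "perturb", label = "missing-beat recovery, three pacing laws",
      CL_star = 350, clv = 35, omega = 2.4, seed = 1, n_dynamic = 140,
      drops = 20
    ),
    fig11 = list(
      protocol = "switch", label = "alternans quenching by switch to periodic pacing",
      scale = list(IKs = 0.4), constant_CL = 350, n_const = 48,
      drop_index = 10,
      pacing = list(law = "periodic", CL_star = 350, clv = 35, omega = 2.4,
                    n_beats = 150)
    )
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path")
  config
}

config_field <- function(config, name, default = NULL, required = FALSE) {
  v <- config[[name]]
  if (is.null(v)) {
    if (required) stop("config field `", name, "` is required for protocol `",
                       config$protocol %||% "?", "`")
    return(default)
  }
  v
}

build_schedule <- function(p) {
  need <- function(f) p[[f]] %||%
    stop("pacing spec needs `", f, "` for law `", p$law %||% "?", "`")
  law <- need("law")
  n <- need("n_beats")
  switch(law,
    constant = constant_schedule(p$CL %||% need("CL_star"), n),
    random = random_schedule(need("CL_star"), need("clv"), n, need("seed")),
    periodic = periodic_schedule(need("CL_star"), need("clv"), need("omega"), n),
    alternating = alternating_schedule(need("CL_star"), need("clv"), n),
    stop("unknown pacing law `", law, "`")
  )
}

write_csv_with_header <- function(df, path, config) {
  hdr <- c(
    paste0("# apmem ", as.character(utils::packageVersion("apmem"))),
    paste0("# config: ", jsonlite::toJSON(config, auto_unbox = TRUE))
  )
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                      append = TRUE, quote = FALSE))
  invisible(path)
}

#' Run a configured experiment
#'
#' Executes one of the named protocols and writes its artifacts to
#' `out_dir`. Protocols: `"rd"` (rate-dependence curve), `"er"` (classic
#' restitution sweep), `"der"` (dynamic train, spaces of states and their
#' descriptors), `"shift_grid"` (Shift_CL/Shift_DI over omega),
#' `"perturb"` (missing-beat scan over the three pacing laws), `"switch"`
#' (constant-to-dynamic quenching), `"clamp"` (current time-dependence
#' removal fit), `"clstats"` (|dCL| distribution statistics).
#'
#' @param config list, or path to a YAML/JSON file. Common fields:
#'   `protocol` (required), `scale` (named conductance multipliers),
#'   `n_cond` (conditioning beats, default 300; `full = TRUE` selects
#'   1000), `dt`, `out_dir`. Protocol-specific fields as in the registry
#'   entries ([experiment_registry()]).
#' @param out_dir output directory (overrides `config$out_dir`; default a
#'   temporary directory).
#' @return named character vector of files written, invisibly; the computed
#'   result object as attribute `"result"`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  config <- read_config(config)
  protocol <- config_field(config, "protocol", required = TRUE)
  known <- c("rd", "er", "der", "shift_grid", "perturb", "switch", "clamp",
             "clstats")
  if (!protocol %in% known)
    stop("config field `protocol` must be one of: ",
         paste(known, collapse = ", "))
  out_dir <- out_dir %||% config_field(config, "out_dir", tempfile("apmem-"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dt <- config_field(config, "dt", 0.02)
  n_cond <- if (isTRUE(config$full)) 1000 else config_field(config, "n_cond", 300)
  scale <- config_field(config, "scale")
  params <- tp06_params()
  # conductance changes are applied acutely to the control-conditioned state
  # (see vignette); conditioning below handles that ordering
  files <- c()
  add <- function(name, path) files[[name]] <<- path

  condition_scaled <- function(CL) {
    base <- condition_at(params, CL, n_cond, dt = dt)
    stim <- attr(base, "stim")
    if (is.null(scale) || !length(scale)) {
      list(state = final_state(base), stim = stim, params = params)
    } else {
      mod <- scale_conductances(params, unlist(scale))
      tr <- resume_train(mod, final_state(base), rep(CL, n_cond), stim, dt = dt)
      list(state = final_state(tr), stim = stim, params = mod)
    }
  }

  result <- switch(protocol,
    rd = {
      cl <- config_field(config, "cl_values", seq(300, 1400, by = 20))
      curve <- rd_curve(params, cl, n_cond = n_cond, dt = dt)
      add("rd", write_csv_with_header(as.data.frame(curve),
                                      file.path(out_dir, "rd_curve.csv"), config))
      curve
    },
    er = {
      cl_star <- config_field(config, "CL_star", 350)
      cs <- condition_scaled(cl_star)
      er <- classic_er(cs$params, cl_star,
                       config_field(config, "half_width", 20),
                       config_field(config, "step", 5),
                       state = cs$state, stim = cs$stim, dt = dt)
      add("er_cl", write_csv_with_header(as.data.frame(er$vs_CL),
                                         file.path(out_dir, "er_cl.csv"), config))
      add("er_di", write_csv_with_header(as.data.frame(er$vs_DI),
                                         file.path(out_dir, "er_di.csv"), config))
      er
    },
    der = {
      sched <- build_schedule(config_field(config, "pacing", required = TRUE))
      cl_star <- schedule_meta(sched)$CL_star
      cs <- condition_scaled(cl_star)
      train <- resume_train(cs$params, cs$state, sched$CL_ms, cs$stim, dt = dt)
      attr(train, "meta") <- schedule_meta(sched)
      sp_cl <- space_of_states(train, "vs_CL")
      sp_di <- space_of_states(train, "vs_DI")
      desc <- list(
        shift_CL = as.numeric(shift(sp_cl, cl_star)),
        major_axis_slope_CL = as.numeric(major_axis_slope(sp_cl)),
        der_DI_slope = tryCatch(as.numeric(der_slope(sp_di)),
                                error = function(e) NA_real_),
        max_local_DI_slope = max_local_slope(sp_di)
      )
      add("space_cl", write_csv_with_header(as.data.frame(sp_cl),
                                            file.path(out_dir, "space_cl.csv"), config))
      add("space_di", write_csv_with_header(as.data.frame(sp_di),
                                            file.path(out_dir, "space_di.csv"), config))
      jsonlite::write_json(desc, file.path(out_dir, "descriptors.json"),
                           auto_unbox = TRUE, digits = NA)
      add("descriptors", file.path(out_dir, "descriptors.json"))
      list(train = train, descriptors = desc)
    },
    shift_grid = {
      cl_star <- config_field(config, "CL_star", 350)
      clv <- config_field(config, "clv", 35)
      omegas <- config_field(config, "omega", seq(0.4, 2.4, by = 0.4))
      nb <- config_field(config, "n_beats", 200)
      cs <- condition_scaled(cl_star)
      rows <- lapply(omegas, function(w) {
        sched <- periodic_schedule(cl_star, clv, w, nb)
        train <- resume_train(cs$params, cs$state, sched$CL_ms, cs$stim, dt = dt)
        attr(train, "meta") <- schedule_meta(sched)
        s_cl <- tryCatch(as.numeric(shift(space_of_states(train, "vs_CL"), cl_star)),
                         error = function(e) NA_real_)
        s_di <- tryCatch(as.numeric(shift(space_of_states(train, "vs_DI"))),
                         error = function(e) NA_real_)
        data.frame(omega = w, shift_CL = s_cl, shift_DI = s_di)
      })
      grid <- do.call(rbind, rows)
      add("shift_grid", write_csv_with_header(grid,
                                              file.path(out_dir, "shift_grid.csv"), config))
      grid
    },
    perturb = {
      cl_star <- config_field(config, "CL_star", 350)
      clv <- config_field(config, "clv", 35)
      omega <- config_field(config, "omega", 2.4)
      n_dyn <- config_field(config, "n_dynamic", 140)
      seed <- config_field(config, "seed", 1)
      cs <- condition_scaled(cl_star)
      scans <- list(
        constant = constant_schedule(cl_star, n_dyn),
        periodic = periodic_schedule(cl_star, clv, omega, n_dyn),
        random = random_schedule(cl_star, clv, n_dyn, seed)
      )
      res <- lapply(scans, function(sched)
        missing_beat_scan(cs$params, sched, first_drop = 41,
                          initial_state = cs$state, stim = cs$stim, dt = dt))
      tab <- data.frame(law = names(res),
                        mean_Nb = vapply(res, `[[`, numeric(1), "mean_Nb"))
      add("nb", write_csv_with_header(tab, file.path(out_dir, "nb.csv"), config))
      res
    },
    switch = {
      cs <- condition_scaled(config_field(config, "constant_CL", 350))
      sched <- build_schedule(config_field(config, "pacing", required = TRUE))
      sw <- switch_experiment(cs$params,
                              constant_CL = config_field(config, "constant_CL", 350),
                              n_const = config_field(config, "n_const", 48),
                              dynamic = sched,
                              drop_index = config_field(config, "drop_index", 10),
                              state = cs$state, stim = cs$stim, dt = dt)
      out <- sw[c("quenched", "beats_to_quench", "alternans_established")]
      jsonlite::write_json(out, file.path(out_dir, "switch.json"),
                           auto_unbox = TRUE, digits = NA)
      add("switch", file.path(out_dir, "switch.json"))
      sw
    },
    clamp = {
      cl_star <- config_field(config, "CL_star", 350)
      current <- config_field(config, "current", required = TRUE)
      cs <- condition_scaled(cl_star)
      cl <- fit_current_clamp(cs$params, current, reference_CL = cl_star,
                              state = cs$state, stim = cs$stim,
                              tol_action = config_field(config, "tol_action", "best"),
                              dt = dt)
      add("clamp", write_clamp_json(cl, file.path(out_dir,
                                                  paste0("clamp_", current, ".json"))))
      cl
    },
    clstats = {
      cl_star <- config_field(config, "CL_star", 350)
      clv <- config_field(config, "clv", 35)
      n <- config_field(config, "n_beats", 10000)
      stats_df <- cl_change_statistics(
        list(periodic = periodic_schedule(cl_star, clv,
                                          config_field(config, "omega", 2.4), n),
             random = random_schedule(cl_star, clv, n,
                                      config_field(config, "seed", 1))),
        config_field(config, "thresholds", 0:70))
      add("clstats", write_csv_with_header(stats_df,
                                           file.path(out_dir, "clstats.csv"), config))
      stats_df
    }
  )
  structure(invisible(unlist(files)), result = result)
}
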