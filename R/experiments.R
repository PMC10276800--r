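experiment_presets <- function() {
  list(
    fig3_scan = list(kind = "scan", preset = "fig11_travelling",
                     c1_values = seq(0.18, 0.35, by = 0.005)),
    fig5_standing = list(kind = "simulate", preset = "fig4_standing",
                         fixture = "gaussian_bump", T = 30, sigma = 0,
                         grid = list(x_min = -60, x_max = 60, n = 2400)),
    fig11_travelling = list(kind = "simulate", preset = "fig11_travelling",
                            fixture = "gaussian_bump", T = 12, sigma = 0),
    fig14_oscillation = list(kind = "simulate", preset = "fig14_oscillatory",
                             fixture = "homog_4v", T = 100, sigma = 0),
    fig16_noisy_oscillation = list(kind = "simulate", preset = "fig14_oscillatory",
                                   fixture = "homog_4v", T = 100, sigma = 0.01,
                                   mode = "full"),
    fig8_stats = list(kind = "stats", preset = "fig4_standing",
                      fixture = "homog_4v", T = 100,
                      sigmas = seq(0.03, 0.06, by = 0.002), runs = 100),
    fig4_wave = list(kind = "waves", preset = "fig4_standing",
                     fix_c_zero = TRUE, t_clip = 20, half_width = 1.5,
                     grid = list(x_min = -60, x_max = 60, n = 2400)),
    fig12_wave = list(kind = "waves", preset = "fig11_travelling",
                      fix_c_zero = FALSE, t_clip = 12, half_width = 6,
                      grid = list(x_min = -60, x_max = 60, n = 2400))
  )
}

#' Build an experiment configuration
#'
#' Experiment presets bundle the pipeline kind (`simulate`, `stats`, `scan`,
#' `waves`), parameter preset, fixture, horizon and noise settings used by
#' the figure-level studies. Any field can be overridden.
#'
#' @param name Experiment preset name (see names below) or `NULL` with all
#'   fields supplied via `...`: `fig3_scan`, `fig5_standing`,
#'   `fig11_travelling`, `fig14_oscillation`, `fig16_noisy_oscillation`,
#'   `fig8_stats`, `fig4_wave`, `fig12_wave`.
#' @param seed Base seed for stochastic runs.
#' @param out Output directory (created if needed).
#' @param ... Field overrides (e.g. `runs = 30`, `T = 50`, `sigma = 0.045`).
#' @return An `experiment_config` list.
#' @export
actin_experiment <- function(name, seed = 1L, out = tempfile("actinwaves_"),
                             ...) {
  presets <- experiment_presets()
  if (!name %in% names(presets)) {
    stop("unknown experiment '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(presets[[name]], list(...))
  cfg$name <- name
  cfg$seed <- as.integer(seed)
  cfg$out <- out
  structure(cfg, class = "experiment_config")
}

#' Run a configured experiment
#'
#' Executes the pipeline named by the configuration and writes its outputs
#' (fields as full-precision CSV + JSON, tables as CSV) together with a JSON
#' echo of the fully resolved configuration, so every artefact records how it
#' was produced. Replaying a config with identical seeds reproduces the
#' statistics files byte for byte.
#'
#' @param config An [actin_experiment()] configuration.
#' @return Invisibly, a list with the computed result object and the paths
#'   written.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  params <- actin_preset(config$preset)
  grid <- if (is.null(config$grid)) wave_grid() else
    do.call(wave_grid, config$grid)
  paths <- character()
  t0 <- Sys.time()
  result <- switch(config$kind,
    scan = {
      tab <- scan_eigenvalues(params, config$c1_values)
      pth <- file.path(config$out, "eigen_scan.csv")
      utils::write.csv(tab, pth, row.names = FALSE)
      paths <- pth
      tab
    },
    simulate = {
      ic <- make_initial_condition(config$fixture, params, grid,
                                   seed = config$seed)
      net <- actin_network(params)
      f <- if (config$sigma > 0) {
        simulate_cle(net, grid, ic, config$T,
                     noise = noise_config(mode = config$mode %||% "full",
                                          sigma = config$sigma,
                                          seed = config$seed))
      } else {
        simulate_rde(net, grid, ic, config$T)
      }
      prefix <- file.path(config$out, "field")
      write_kymograph(f, prefix)
      paths <- paste0(prefix, c("_u.csv", "_v.csv", ".json"))
      f
    },
    stats = {
      st <- ensemble_event_stats(params, sigmas = config$sigmas,
                                 n_runs = config$runs, T = config$T,
                                 base_seed = config$seed, grid = grid)
      p1 <- file.path(config$out, "ensemble_summary.csv")
      p2 <- file.path(config$out, "events.csv")
      utils::write.csv(st$summary, p1, row.names = FALSE)
      utils::write.csv(st$events, p2, row.names = FALSE)
      paths <- c(p1, p2)
      st
    },
    waves = {
      seeded <- seed_wave_profile(params, grid, t_clip = config$t_clip,
                                  half_width = config$half_width %||% 5)
      prof <- solve_wave_profile(params, grid, seeded$init,
                                 init_c = seeded$init_c,
                                 fix_c_zero = isTRUE(config$fix_c_zero))
      prefix <- file.path(config$out, "wave_profile")
      write_wave_profile(prof, prefix)
      paths <- paste0(prefix, c(".csv", ".json"))
      prof
    },
    stop("unknown experiment kind '", config$kind, "'", call. = FALSE)
  )
  echo <- unclass(config)
  echo$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  cfg_path <- file.path(config$out, "config.json")
  jsonlite::write_json(echo, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  message(sprintf("[%s] done in %.1f s -> %s", config$name, echo$elapsed_s,
                  config$out))
  invisible(list(result = result, paths = c(paths, cfg_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seed the wave solver from a PDE simulation
#'
#' Runs the deterministic simulation from the Gaussian-bump fixture, lets the
#' initial condition split into two counter-propagating pulses, clips the
#' left-moving pulse, and estimates its speed — the crude starting point the
#' profile solver needs.
#'
#' @param params An [actin_params()] object.
#' @param grid A [wave_grid()]; the pulse must stay clear of the boundary up
#'   to `t_clip`.
#' @param t_clip Snapshot time for clipping.
#' @param half_width Window half-width passed to [clip_wave_pulse()].
#' @return List with `init` (profile), `init_c` (measured speed), and the
#'   simulation `field`.
#' @export
seed_wave_profile <- function(params, grid = wave_grid(), t_clip = NULL,
                              half_width = 5) {
  det <- actin_preset_like(params, sigma = 0)
  ic <- make_initial_condition("gaussian_bump", det, grid)
  # pick a clip time before the pulses reach the boundary
  if (is.null(t_clip)) t_clip <- 0.35 * grid$length / 2 / 2.2
  f <- simulate_rde(actin_network(det), grid, ic, T = t_clip)
  init <- clip_wave_pulse(f, time = t_clip, x_range = c(grid$x_min, 0),
                          half_width = half_width)
  init_c <- tryCatch(
    measure_speed(f, window = c(t_clip / 2, t_clip),
                  x_range = c(grid$x_min, -grid$dx)),
    error = function(e) 0)
  list(init = init, init_c = init_c, field = f)
}

# copy of params with a different noise level (preserving the preset tag)
actin_preset_like <- function(params, sigma) {
  p <- actin_params(a1 = params$a1, a2 = params$a2, a3 = params$a3,
                    a4 = params$a4, a5 = params$a5, c1 = params$c1,
                    c2 = params$c2, eps = params$eps, Du = params$Du,
                    Dv = params$Dv, sigma = sigma)
  attr(p, "preset") <- attr(params, "preset")
  p
}
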