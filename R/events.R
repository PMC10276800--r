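.threshold_cache <- new.env(parent = emptyenv())

#' Default activation-detection threshold for a parameter set
#'
#' Activation events are super-threshold patches of activator in the
#' kymograph. The default threshold adapts to the parameter set:
#' `u* + 0.25 (u_pulse_max - u*)`, where `u_pulse_max` is the maximum of the
#' deterministic pulse grown from the Gaussian-bump initial condition (the
#' late-time maximum of a short deterministic run). The value is cached per
#' parameter set.
#'
#' The reference run uses a large domain (`[-60, 60)`) so that the two pulses
#' grown from the bump are still alive and settled when the maximum is read
#' off (on small periodic domains they annihilate through the boundary).
#'
#' @param params An [actin_params()] object.
#' @param grid Grid used for the reference deterministic run.
#' @return Threshold on `u` (concentration, model units).
#' @export
default_event_threshold <- function(params, grid = wave_grid(-60, 60, 2400)) {
  key <- paste(unlist(params[c("a1","a2","a3","a4","a5","c1","c2","eps","Du","Dv")]),
               collapse = "|")
  hit <- .threshold_cache[[key]]
  if (!is.null(hit)) return(hit)
  bg <- background_states(params)
  us <- bg$u_star[1]
  det <- actin_params(a1 = params$a1, a2 = params$a2, a3 = params$a3,
                      a4 = params$a4, a5 = params$a5, c1 = params$c1,
                      c2 = params$c2, eps = params$eps, Du = params$Du,
                      Dv = params$Dv, sigma = 0)
  ic <- make_initial_condition("gaussian_bump", det, grid)
  f <- simulate_rde(actin_network(det), grid, ic, T = 15)
  pulse_max <- max(f$u[f$times >= 5, ])
  thr <- us + 0.25 * (pulse_max - us)
  .threshold_cache[[key]] <- thr
  thr
}

# label 8-connected components of a logical matrix (rows = time, columns =
# space, periodic in columns); compiled flood fill
label_components <- function(mask) {
  label_components_cpp(mask)
}

# occupied circular span (in cells) of a set of column indices
circular_span <- function(cols, nx) {
  cols <- sort(unique(cols))
  if (length(cols) == nx) return(nx)
  d <- diff(c(cols, cols[1] + nx))
  nx - max(d) + 1L
}

#' Detect activation events in a kymograph
#'
#' Thresholds the activator field and labels connected components of the
#' super-threshold mask on the space-time lattice (8-connectivity, periodic
#' wrap in space only); components smaller than `min_cells` cells are
#' discarded. Each surviving component is one activation event, characterised
#' by its onset, duration ("length"), spatial width (periodic-aware: domain
#' length minus the largest empty gap in the component's x-projection), and
#' peak activator value. Deterministic for a fixed field.
#'
#' @param field A `kymograph`.
#' @param threshold Detection threshold on `u`; defaults to
#'   [default_event_threshold()] for the field's parameters.
#' @param min_cells Minimum component size in lattice cells.
#' @return A tibble with one row per event: `event`, `t_on`, `t_off`,
#'   `duration`, `width`, `u_max`, `n_cells`. Zero rows if nothing is
#'   detected.
#' @export
detect_events <- function(field, threshold = NULL, min_cells = 8) {
  stopifnot(inherits(field, "kymograph"))
  if (is.null(threshold)) threshold <- default_event_threshold(field$params)
  dt_s <- sampling_dt(field)
  dx <- field$grid$dx
  mask <- field$u > threshold
  empty <- tibble(event = integer(), t_on = numeric(), t_off = numeric(),
                  duration = numeric(), width = numeric(), u_max = numeric(),
                  n_cells = integer())
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  on <- which(lab > 0L)
  comps <- split(on, lab[on])
  rows <- lapply(comps, function(idx) {
    if (length(idx) < min_cells) return(NULL)
    i <- ((idx - 1L) %% nrow(mask)) + 1L
    j <- ((idx - 1L) %/% nrow(mask)) + 1L
    t_on <- field$times[min(i)]
    duration <- (max(i) - min(i) + 1L) * dt_s
    tibble(t_on = t_on, t_off = t_on + duration, duration = duration,
           width = circular_span(j, ncol(mask)) * dx,
           u_max = max(field$u[idx]),
           n_cells = length(idx))
  })
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) == 0L) return(empty)
  rows <- dplyr::arrange(rows, .data$t_on)
  dplyr::mutate(rows, event = dplyr::row_number(), .before = 1)
}

#' Ensemble event statistics across noise intensities
#'
#' Runs the chemical Langevin simulation repeatedly for each noise intensity
#' (seeds `base_seed + run - 1`), with the homogeneous `(u*, 4 v*)` initial
#' condition plus a small seeded perturbation, detects activation events in
#' every run, and aggregates counts and per-event width, duration and
#' maximum.
#'
#' @param params An [actin_params()] object.
#' @param sigmas Numeric vector of noise intensities.
#' @param n_runs Runs per intensity (at least 2).
#' @param T Time horizon per run.
#' @param base_seed Base seed; run `i` uses `base_seed + i - 1`.
#' @param grid A [wave_grid()].
#' @param mode,variance_convention Passed to [noise_config()].
#' @param threshold,min_cells Event-detector settings; the threshold defaults
#'   to [default_event_threshold()] computed once, and `min_cells` to the
#'   number of lattice cells covering the same space-time area as 8 cells at
#'   the reference sampling (dx = 0.05, frame spacing 0.1), so detection does
#'   not depend on the save cadence.
#' @param fixture Initial-condition fixture name (default `"homog_4v"`).
#' @return An `ensemble_stats` object: `$summary` (one row per sigma with
#'   per-run event-count mean/sd and across-event width/duration/max
#'   mean/sd), `$events` (one row per detected event, tagged with `sigma`
#'   and `run`), plus the detector settings.
#' @export
ensemble_event_stats <- function(params, sigmas, n_runs, T = 100,
                                 base_seed = 1, grid = wave_grid(),
                                 mode = "full",
                                 variance_convention = "sum_of_propensities",
                                 threshold = NULL, min_cells = NULL,
                                 fixture = "homog_4v") {
  stopifnot(inherits(params, "actin_params"), n_runs >= 2)
  if (is.null(threshold)) threshold <- default_event_threshold(params)
  net <- actin_network(params)
  # frames spaced <= dx/4 in time so that travelling events (|c| up to 4)
  # advance at most one cell per frame and stay 8-connected
  dt <- default_dt(params, grid)
  save_every <- max(1L, floor((grid$dx / 4) / dt))
  if (is.null(min_cells)) {
    # sampling-invariant size filter: the same space-time area as 8 lattice
    # cells at the reference cadence (dx = 0.05, frame spacing 0.1)
    dt_frame <- save_every * dt
    min_cells <- max(8L, as.integer(round(8 * 0.05 * 0.1 / (grid$dx * dt_frame))))
  }
  all_events <- list()
  counts <- list()
  for (sig in sigmas) {
    for (i in seq_len(n_runs)) {
      seed <- base_seed + i - 1
      ic <- make_initial_condition(fixture, params, grid, seed = seed)
      f <- tryCatch(
        simulate_cle(net, grid, ic, T, save_every = save_every,
                     noise = noise_config(mode = mode,
                                          variance_convention = variance_convention,
                                          sigma = sig, seed = seed)),
        error = function(e) stop("run ", i, " at sigma = ", sig, ": ",
                                 conditionMessage(e), call. = FALSE))
      ev <- detect_events(f, threshold = threshold, min_cells = min_cells)
      counts[[length(counts) + 1L]] <- tibble(sigma = sig, run = i,
                                              n_events = nrow(ev))
      if (nrow(ev) > 0) {
        all_events[[length(all_events) + 1L]] <-
          dplyr::mutate(ev, sigma = sig, run = i, .before = 1)
      }
    }
  }
  counts <- dplyr::bind_rows(counts)
  events <- if (length(all_events)) dplyr::bind_rows(all_events) else
    tibble(sigma = numeric(), run = integer(), event = integer(),
           t_on = numeric(), t_off = numeric(), duration = numeric(),
           width = numeric(), u_max = numeric(), n_cells = integer())
  count_sum <- counts |>
    dplyr::group_by(.data$sigma) |>
    dplyr::summarise(n_runs = dplyr::n(),
                     mean_count = mean(.data$n_events),
                     sd_count = stats::sd(.data$n_events), .groups = "drop")
  ev_sum <- events |>
    dplyr::group_by(.data$sigma) |>
    dplyr::summarise(mean_width = mean(.data$width),
                     sd_width = stats::sd(.data$width),
                     mean_duration = mean(.data$duration),
                     sd_duration = stats::sd(.data$duration),
                     mean_max = mean(.data$u_max),
                     sd_max = stats::sd(.data$u_max), .groups = "drop")
  summary <- dplyr::left_join(count_sum, ev_sum, by = "sigma")
  structure(list(summary = summary, events = events, counts = counts,
                 threshold = threshold, min_cells = min_cells,
                 base_seed = base_seed, T = T, mode = mode),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("<ensemble_stats> %d sigma value(s), threshold = %.4g, mode = %s\n",
              nrow(x$summary), x$threshold, x$mode))
  print(x$summary)
  invisible(x)
}

#' @rdname ensemble_event_stats
#' @param x An `ensemble_stats` object.
#' @param ... Unused.
#' @export
tidy.ensemble_stats <- function(x, ...) x$summary

#' Estimate the oscillation period
#'
#' For a kymograph, averages the activator over space and measures the mean
#' spacing between successive prominence-filtered local maxima of the
#' resulting time series, after discarding an initial transient. At least
#' three maxima are required.
#'
#' @param x A `kymograph`, or a numeric time series (then supply `times`).
#' @param times Sample times for the numeric method.
#' @param transient Initial time span to discard (default 10).
#' @param prominence Minimum peak prominence as a fraction of the signal
#'   range after the transient (default 0.25).
#' @param ... Passed between methods.
#' @return Estimated period (model time units).
#' @export
estimate_period <- function(x, ...) UseMethod("estimate_period")

#' @rdname estimate_period
#' @export
estimate_period.kymograph <- function(x, transient = 10, prominence = 0.25, ...) {
  estimate_period(rowMeans(x$u), times = x$times, transient = transient,
                  prominence = prominence)
}

#' @rdname estimate_period
#' @export
estimate_period.numeric <- function(x, times, transient = 10,
                                    prominence = 0.25, ...) {
  stopifnot(length(x) == length(times))
  keep <- times >= transient
  y <- x[keep]; tt <- times[keep]
  rng <- diff(range(y))
  if (rng <= 0) stop("signal is constant after the transient", call. = FALSE)
  dt_s <- stats::median(diff(tt))
  pk <- pracma::findpeaks(y, minpeakheight = min(y) + prominence * rng,
                          minpeakdistance = max(1L, round(0.5 / dt_s)))
  if (is.null(pk) || nrow(pk) < 3) {
    stop("fewer than 3 maxima after the transient; cannot estimate a period",
         call. = FALSE)
  }
  mean(diff(sort(tt[pk[, 2]])))
}

#' Histograms of event width, duration and maximum
#'
#' Fixed-bin-width histograms of the per-event quantities, with the
#' conventional bin widths 0.25 for width and duration and 0.1 for the
#' maximum. Bins are aligned at zero.
#'
#' @param events Event tibble from [detect_events()] (non-empty).
#' @param bin_widths Named bin widths for `width`, `duration`, `u_max`.
#' @return A tibble with columns `quantity`, `bin_left`, `bin_mid`, `count`.
#' @export
event_histograms <- function(events,
                             bin_widths = c(width = 0.25, duration = 0.25,
                                            u_max = 0.1)) {
  if (nrow(events) == 0L) stop("empty event list", call. = FALSE)
  out <- lapply(names(bin_widths), function(q) {
    bw <- bin_widths[[q]]
    vals <- events[[q]]
    bin <- floor(vals / bw)
    tab <- table(bin)
    tibble(quantity = q,
           bin_left = as.numeric(names(tab)) * bw,
           bin_mid = (as.numeric(names(tab)) + 0.5) * bw,
           count = as.integer(tab))
  })
  dplyr::bind_rows(out)
}
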