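#' Exact well-mixed stochastic simulation (Gillespie direct method)
#'
#' Simulates the six-reaction kinetics exactly at the level of integer
#' molecule counts. Propensities are the concentration-level rates converted
#' to count-rates at system size `omega` (molecules per unit concentration):
#' linear terms scale as `a * count`, the bimolecular term as
#' `a2 n_u n_v / omega`, the Hill term is evaluated on the concentration
#' `n_u/omega` and multiplied by `omega`, and the zeroth-order source is
#' `a5 omega`. Waiting times are exponential; counts never go negative.
#'
#' @param network An actin [reaction_network()] (supplies the rate constants).
#' @param omega System size.
#' @param x0 Integer initial counts `c(u, v)`.
#' @param T Time horizon.
#' @param seed Integer RNG seed.
#' @param n_save Number of equally spaced sample times in `[0, T]`.
#' @return An `ssa_trajectory`: `times`, `u_counts`, `v_counts`,
#'   concentrations `u`, `v` (`counts/omega`), `n_events`,
#'   `first_event_time`, `omega`, `seed`.
#' @export
simulate_ssa_wellmixed <- function(network, omega, x0, T, seed = 1L,
                                   n_save = 201L) {
  stopifnot(inherits(network, "reaction_network"),
            identical(network$kinetics, "actin"),
            omega > 0, all(x0 >= 0), all(x0 == round(x0)))
  save_times <- seq(0, T, length.out = n_save)
  res <- ssa_wellmixed_cpp(unclass(network$params), omega,
                           as.double(x0[1]), as.double(x0[2]),
                           save_times, as.double(seed))
  structure(
    list(times = save_times,
         u_counts = res$u_counts, v_counts = res$v_counts,
         u = res$u_counts / omega, v = res$v_counts / omega,
         n_events = res$n_events, first_event_time = res$first_event_time,
         omega = omega, seed = seed),
    class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("<ssa_trajectory> omega = %g, %g reaction events, T = %g\n",
              x$omega, x$n_events, max(x$times)))
  invisible(x)
}

#' @rdname simulate_ssa_wellmixed
#' @param x An `ssa_trajectory`.
#' @param ... Unused.
#' @export
as_tibble.ssa_trajectory <- function(x, ...) {
  tibble(t = x$times, u_count = x$u_counts, v_count = x$v_counts,
         u = x$u, v = x$v)
}

#' Spatial stochastic simulation (reaction-diffusion master equation)
#'
#' Exact spatial SSA on a periodic grid: per-cell reactions (count-rate
#' conversion at cell size `omega * dx`) plus diffusion as jump events, each
#' molecule hopping to either neighbour at rate `D/dx^2`. Snapshots are
#' returned as concentration fields (`counts/(omega dx)`) in the same
#' kymograph container as the PDE solvers, for direct comparison.
#'
#' @inheritParams simulate_ssa_wellmixed
#' @param grid A [wave_grid()].
#' @param ic_counts List with non-negative integer vectors `u`, `v` of
#'   per-cell molecule counts, or `NULL` to discretise `ic_conc`.
#' @param ic_conc Concentration initial condition (list `u`, `v`) converted
#'   to counts by rounding `conc * omega * dx`; ignored if `ic_counts` given.
#' @param reactions_on Set `FALSE` for a diffusion-only run (reaction
#'   channels disabled).
#' @return A `kymograph` of concentrations with extra fields `omega` and
#'   `n_events`.
#' @export
simulate_rdme <- function(network, grid, omega, ic_counts = NULL,
                          ic_conc = NULL, T, seed = 1L, n_save = 101L,
                          reactions_on = TRUE) {
  stopifnot(inherits(network, "reaction_network"),
            identical(network$kinetics, "actin"),
            inherits(grid, "wave_grid"), omega > 0)
  if (is.null(ic_counts)) {
    if (is.null(ic_conc)) stop("supply `ic_counts` or `ic_conc`", call. = FALSE)
    ic_counts <- list(u = round(ic_conc$u * omega * grid$dx),
                      v = round(ic_conc$v * omega * grid$dx))
  }
  stopifnot(length(ic_counts$u) == grid$n, length(ic_counts$v) == grid$n,
            all(ic_counts$u >= 0), all(ic_counts$v >= 0),
            all(ic_counts$u == round(ic_counts$u)),
            all(ic_counts$v == round(ic_counts$v)))
  save_times <- seq(0, T, length.out = n_save)
  res <- rdme_cpp(unclass(network$params), omega, grid$dx,
                  as.double(ic_counts$u), as.double(ic_counts$v),
                  save_times, as.double(seed), reactions_on)
  vol <- omega * grid$dx
  field <- new_kymograph(res$u_counts / vol, res$v_counts / vol, save_times,
                         grid, network$params, seed = seed)
  field$u_counts <- res$u_counts
  field$v_counts <- res$v_counts
  field$omega <- omega
  field$n_events <- res$n_events
  field
}
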