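#' Named initial-condition fixtures
#'
#' The initial conditions used by the simulation studies, all built on top of
#' the background state `(u*, v*)` of the supplied parameters:
#' * `"gaussian_bump"` — `u0 = u* + exp(-x^2)`, `v0 = v* + 2/cosh(5x)^2`;
#'   a crude localised-wave approximation that splits into two
#'   counter-propagating pulses.
#' * `"homog_4v"` — homogeneous `(u*, 4 v*)` plus a small seeded perturbation
#'   on `u` (uniform, amplitude `perturbation * u*`); the ensemble-statistics
#'   protocol.
#' * `"homog_2v"` — homogeneous `(u*, 2 v*)`; the wild-type / PTEN-null
#'   comparison protocol.
#' * `"homog_eq"` — the homogeneous equilibrium `(u*, v*)`.
#' * `"from_file"` — read `u0`, `v0` from a two-column CSV (`u`, `v`).
#'
#' @param fixture Fixture name.
#' @param params An [actin_params()] object.
#' @param grid A [wave_grid()].
#' @param seed Integer seed used for the `"homog_4v"` perturbation.
#' @param perturbation Relative perturbation amplitude (default `1e-2`).
#' @param file Path for `"from_file"`.
#' @return List with numeric vectors `u` and `v` of length `grid$n`.
#' @examples
#' p <- actin_preset("fig4_standing")
#' ic <- make_initial_condition("gaussian_bump", p, wave_grid())
#' @export
make_initial_condition <- function(fixture, params, grid, seed = 1L,
                                   perturbation = 1e-2, file = NULL) {
  stopifnot(inherits(params, "actin_params"), inherits(grid, "wave_grid"))
  bg <- background_states(params)
  if (nrow(bg) == 0L) stop("no positive background state", call. = FALSE)
  us <- bg$u_star[1]; vs <- bg$v_star[1]
  x <- grid$x
  n <- grid$n
  switch(fixture,
    gaussian_bump = list(u = us + exp(-x^2), v = vs + 2 / cosh(5 * x)^2),
    homog_4v = {
      set.seed(seed)
      list(u = us + perturbation * us * runif(n, -1, 1), v = rep(4 * vs, n))
    },
    homog_2v = list(u = rep(us, n), v = rep(2 * vs, n)),
    homog_eq = list(u = rep(us, n), v = rep(vs, n)),
    from_file = {
      if (is.null(file)) stop("`file` is required for fixture 'from_file'",
                              call. = FALSE)
      d <- read.csv(file)
      if (nrow(d) != n) stop("file has ", nrow(d), " rows, grid has ", n,
                             call. = FALSE)
      list(u = d$u, v = d$v)
    },
    stop("unknown fixture '", fixture, "'", call. = FALSE)
  )
}
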