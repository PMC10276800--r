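#' Noise configuration for the chemical Langevin equation
#'
#' Selects which stochastic terms enter the mesoscopic simulation:
#' * `"full"` — multiplicative reaction noise plus the conservative
#'   diffusion-noise flux term \eqn{\partial_x(\sqrt{2 D X}\, d\tilde W)};
#' * `"reaction_only"` — reaction noise with the diffusion flux term set to
#'   zero (the analytically tractable ablation);
#' * `"additive_u"` — all structured noise replaced by additive space-time
#'   white noise on the activator only (the naive ablation).
#'
#' `variance_convention` controls the inhibitor reaction-noise amplitude.
#' The diagonal of `S diag(R) S^T` gives variance
#' \eqn{\varepsilon(c_1 v + c_2 u)} (`"sum_of_propensities"`, the default:
#' both inhibitor reactions add variance). The alternative `"as_printed"`
#' uses the signed form \eqn{\varepsilon(-c_1 v + c_2 u)}, which mirrors the
#' drift and vanishes exactly at the background state; it is exposed for
#' fidelity experiments. Negative variance arguments are clamped to zero
#' before the square root.
#'
#' @param mode One of `"full"`, `"reaction_only"`, `"additive_u"`.
#' @param variance_convention `"sum_of_propensities"` or `"as_printed"`.
#' @param sigma Noise strength (`1/sqrt(omega)`).
#' @param seed Integer seed for the simulation RNG.
#' @return A `noise_config` object.
#' @export
noise_config <- function(mode = c("full", "reaction_only", "additive_u"),
                         variance_convention = c("sum_of_propensities", "as_printed"),
                         sigma = 0.045, seed = 1L) {
  mode <- match.arg(mode)
  variance_convention <- match.arg(variance_convention)
  stopifnot(is.finite(sigma), sigma >= 0, is.finite(seed))
  structure(list(mode = mode, variance_convention = variance_convention,
                 sigma = sigma, seed = as.integer(seed)),
            class = "noise_config")
}

#' Per-species reaction-noise amplitude
#'
#' The standard deviation of the reaction noise per species, i.e. the square
#' root of the diagonal of `S diag(R(X)) S^T` (which is diagonal here because
#' no reaction changes both species). For the actin network the activator
#' amplitude squared is `(a1 + a2 v) u + a3 u^2/(a4+u^2) + a5` under either
#' convention; the inhibitor amplitude squared is `eps (c1 v + c2 u)` under
#' `"sum_of_propensities"` and `eps (-c1 v + c2 u)` under `"as_printed"`.
#' Negative arguments are clamped to zero before the square root.
#'
#' @param network A [reaction_network()].
#' @param state Species vector or species x cells matrix.
#' @param variance_convention See [noise_config()].
#' @return Amplitudes with the shape of `state`.
#' @export
reaction_noise_amplitude <- function(network, state,
                                     variance_convention = c("sum_of_propensities",
                                                             "as_printed")) {
  variance_convention <- match.arg(variance_convention)
  R <- propensities(network, state)
  if (is.null(dim(R))) R <- matrix(R, ncol = 1)
  if (variance_convention == "sum_of_propensities") {
    v2 <- (network$stoich^2) %*% R
  } else {
    # signed form: variance mirrors the drift S R
    v2 <- network$stoich %*% R
    # the activator row of S has entries +-1 only, so |S| R == S^2 R there;
    # keep the summed form for u and the signed form for v
    v2[1, ] <- ((network$stoich^2) %*% R)[1, ]
  }
  out <- sqrt(pmax(v2, 0))
  if (is.matrix(state)) out else drop(out)
}

#' Conservative diffusion-noise increment
#'
#' One Euler step of the discretised flux term
#' \eqn{\partial_x(\sqrt{2 D X}\, d\tilde W)} for a single species: one
#' independent standard normal per cell interface,
#' `F[k+1/2] = sqrt(2 D max(0, (X[k]+X[k+1])/2)) * xi / sqrt(dx dt)`, and
#' increment `(F[k+1/2] - F[k-1/2]) * dt / dx` with periodic interfaces.
#' Fluxes telescope on the circle, so the increment sums to zero exactly.
#' The amplitude prefactor `sigma` is applied by the caller.
#'
#' @param state Non-negative species values per cell (clamped upstream).
#' @param D Diffusion coefficient.
#' @param dx,dt Space and time steps.
#' @return Numeric increment vector, one entry per cell.
#' @export
diffusion_noise_increment <- function(state, D, dx, dt) {
  n <- length(state)
  mid <- pmax(0, (state + state[c(2:n, 1)]) / 2)
  Fp <- sqrt(2 * D * mid) * rnorm(n) / sqrt(dx * dt)
  (Fp - Fp[c(n, 1:(n - 1))]) * dt / dx
}

#' Integrate the chemical Langevin equation
#'
#' Euler-Maruyama integration of the mesoscopic stochastic PDE: the
#' deterministic reaction-diffusion drift plus, per cell and species,
#' multiplicative reaction noise
#' `sigma * amplitude * N(0,1) * sqrt(dt/dx)` and (in `"full"` mode) the
#' conservative diffusion-noise increment. In the multiplicative-noise modes
#' states are clamped to zero after each step (the Langevin approximation
#' does not preserve positivity) and the fraction of clamped cell-updates is
#' recorded; the `"additive_u"` ablation is left unclamped, as its solutions
#' are allowed to go negative. In the
#' no-noise limit `sigma = 0` the trajectory coincides with [simulate_rde()]
#' to machine precision.
#'
#' @inheritParams simulate_rde
#' @param noise A [noise_config()]; its `seed` makes the run reproducible.
#' @return A `kymograph` with the noise configuration attached.
#' @examples
#' p <- actin_preset("fig4_standing")
#' g <- wave_grid(n = 64)
#' ic <- make_initial_condition("homog_4v", p, g, seed = 1)
#' f <- simulate_cle(actin_network(p), g, ic, T = 2,
#'                   noise = noise_config(sigma = 0.03, seed = 1))
#' @export
simulate_cle <- function(network, grid, ic, T, dt = NULL,
                         noise = noise_config(), save_every = NULL) {
  stopifnot(inherits(network, "reaction_network"), inherits(grid, "wave_grid"),
            inherits(noise, "noise_config"))
  params <- network$params
  st <- resolve_stepping(params, grid, T, dt, save_every)
  check_ic(ic, grid)
  mode_code <- match(noise$mode, c("full", "reaction_only", "additive_u"))
  conv_code <- match(noise$variance_convention,
                     c("sum_of_propensities", "as_printed")) - 1L
  if (identical(network$kinetics, "actin")) {
    res <- sim_actin_cpp(ic$u, ic$v, grid$dx, st$dt, st$nsteps, st$save_every,
                         unclass(params), noise$sigma, mode_code, conv_code,
                         as.double(noise$seed))
  } else {
    res <- sim_generic_r(network, grid, ic, st, sigma = noise$sigma,
                         noise = noise, seed = noise$seed)
  }
  finish_field(res, st, grid, params, noise = noise, seed = noise$seed)
}
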