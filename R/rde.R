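#' Periodic second-difference Laplacian
#'
#' Second-order central difference `(f[k-1] - 2 f[k] + f[k+1]) / dx^2` with
#' wraparound indices; the discrete operator conserves mass (its output sums
#' to zero for any input).
#'
#' @param f Numeric vector of length >= 3 (one value per grid cell).
#' @param dx Cell width.
#' @return Numeric vector of the same length.
#' @export
laplacian_periodic <- function(f, dx) {
  n <- length(f)
  if (n < 3) stop("`f` must have length >= 3", call. = FALSE)
  (f[c(n, 1:(n - 1))] - 2 * f + f[c(2:n, 1)]) / dx^2
}

default_dt <- function(params, grid, cfl = 0.2) {
  cfl * grid$dx^2 / max(params$Du, params$Dv)
}

# Resolve (dt, nsteps, save_every) so that nsteps is a multiple of save_every
# and nsteps*dt >= T (the horizon may overshoot by < one frame).
resolve_stepping <- function(params, grid, T, dt, save_every) {
  if (is.null(dt)) dt <- default_dt(params, grid)
  stab <- default_dt(params, grid, cfl = 0.5)
  if (dt > stab) {
    stop(sprintf("dt = %g exceeds the diffusive stability limit %g", dt, stab),
         call. = FALSE)
  }
  if (is.null(save_every)) save_every <- max(1L, round(0.1 / dt))
  nsteps <- as.integer(save_every * ceiling(T / (dt * save_every)))
  list(dt = dt, nsteps = nsteps, save_every = as.integer(save_every))
}

finish_field <- function(res, st, grid, params, noise = NULL, seed = NULL) {
  if (res$bad_time >= 0) {
    stop(sprintf("integration blew up (non-finite state) at t = %g", res$bad_time),
         call. = FALSE)
  }
  times <- (seq_len(res$nframes) - 1) * st$save_every * st$dt
  new_kymograph(res$u[seq_len(res$nframes), , drop = FALSE],
                res$v[seq_len(res$nframes), , drop = FALSE],
                times, grid, params, noise = noise, seed = seed,
                clamp_fraction = res$clamp_fraction)
}

#' Integrate the deterministic reaction-diffusion equation
#'
#' Method-of-lines integration of
#' \deqn{\partial_t u = D_u \partial_{xx} u - a_1 u - a_2 u v
#'   + a_3 u^2/(a_4+u^2) + a_5, \quad
#'   \partial_t v = D_v \partial_{xx} v + \varepsilon(-c_1 v + c_2 u)}
#' on a periodic grid with explicit Euler stepping. The default step is
#' `dt = 0.2 dx^2 / max(Du, Dv)`. Concentrations are not clamped: the
#' deterministic flow preserves positivity for this kinetics from positive
#' initial data. Bit-stable for fixed inputs.
#'
#' @param network A [reaction_network()]; networks with the built-in actin
#'   kinetics use a compiled stepper, any other network is integrated by an
#'   equivalent R path.
#' @param grid A [wave_grid()].
#' @param ic List with numeric vectors `u` and `v` of length `grid$n`
#'   (see [make_initial_condition()]).
#' @param T Time horizon (model units). The realised horizon may overshoot by
#'   less than one saved frame so that frames are equally spaced.
#' @param dt Time step; `NULL` for the default.
#' @param save_every Save every this many steps; `NULL` targets a frame
#'   spacing of about 0.1 time units. Analysis functions read the realised
#'   spacing from the returned object via [sampling_dt()].
#' @return A `kymograph` object.
#' @examples
#' p <- actin_preset("fig4_standing")
#' g <- wave_grid(n = 64)
#' ic <- make_initial_condition("homog_eq", p, g)
#' f <- simulate_rde(actin_network(p), g, ic, T = 1)
#' max(abs(f$u - f$u[1, 1]))  # equilibrium is invariant
#' @export
simulate_rde <- function(network, grid, ic, T, dt = NULL, save_every = NULL) {
  stopifnot(inherits(network, "reaction_network"), inherits(grid, "wave_grid"))
  params <- network$params
  st <- resolve_stepping(params, grid, T, dt, save_every)
  check_ic(ic, grid)
  if (identical(network$kinetics, "actin")) {
    res <- sim_actin_cpp(ic$u, ic$v, grid$dx, st$dt, st$nsteps, st$save_every,
                         unclass(params), 0, 0L, 0L, 0)
  } else {
    res <- sim_generic_r(network, grid, ic, st, sigma = 0, noise = NULL, seed = 0)
  }
  finish_field(res, st, grid, params)
}

check_ic <- function(ic, grid) {
  if (!is.list(ic) || is.null(ic$u) || is.null(ic$v) ||
      length(ic$u) != grid$n || length(ic$v) != grid$n) {
    stop("`ic` must be a list with numeric `u` and `v` of length grid$n",
         call. = FALSE)
  }
  if (!all(is.finite(ic$u)) || !all(is.finite(ic$v))) {
    stop("initial condition must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

# Generic (pure-R) Euler-Maruyama path for arbitrary reaction networks.
# Reaction-noise amplitude per species i is sqrt(sum_j S_ij^2 R_j), the
# diagonal of S diag(R) S^T.
sim_generic_r <- function(network, grid, ic, st, sigma, noise, seed) {
  n <- grid$n
  S <- network$stoich
  S2 <- S^2
  D <- network$diffusion
  dt <- st$dt; dx <- grid$dx
  nframes <- st$nsteps / st$save_every + 1
  U <- matrix(NA_real_, nframes, n); V <- matrix(NA_real_, nframes, n)
  X <- rbind(ic$u, ic$v)
  U[1, ] <- X[1, ]; V[1, ] <- X[2, ]
  stochastic <- !is.null(noise) && sigma > 0
  if (stochastic) set.seed(seed)
  clamped <- 0
  frame <- 2L
  bad_time <- -1
  for (s in seq_len(st$nsteps)) {
    R <- propensities(network, X)
    dX <- S %*% R
    for (i in seq_len(nrow(X))) {
      dX[i, ] <- dX[i, ] + D[i] * laplacian_periodic(X[i, ], dx)
    }
    inc <- dt * dX
    if (stochastic) {
      if (noise$mode == "additive_u") {
        inc[1, ] <- inc[1, ] + sigma * rnorm(n) * sqrt(dt / dx)
      } else {
        amp <- sqrt(pmax(S2 %*% R, 0))
        inc <- inc + sigma * amp * matrix(rnorm(2 * n), 2, n) * sqrt(dt / dx)
        if (noise$mode == "full") {
          for (i in seq_len(nrow(X))) {
            inc[i, ] <- inc[i, ] + sigma *
              diffusion_noise_increment(X[i, ], D[i], dx, dt)
          }
        }
      }
    }
    X <- X + inc
    if (stochastic && noise$mode != "additive_u") {
      neg <- X < 0
      clamped <- clamped + sum(neg)
      X[neg] <- 0
    }
    if (s %% st$save_every == 0) {
      if (!all(is.finite(X))) { bad_time <- s * dt; break }
      U[frame, ] <- X[1, ]; V[frame, ] <- X[2, ]
      frame <- frame + 1L
    }
  }
  list(u = U, v = V, nframes = frame - 1L,
       clamp_fraction = clamped / (2 * n * st$nsteps), bad_time = bad_time)
}
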