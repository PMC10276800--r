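#' Solve for a travelling- or standing-wave profile
#'
#' A localised wave is a fixed profile `(Phi_u, Phi_v)` moving at constant
#' speed `c` (zero for standing waves). In the co-moving coordinate
#' `xi = x - c t` the profile satisfies
#' \deqn{0 = D_u \Phi_u'' + c \Phi_u' - (a_1 + a_2 \Phi_v)\Phi_u
#'   + a_3 \Phi_u^2/(a_4+\Phi_u^2) + a_5, \quad
#'   0 = D_v \Phi_v'' + c \Phi_v' + \varepsilon(-c_1 \Phi_v + c_2 \Phi_u),}
#' discretised with the same periodic central differences as the PDE solver
#' (the wave is localised, so the tails meet smoothly). The problem is
#' translation invariant; an integral phase condition
#' `<d_xi(init_u), Phi_u - init_u> = 0` pins the translate. With `c` unknown
#' the augmented square system is solved by damped Newton with an analytic
#' sparse Jacobian; with `fix_c_zero` the speed is held at zero and the
#' pinning row is retained, giving an overdetermined system solved by
#' Gauss-Newton. Positive `c` means rightward motion.
#'
#' @param params An [actin_params()] object.
#' @param grid A [wave_grid()].
#' @param init List with `u`, `v` initial profile (a crude start clipped from
#'   a simulation works; see [clip_wave_pulse()]). Its tails must sit near the
#'   background state.
#' @param init_c Initial speed guess.
#' @param fix_c_zero If `TRUE`, solve for a standing wave (`c = 0`).
#' @param tol Convergence tolerance on the max-norm of the profile residual.
#' @param max_iter Maximum Newton iterations.
#' @param tail_tol Tolerance for the converged tails relative to the
#'   background state (the initial profile is allowed 5x this).
#' @return A `wave_profile` object: `xi`, `phi_u`, `phi_v`, `c`,
#'   `residual_norm`, `n_iter`, `converged`, `params`.
#' @export
solve_wave_profile <- function(params, grid, init, init_c = 0,
                               fix_c_zero = FALSE, tol = 1e-8, max_iter = 40,
                               tail_tol = 0.1) {
  stopifnot(inherits(params, "actin_params"), inherits(grid, "wave_grid"))
  check_ic(init, grid)
  n <- grid$n; dx <- grid$dx
  p <- params
  bg <- background_states(params)
  us <- bg$u_star[1]; vs <- bg$v_star[1]

  check_tails <- function(u, v, tol_, what) {
    far <- ((which.max(u) - 1 + n %/% 2) %% n) + 1  # cell opposite the peak
    if (abs(u[far] - us) > tol_ || abs(v[far] - vs) > tol_) {
      stop(what, " tails are not near the background state (u*, v*) = (",
           signif(us, 4), ", ", signif(vs, 4), ")", call. = FALSE)
    }
  }
  check_tails(init$u, init$v, 5 * tail_tol, "initial profile")

  # periodic first- and second-difference operators
  idx <- seq_len(n)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  L <- Matrix::sparseMatrix(
    i = c(idx, idx, idx), j = c(idx, ip, im),
    x = c(rep(-2, n), rep(1, n), rep(1, n)) / dx^2)
  Dx <- Matrix::sparseMatrix(
    i = c(idx, idx), j = c(ip, im),
    x = c(rep(1, n), rep(-1, n)) / (2 * dx))

  w <- as.vector(Dx %*% init$u)  # phase-condition weight

  kin_u <- function(u, v) -(p$a1 + p$a2 * v) * u + p$a3 * u^2 / (p$a4 + u^2) + p$a5
  kin_v <- function(u, v) p$eps * (-p$c1 * v + p$c2 * u)

  residual <- function(u, v, c) {
    c(as.vector(p$Du * (L %*% u) + c * (Dx %*% u)) + kin_u(u, v),
      as.vector(p$Dv * (L %*% v) + c * (Dx %*% v)) + kin_v(u, v))
  }
  phase <- function(u) sum(w * (u - init$u)) * dx

  u <- init$u; v <- init$v; c_val <- if (fix_c_zero) 0 else init_c
  res <- residual(u, v, c_val)
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    r_norm <- max(abs(res))
    if (r_norm <= tol && (fix_c_zero || abs(phase(u)) <= tol)) break
    n_iter <- it
    dfu <- -p$a1 - p$a2 * v + 2 * p$a3 * p$a4 * u / (p$a4 + u^2)^2
    dfv <- -p$a2 * u
    Auu <- p$Du * L + c_val * Dx + Matrix::Diagonal(n, dfu)
    Auv <- Matrix::Diagonal(n, dfv)
    Avu <- Matrix::Diagonal(n, rep(p$eps * p$c2, n))
    Avv <- p$Dv * L + c_val * Dx + Matrix::Diagonal(n, rep(-p$eps * p$c1, n))
    Jprof <- rbind(cbind(Auu, Auv), cbind(Avu, Avv))
    phase_row <- c(w * dx, rep(0, n))
    rhs <- c(res, phase(u))
    if (fix_c_zero) {
      # c = 0 held fixed and the phase condition dropped: the translation
      # mode is only approximately null on the lattice, so the square system
      # is solvable; the initial clip fixes which translate Newton lands on
      step <- as.vector(Matrix::solve(Jprof, -res))
      dc <- 0
    } else {
      c_col <- c(as.vector(Dx %*% u), as.vector(Dx %*% v))
      J <- rbind(cbind(Jprof, Matrix::Matrix(c_col, ncol = 1)),
                 Matrix::Matrix(c(phase_row, 0), nrow = 1))
      step <- as.vector(Matrix::solve(J, -rhs))
      dc <- step[2 * n + 1]
    }
    # damped update: backtrack while the residual grows
    lambda <- 1
    repeat {
      u_new <- u + lambda * step[1:n]
      v_new <- v + lambda * step[(n + 1):(2 * n)]
      c_new <- c_val + lambda * dc
      res_new <- residual(u_new, v_new, c_new)
      ok <- all(is.finite(res_new)) &&
        max(abs(res_new)) < max(abs(res)) * (1 - 1e-4 * lambda)
      if (ok || lambda < 1 / 64) break
      lambda <- lambda / 2
    }
    if (!all(is.finite(res_new))) {
      stop("wave solver diverged (non-finite residual)", call. = FALSE)
    }
    u <- u_new; v <- v_new; c_val <- c_new; res <- res_new
  }
  r_norm <- max(abs(res))
  converged <- r_norm <= tol
  if (!converged) {
    stop(sprintf("wave solver did not converge in %d iterations (residual %.3g)",
                 max_iter, r_norm), call. = FALSE)
  }
  check_tails(u, v, tail_tol, "converged profile")
  structure(
    list(xi = grid$x, phi_u = u, phi_v = v, c = c_val,
         residual_norm = r_norm, n_iter = n_iter, converged = converged,
         params = params, grid = grid,
         background = c(u_star = us, v_star = vs)),
    class = "wave_profile")
}

#' @export
print.wave_profile <- function(x, ...) {
  cat(sprintf("<wave_profile> c = %.6g, residual = %.3g, %d Newton iterations\n",
              x$c, x$residual_norm, x$n_iter))
  invisible(x)
}

#' @rdname solve_wave_profile
#' @param x A `wave_profile`.
#' @param ... Unused.
#' @export
tidy.wave_profile <- function(x, ...) {
  tibble(xi = x$xi, phi_u = x$phi_u, phi_v = x$phi_v)
}

#' @rdname solve_wave_profile
#' @export
glance.wave_profile <- function(x, ...) {
  tibble(c = x$c, residual_norm = x$residual_norm, n_iter = x$n_iter,
         converged = x$converged)
}

#' Clip a single pulse from a simulation snapshot
#'
#' Extracts the frame nearest `time`, locates the pulse maximum (optionally
#' within `x_range`), keeps a window of `half_width` on either side (with
#' periodic wrap), replaces everything outside with the background state, and
#' rotates the profile so the pulse sits at the domain centre. The result is
#' a crude but tail-correct starting point for [solve_wave_profile()].
#'
#' @param field A `kymograph`.
#' @param time Snapshot time (nearest saved frame is used).
#' @param x_range Optional interval restricting where the maximum is sought.
#' @param half_width Half-width of the retained window (model length units).
#' @return List with `u`, `v` of length `grid$n`.
#' @export
clip_wave_pulse <- function(field, time, x_range = NULL, half_width = 5) {
  stopifnot(inherits(field, "kymograph"))
  g <- field$grid
  i <- which.min(abs(field$times - time))
  u <- field$u[i, ]; v <- field$v[i, ]
  bg <- background_states(field$params)
  us <- bg$u_star[1]; vs <- bg$v_star[1]
  cand <- seq_len(g$n)
  if (!is.null(x_range)) cand <- which(g$x >= x_range[1] & g$x <= x_range[2])
  j0 <- cand[which.max(u[cand])]
  circ_dist <- abs(g$x - g$x[j0])
  circ_dist <- pmin(circ_dist, g$length - circ_dist)
  outside <- circ_dist > half_width
  u[outside] <- us; v[outside] <- vs
  shift <- (g$n %/% 2 + 1) - j0  # rotate pulse to centre cell
  rot <- function(z, s) z[((seq_along(z) - 1 - s) %% length(z)) + 1]
  list(u = rot(u, shift), v = rot(v, shift))
}

#' Measure propagation speed from a kymograph
#'
#' Tracks the location of the activator maximum frame by frame inside a time
#' window, unwraps it on the periodic domain, and returns the least-squares
#' slope of position versus time. Requires a single coherent moving maximum
#' in the window; restrict `x_range` when two pulses coexist.
#'
#' @param field A `kymograph`.
#' @param window Length-2 time interval to fit over.
#' @param x_range Optional interval restricting the tracked maximum.
#' @param min_height Minimum pulse elevation above the background state; a
#'   window with no maximum this high is a measurement error.
#' @return Speed (space/time, model units); negative means leftward motion.
#' @export
measure_speed <- function(field, window, x_range = NULL, min_height = 0.5) {
  stopifnot(inherits(field, "kymograph"), length(window) == 2)
  sel <- which(field$times >= window[1] & field$times <= window[2])
  if (length(sel) < 3) stop("window contains fewer than 3 frames", call. = FALSE)
  g <- field$grid
  cols <- seq_len(g$n)
  if (!is.null(x_range)) cols <- which(g$x >= x_range[1] & g$x <= x_range[2])
  bg <- background_states(field$params)
  us <- bg$u_star[1]
  pos <- vapply(sel, function(i) {
    row <- field$u[i, cols]
    if (max(row) < us + min_height) return(NA_real_)
    g$x[cols[which.max(row)]]
  }, numeric(1))
  if (anyNA(pos)) {
    stop("no maximum above threshold throughout the window", call. = FALSE)
  }
  d <- diff(pos)
  d[d > g$length / 2] <- d[d > g$length / 2] - g$length
  d[d < -g$length / 2] <- d[d < -g$length / 2] + g$length
  unwrapped <- pos[1] + cumsum(c(0, d))
  unname(coef(lm(unwrapped ~ field$times[sel]))[2])
}

#' Measure the width of a super-threshold pulse
#'
#' The spatial extent (in model length units) of the widest contiguous region
#' where the activator exceeds the detection threshold, with periodic wrap.
#' Shares its threshold rule with the event detector (see
#' [default_event_threshold()]).
#'
#' @param u Numeric snapshot (one value per cell) or a `wave_profile`
#'   (its `phi_u` is used).
#' @param dx Cell width (taken from the profile if omitted).
#' @param threshold Detection threshold on `u`.
#' @return Width in model length units.
#' @export
measure_width <- function(u, threshold, dx = NULL) {
  if (inherits(u, "wave_profile")) {
    if (is.null(dx)) dx <- u$grid$dx
    u <- u$phi_u
  }
  stopifnot(!is.null(dx))
  mask <- u > threshold
  if (!any(mask)) stop("nothing above threshold", call. = FALSE)
  n <- length(mask)
  r <- rle(mask)
  widths <- r$lengths[r$values]
  # merge a run that wraps across the periodic boundary
  if (length(widths) > 1 && mask[1] && mask[n]) {
    widths[1] <- widths[1] + widths[length(widths)]
    widths <- widths[-length(widths)]
  }
  max(widths) * dx
}
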