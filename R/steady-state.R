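#' Spatially homogeneous background states
#'
#' The homogeneous equilibria of the kinetics are the intersections of the
#' u- and v-nullclines. Substituting `v* = c2 u*/c1` into the u-nullcline
#' gives a quartic in `u`:
#' \deqn{-(a_2 c_2/c_1) u^4 - a_1 u^3 + (a_3 + a_5 - a_2 a_4 c_2/c_1) u^2
#'       - a_1 a_4 u + a_5 a_4 = 0,}
#' whose positive real roots are the admissible states. Roots are found as
#' eigenvalues of the companion matrix; a root counts as real when
#' `|Im| < 1e-9 * max(1, |Re|)` and positive when `Re > 1e-12`. Each state is
#' paired with the eigenvalues of the kinetics Jacobian.
#'
#' @param params An [actin_params()] object.
#' @return A tibble with one row per admissible state, sorted by `u_star`:
#'   columns `u_star`, `v_star`, `lambda1`, `lambda2` (complex Jacobian
#'   eigenvalues, `lambda1` has the larger real part), `is_complex`, `stable`.
#' @examples
#' background_states(actin_preset("fig4_standing"))  # u* ~ 0.0523
#' @export
background_states <- function(params) {
  stopifnot(inherits(params, "actin_params"))
  u <- positive_quartic_roots(params)
  rows <- lapply(u, function(us) {
    vs <- params$c2 * us / params$c1
    ev <- eigen(jacobian_matrix(params, c(us, vs)), only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    tibble(
      u_star = us, v_star = vs,
      lambda1 = as.complex(ev[1]), lambda2 = as.complex(ev[2]),
      is_complex = abs(Im(ev[1])) > 0,
      stable = max(Re(ev)) < 0
    )
  })
  dplyr::bind_rows(rows)
}

# coefficients of the background-state quartic, descending powers
quartic_coefficients <- function(params) {
  p <- params
  c(-p$a2 * p$c2 / p$c1,
    -p$a1,
    p$a3 + p$a5 - p$a2 * p$a4 * p$c2 / p$c1,
    -p$a1 * p$a4,
    p$a5 * p$a4)
}

positive_quartic_roots <- function(params) {
  co <- quartic_coefficients(params)
  # companion matrix of the monic quartic
  monic <- co[-1] / co[1]
  n <- length(monic)
  comp <- rbind(-monic, cbind(diag(n - 1), 0))
  r <- eigen(comp, only.values = TRUE)$values
  keep <- abs(Im(r)) < 1e-9 * pmax(1, abs(Re(r))) & Re(r) > 1e-12
  sort(Re(r[keep]))
}

#' Descartes root-count bound for the background-state quartic
#'
#' By Descartes' rule of signs the quartic has exactly one positive real root
#' when `c1 (a3 + a5) < a2 a4 c2` (strict), and one or three otherwise. The
#' boundary case (equality) conservatively reports `"one_or_three"`.
#'
#' @inheritParams background_states
#' @return `"one"` or `"one_or_three"`.
#' @export
descartes_root_bound <- function(params) {
  stopifnot(inherits(params, "actin_params"))
  p <- params
  if (p$c1 * (p$a3 + p$a5) < p$a2 * p$a4 * p$c2) "one" else "one_or_three"
}

#' Kinetics Jacobian at a background state
#'
#' The 2 x 2 Jacobian of the reaction kinetics evaluated at `(u*, v*)`:
#' \deqn{J = \begin{pmatrix} -a_1 - a_2 v^* + 2 a_3 a_4 u^*/(a_4+u^{*2})^2 &
#' -a_2 u^* \\ \varepsilon c_2 & -\varepsilon c_1 \end{pmatrix}.}
#'
#' @inheritParams background_states
#' @param state Numeric `(u*, v*)`.
#' @return A 2 x 2 numeric matrix.
#' @export
jacobian_matrix <- function(params, state) {
  p <- params
  u <- state[1]; v <- state[2]
  matrix(c(-p$a1 - p$a2 * v + 2 * p$a3 * p$a4 * u / (p$a4 + u^2)^2, -p$a2 * u,
           p$eps * p$c2, -p$eps * p$c1),
         nrow = 2, byrow = TRUE)
}

# background state continued along a c1 scan: the positive root nearest the
# previous one (unique-root regimes are unaffected)
continued_state <- function(params, c1, u_prev = NULL) {
  params$c1 <- c1
  u <- positive_quartic_roots(params)
  if (length(u) == 0L) stop("no positive background state at c1 = ", c1, call. = FALSE)
  us <- if (is.null(u_prev)) u[1] else u[which.min(abs(u - u_prev))]
  c(us, params$c2 * us / params$c1)
}

#' Locate the complex-eigenvalue onset and the Hopf bifurcation in c1
#'
#' Scans the inhibitor decay rate `c1` over a range, following the background
#' state by nearest-neighbour continuation, and locates two transitions by
#' bisection: the value where the Jacobian discriminant
#' `tr(J)^2 - 4 det(J)` changes sign (eigenvalues become complex) and the
#' value where the maximal real part of the eigenvalues crosses zero (Hopf
#' bifurcation, onset of time-periodic dynamics).
#'
#' @inheritParams background_states
#' @param c1_range Length-2 interval to scan; must bracket both transitions.
#' @param tol Bisection tolerance in `c1`.
#' @param n_scan Number of coarse scan points used to bracket sign changes.
#' @return A list with `c1_complex_onset` and `c1_hopf`.
#' @examples
#' \donttest{
#' eigen_scan(actin_params(c1 = 0.2))  # onset ~0.25, Hopf ~0.29
#' }
#' @export
eigen_scan <- function(params, c1_range = c(0.18, 0.35), tol = 1e-6,
                       n_scan = 120) {
  stopifnot(inherits(params, "actin_params"), length(c1_range) == 2)
  grid <- seq(c1_range[1], c1_range[2], length.out = n_scan)

  disc_fun <- function(c1, u_prev) {
    st <- continued_state(params, c1, u_prev)
    J <- jacobian_matrix(params, st)
    tr <- J[1, 1] + J[2, 2]
    dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    list(disc = tr^2 - 4 * dt, maxre = max(Re(eigen(J, only.values = TRUE)$values)),
         u = st[1])
  }

  vals <- vector("list", n_scan)
  u_prev <- NULL
  for (i in seq_len(n_scan)) {
    vals[[i]] <- disc_fun(grid[i], u_prev)
    u_prev <- vals[[i]]$u
  }
  disc <- vapply(vals, `[[`, numeric(1), "disc")
  maxre <- vapply(vals, `[[`, numeric(1), "maxre")
  us <- vapply(vals, `[[`, numeric(1), "u")

  bisect <- function(f, lo, hi, u_lo, what) {
    f_lo <- f(lo, u_lo)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      f_mid <- f(mid, u_lo)
      if (sign(f_mid) == sign(f_lo)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  first_change <- function(y, what) {
    idx <- which(sign(y[-1]) != sign(y[-length(y)]))
    if (length(idx) == 0L) {
      stop("c1_range does not bracket the ", what, " transition", call. = FALSE)
    }
    idx[1]
  }

  i_disc <- first_change(disc, "complex-eigenvalue onset")
  i_hopf <- first_change(maxre, "Hopf (real-part zero crossing)")

  onset <- bisect(function(c1, u0) disc_fun(c1, u0)$disc,
                  grid[i_disc], grid[i_disc + 1], us[i_disc], "onset")
  hopf <- bisect(function(c1, u0) disc_fun(c1, u0)$maxre,
                 grid[i_hopf], grid[i_hopf + 1], us[i_hopf], "hopf")
  list(c1_complex_onset = onset, c1_hopf = hopf)
}

#' Tabulate background state and eigenvalues along a c1 scan
#'
#' The numeric twin of an eigenvalue-locus plot: for each `c1` the continued
#' background state and the complex Jacobian eigenvalues.
#'
#' @inheritParams background_states
#' @param c1_values Numeric vector of `c1` values (scanned in order).
#' @return A tibble with columns `c1`, `u_star`, `v_star`, `re_lambda1`,
#'   `im_lambda1`, `re_lambda2`, `im_lambda2`.
#' @export
scan_eigenvalues <- function(params, c1_values = seq(0.18, 0.35, by = 0.005)) {
  stopifnot(inherits(params, "actin_params"))
  u_prev <- NULL
  rows <- lapply(c1_values, function(c1) {
    st <- continued_state(params, c1, u_prev)
    u_prev <<- st[1]
    ev <- eigen(jacobian_matrix(params, st), only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    tibble(c1 = c1, u_star = st[1], v_star = st[2],
           re_lambda1 = Re(ev[1]), im_lambda1 = Im(ev[1]),
           re_lambda2 = Re(ev[2]), im_lambda2 = Im(ev[2]))
  })
  dplyr::bind_rows(rows)
}
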