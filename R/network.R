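#' Construct a reaction network
#'
#' A `reaction_network` is the generic object every solver in the package
#' consumes: an ordered set of species, an M x N stoichiometric matrix, a
#' propensity evaluator, and per-species diffusion coefficients. Propensities
#' are evaluated exactly as written, even for (unphysical) negative states;
#' keeping states admissible is the solvers' responsibility, not the model's.
#'
#' @param species Character vector of species names (length M).
#' @param stoich Integer M x N stoichiometric matrix: column j is the change
#'   in each species when reaction j fires.
#' @param propensity Function `(state, params) -> propensities`. `state` is a
#'   species vector (length M) or an M x K matrix of K spatial cells;
#'   the return value is a length-N vector or N x K matrix of reaction rates.
#' @param diffusion Numeric vector of per-species diffusion coefficients.
#' @param params Parameter object stored with the network and passed to
#'   `propensity`.
#' @param kinetics Optional tag naming a compiled fast path (`"actin"` for the
#'   built-in model); `NULL` for networks integrated via the generic R path.
#' @return A `reaction_network` object.
#' @seealso [actin_network()]
#' @export
reaction_network <- function(species, stoich, propensity, diffusion,
                             params = NULL, kinetics = NULL) {
  stoich <- as.matrix(stoich)
  if (nrow(stoich) != length(species)) {
    stop("`stoich` must have one row per species", call. = FALSE)
  }
  if (length(diffusion) != length(species) || any(diffusion < 0)) {
    stop("`diffusion` must be a non-negative vector with one entry per species",
         call. = FALSE)
  }
  stopifnot(is.function(propensity))
  structure(
    list(species = species, stoich = stoich, propensity = propensity,
         diffusion = diffusion, params = params, kinetics = kinetics),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species (%s), %d reactions\n",
              length(x$species), paste(x$species, collapse = ", "),
              ncol(x$stoich)))
  invisible(x)
}

actin_propensity <- function(state, params) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 2)
  stopifnot(nrow(state) == 2)
  u <- state[1, ]
  v <- state[2, ]
  p <- params
  out <- rbind(
    p$a1 * u,
    p$a2 * u * v,
    p$a3 * u^2 / (p$a4 + u^2),
    rep(p$a5, length(u)),
    p$eps * p$c1 * v,
    p$eps * p$c2 * u
  )
  if (ncol(out) == 1L) drop(out) else out
}

#' The built-in actin-wave reaction network
#'
#' Builds the six-reaction activator-inhibitor network driving cortical actin
#' waves: activator degradation (`a1 u`), inhibitor-mediated degradation
#' (`a2 u v`), autocatalytic Hill activation (`a3 u^2/(a4+u^2)`), basal
#' activation (`a5`), inhibitor decay (`eps c1 v`), and activator-driven
#' inhibitor production (`eps c2 u`), with stoichiometry
#' `u: (-1,-1,1,1,0,0)`, `v: (0,0,0,0,-1,1)`.
#'
#' @param params An [actin_params()] object.
#' @return A [reaction_network()] with species `c("u","v")` and a compiled
#'   fast path for the simulators.
#' @examples
#' net <- actin_network(actin_preset("fig4_standing"))
#' propensities(net, c(0, 0))  # only basal production is active
#' @export
actin_network <- function(params) {
  stopifnot(inherits(params, "actin_params"))
  S <- matrix(c(-1, -1, 1, 1, 0, 0,
                 0,  0, 0, 0, -1, 1),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("u", "v"), NULL))
  reaction_network(
    species = c("u", "v"),
    stoich = S,
    propensity = actin_propensity,
    diffusion = c(u = params$Du, v = params$Dv),
    params = params,
    kinetics = "actin"
  )
}

#' Evaluate reaction propensities
#'
#' @param network A [reaction_network()].
#' @param state Species vector (length M) or M x K matrix over K cells.
#' @return Length-N vector or N x K matrix of reaction rates.
#' @export
propensities <- function(network, state) {
  stopifnot(inherits(network, "reaction_network"))
  network$propensity(state, network$params)
}

#' Reaction drift S R(X)
#'
#' The deterministic reaction term of the rate equation: the stoichiometric
#' matrix applied to the propensity vector. For the actin network this equals
#' the kinetic right-hand side of the macroscopic reaction-diffusion equation.
#'
#' @inheritParams propensities
#' @return Species vector (or M x K matrix) of net rates of change.
#' @export
drift <- function(network, state) {
  r <- propensities(network, state)
  if (is.null(dim(r))) r <- matrix(r, ncol = 1)
  out <- network$stoich %*% r
  if (is.matrix(state)) out else drop(out)
}
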