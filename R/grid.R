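#' Periodic 1-D spatial grid
#'
#' The membrane slice is an (approximate) circle: the domain
#' `[x_min, x_max)` is discretised into `n` cells of width
#' `dx = (x_max - x_min)/n` with nodes `x_k = x_min + k dx`, `k = 0..n-1`,
#' and periodic wraparound. The default `[-10, 10)` with `n = 400`
#' (`dx = 0.05`) resolves the deterministic pulse (width about 0.87) with
#' roughly 17 points.
#'
#' @param x_min,x_max Domain ends (model length units).
#' @param n Number of cells (at least 8).
#' @return A `wave_grid` object with fields `x` (nodes), `dx`, `n`,
#'   `x_min`, `x_max`, `length`.
#' @examples
#' g <- wave_grid()
#' g$dx
#' @export
wave_grid <- function(x_min = -10, x_max = 10, n = 400) {
  stopifnot(x_max > x_min, n >= 8)
  dx <- (x_max - x_min) / n
  structure(
    list(x = x_min + (seq_len(n) - 1) * dx, dx = dx, n = as.integer(n),
         x_min = x_min, x_max = x_max, length = x_max - x_min),
    class = "wave_grid"
  )
}

#' @export
print.wave_grid <- function(x, ...) {
  cat(sprintf("<wave_grid> [%g, %g) periodic, n = %d, dx = %g\n",
              x$x_min, x$x_max, x$n, x$dx))
  invisible(x)
}

new_kymograph <- function(u, v, times, grid, params, noise = NULL,
                          seed = NULL, clamp_fraction = 0) {
  structure(
    list(u = u, v = v, times = times, grid = grid, params = params,
         noise = noise, seed = seed, clamp_fraction = clamp_fraction),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  mode <- if (is.null(x$noise)) "deterministic" else x$noise$mode
  cat(sprintf("<kymograph> %d times x %d cells, t in [0, %g], %s\n",
              nrow(x$u), ncol(x$u), max(x$times), mode))
  if (!is.null(x$noise)) {
    cat(sprintf("  sigma = %g, seed = %s, clamped cell fraction = %.2g\n",
                x$noise$sigma, format(x$seed), x$clamp_fraction))
  }
  invisible(x)
}

#' Tidy a kymograph into a long tibble
#'
#' @param x A `kymograph`.
#' @param ... Unused.
#' @return A tibble with columns `t`, `x`, `u`, `v` (one row per space-time
#'   sample).
#' @export
as_tibble.kymograph <- function(x, ...) {
  nt <- nrow(x$u); nx <- ncol(x$u)
  u <- as.vector(x$u)
  v <- as.vector(x$v)
  tibble(
    t = rep(x$times, times = nx),
    x = rep(x$grid$x, each = nt),
    u = u,
    v = v
  )
}

#' Sampling interval of a saved kymograph
#' @param field A `kymograph`.
#' @return Time between consecutive saved frames.
#' @export
sampling_dt <- function(field) {
  stopifnot(inherits(field, "kymograph"))
  if (length(field$times) < 2) stop("field has fewer than 2 frames", call. = FALSE)
  diff(field$times[1:2])
}
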