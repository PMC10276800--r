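#' Parameters of the actin-wave activator-inhibitor model
#'
#' Bundles the rate constants of the six-reaction activator (`u`) / inhibitor
#' (`v`) network, the diffusion coefficients, and the noise strength into a
#' validated parameter object. All quantities are in nondimensional model
#' units. The noise strength `sigma` and the system size `omega` (molecules
#' per unit concentration per unit length) are tied by `sigma = 1/sqrt(omega)`:
#' either may be supplied and the other is filled in.
#'
#' @param a1,a2,a3,a4,a5 Activator reaction rates: linear degradation (`a1 u`),
#'   inhibitor-mediated degradation (`a2 u v`), autocatalytic Hill activation
#'   (`a3 u^2/(a4 + u^2)`), and basal production (`a5`).
#' @param c1,c2 Inhibitor rates: decay (`eps c1 v`) and production driven by
#'   the activator (`eps c2 u`).
#' @param eps Timescale separation between activator and inhibitor kinetics.
#' @param Du,Dv Diffusion coefficients (space^2/time); the model assumes
#'   `Du < Dv`.
#' @param sigma Noise strength `sigma = 1/sqrt(omega)`; `0` gives the
#'   deterministic limit.
#' @param omega System size; only consumed by the microscopic simulators.
#' @return An object of class `actin_params` (a named list).
#' @examples
#' p <- actin_params(c1 = 0.1)
#' p$c1
#' @export
actin_params <- function(a1 = 0.167, a2 = 16.67, a3 = 167, a4 = 1.44,
                         a5 = 1.47, c1 = 0.1, c2 = 3.9, eps = 0.52,
                         Du = 0.1, Dv = 1, sigma = 0, omega = NULL) {
  rates <- c(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5,
             c1 = c1, c2 = c2, eps = eps, Du = Du, Dv = Dv)
  if (!all(is.finite(rates)) || any(rates <= 0)) {
    stop("all rate constants, eps, Du and Dv must be finite and strictly positive",
         call. = FALSE)
  }
  if (!is.finite(sigma) || sigma < 0) {
    stop("`sigma` must be >= 0", call. = FALSE)
  }
  if (is.null(omega)) {
    omega <- if (sigma > 0) 1 / sigma^2 else Inf
  } else {
    if (!is.finite(omega) || omega <= 0) stop("`omega` must be > 0", call. = FALSE)
    sig_from_omega <- 1 / sqrt(omega)
    if (sigma == 0) {
      sigma <- sig_from_omega
    } else if (abs(sigma - sig_from_omega) > 1e-8 * max(sigma, sig_from_omega)) {
      stop("`sigma` and `omega` are inconsistent: sigma must equal 1/sqrt(omega)",
           call. = FALSE)
    }
  }
  structure(
    list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5,
         c1 = c1, c2 = c2, eps = eps, Du = Du, Dv = Dv,
         sigma = sigma, omega = omega),
    class = "actin_params"
  )
}

#' @export
print.actin_params <- function(x, ...) {
  cat("<actin_params>\n")
  cat(sprintf("  kinetics: a1=%g a2=%g a3=%g a4=%g a5=%g\n",
              x$a1, x$a2, x$a3, x$a4, x$a5))
  cat(sprintf("  inhibitor: c1=%g c2=%g eps=%g\n", x$c1, x$c2, x$eps))
  cat(sprintf("  diffusion: Du=%g Dv=%g\n", x$Du, x$Dv))
  cat(sprintf("  noise: sigma=%g (omega=%g)\n", x$sigma, x$omega))
  invisible(x)
}

preset_table <- list(
  fig4_standing    = list(c1 = 0.1),
  fig11_travelling = list(c1 = 0.2),
  fig14_oscillatory = list(c1 = 0.4),
  fig17a = list(c1 = 0.1, eps = 0.4, a3 = 167,   c2 = 2.1),
  fig17b = list(c1 = 0.1, eps = 0.4, a3 = 300.6, c2 = 3)
)

#' Named parameter presets
#'
#' Versioned parameter sets used throughout the package: `"fig4_standing"`
#' (standing-wave regime, c1 = 0.1), `"fig11_travelling"` (travelling-wave
#' regime, c1 = 0.2), `"fig14_oscillatory"` (time-periodic regime, c1 = 0.4),
#' and the wild-type / PTEN-null pair `"fig17a"` (eps = 0.4, a3 = 167,
#' c2 = 2.1) and `"fig17b"` (eps = 0.4, a3 = 300.6, c2 = 3). All share
#' Du = 0.1, Dv = 1, a1 = 0.167, a2 = 16.67, a4 = 1.44, a5 = 1.47, and (except
#' the fig17 pair) eps = 0.52, c2 = 3.9.
#'
#' @param name Preset name, one of `actin_preset_names()`.
#' @param sigma,omega Optional noise strength / system size overrides,
#'   see [actin_params()].
#' @return An `actin_params` object.
#' @examples
#' actin_preset("fig11_travelling")$c1
#' @export
actin_preset <- function(name, sigma = 0, omega = NULL) {
  if (!name %in% names(preset_table)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(preset_table), collapse = ", "), call. = FALSE)
  }
  args <- c(preset_table[[name]], list(sigma = sigma, omega = omega))
  p <- do.call(actin_params, args)
  attr(p, "preset") <- name
  p
}

#' @rdname actin_preset
#' @export
actin_preset_names <- function() names(preset_table)

#' Read or write a parameter set as JSON
#'
#' Presets and ad-hoc parameter sets round-trip through a plain JSON config
#' file whose keys match the fields of [actin_params()].
#'
#' @param params An `actin_params` object.
#' @param path File path.
#' @return `read_params()` returns an `actin_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "actin_params"))
  x <- unclass(params)
  if (!is.finite(x$omega)) x$omega <- NULL
  x$preset <- attr(params, "preset")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  preset <- x$preset
  x$preset <- NULL
  p <- do.call(actin_params, x)
  if (!is.null(preset)) attr(p, "preset") <- preset
  p
}
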