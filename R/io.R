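fmt_matrix_csv <- function(m, path) {
  lines <- apply(m, 1, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = ","))
  writeLines(lines, path)
}

read_matrix_csv <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE, colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Save or load a kymograph as plain-text files
#'
#' Writes `<prefix>_u.csv` and `<prefix>_v.csv` (frames x cells matrices at
#' full double precision, so the round trip is exact) plus `<prefix>.json`
#' carrying the grid, sample times, parameters, noise configuration, seed
#' and clamping diagnostics.
#'
#' @param field A `kymograph`.
#' @param prefix Path prefix for the three files.
#' @return `write_kymograph()` returns `prefix` invisibly;
#'   `read_kymograph()` returns the reconstructed `kymograph`.
#' @export
write_kymograph <- function(field, prefix) {
  stopifnot(inherits(field, "kymograph"))
  fmt_matrix_csv(field$u, paste0(prefix, "_u.csv"))
  fmt_matrix_csv(field$v, paste0(prefix, "_v.csv"))
  meta <- list(
    grid = list(x_min = field$grid$x_min, x_max = field$grid$x_max,
                n = field$grid$n),
    times = field$times,
    params = unclass(field$params),
    preset = attr(field$params, "preset"),
    noise = if (!is.null(field$noise)) unclass(field$noise),
    seed = field$seed,
    clamp_fraction = field$clamp_fraction)
  if (!is.finite(meta$params$omega)) meta$params$omega <- NULL
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  g <- wave_grid(meta$grid$x_min, meta$grid$x_max, meta$grid$n)
  pl <- meta$params
  pl$preset <- NULL
  params <- do.call(actin_params, pl)
  if (!is.null(meta$preset)) attr(params, "preset") <- meta$preset
  noise <- NULL
  if (!is.null(meta$noise) && length(meta$noise) > 0) {
    noise <- noise_config(mode = meta$noise$mode,
                          variance_convention = meta$noise$variance_convention,
                          sigma = meta$noise$sigma, seed = meta$noise$seed)
  }
  new_kymograph(read_matrix_csv(paste0(prefix, "_u.csv")),
                read_matrix_csv(paste0(prefix, "_v.csv")),
                meta$times, g, params, noise = noise, seed = meta$seed,
                clamp_fraction = meta$clamp_fraction)
}

#' Save a wave profile as CSV plus a JSON sidecar
#'
#' Writes `<prefix>.csv` with columns `xi`, `phi_u`, `phi_v` and
#' `<prefix>.json` with the speed, residual and parameters.
#'
#' @param profile A `wave_profile`.
#' @param prefix Path prefix.
#' @return `prefix`, invisibly.
#' @export
write_wave_profile <- function(profile, prefix) {
  stopifnot(inherits(profile, "wave_profile"))
  utils::write.csv(tidy(profile), paste0(prefix, ".csv"), row.names = FALSE)
  meta <- list(c = profile$c, residual_norm = profile$residual_norm,
               n_iter = profile$n_iter, params = unclass(profile$params))
  if (!is.finite(meta$params$omega)) meta$params$omega <- NULL
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
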