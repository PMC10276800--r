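# Small shared fixtures. Heavy figure-scale runs live in test-acceptance.R.

fig4 <- actin_preset("fig4_standing")
fig11 <- actin_preset("fig11_travelling")
fig14 <- actin_preset("fig14_oscillatory")

small_grid <- wave_grid(-4, 4, 64)

# hand-coded kinetics right-hand side, independent transcription of the
# reaction terms of the macroscopic rate equation
kinetics_rhs <- function(u, v, p) {
  c(-p$a1 * u - p$a2 * u * v + p$a3 * u^2 / (p$a4 + u^2) + p$a5,
    p$eps * (-p$c1 * v + p$c2 * u))
}

# brute-force connected-component oracle: start from per-pixel labels and
# iterate neighbour-minimum relabelling to a fixed point (8-connectivity,
# periodic in columns). O(N^2)-ish, for small masks only.
floodfill_oracle <- function(mask) {
  nt <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, nt, nx)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (i in seq_len(nt)) {
      for (j in seq_len(nx)) {
        if (!mask[i, j]) next
        for (di in -1:1) {
          for (dj in -1:1) {
            ii <- i + di
            jj <- ((j + dj - 1) %% nx) + 1
            if (ii < 1 || ii > nt) next
            if (mask[ii, jj] && lab[ii, jj] < lab[i, j]) {
              lab[i, j] <- lab[ii, jj]
              changed <- TRUE
            }
          }
        }
      }
    }
    if (!changed) break
  }
  lab
}

# canonical form of a labelling: list of sorted cell-index sets
component_sets <- function(lab) {
  on <- which(lab > 0)
  unname(lapply(split(on, lab[on]), sort))
}

make_field <- function(u, v = u, times, grid, params = fig4) {
  actinwaves:::new_kymograph(u, v, times, grid, params)
}

# periodic spline interpolation of a wave profile onto a finer grid
refine_profile <- function(prof, g_from, g_to) {
  per <- function(z) splinefun(c(g_from$x, g_from$x_max), c(z, z[1]),
                               method = "periodic")(g_to$x)
  list(u = per(prof$phi_u), v = per(prof$phi_v))
}
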