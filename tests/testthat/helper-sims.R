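# Shared simulation fixtures, memoised so that several test files can reuse
# the same runs. The three 15,000-mcs runs double as the desk-scale study
# condition: 125 x 100 field, 50 seeders, stationary cells scaled by area.

.gc_cache <- new.env(parent = emptyenv())

scaled_config <- function() {
  scale_config(gc_config(), grid_x = 125, grid_y = 100, n_seeder = 50)
}

scaled_sims <- function() {
  if (is.null(.gc_cache$sims)) {
    cfg <- scaled_config()
    .gc_cache$sims <- lapply(1:3, function(s)
      simulate_gc(cfg, seed = s, t_end = 15000))
  }
  .gc_cache$sims
}

# a quick small-field run for structural checks
small_config <- function() {
  scale_config(gc_config(), grid_x = 70, grid_y = 56, n_seeder = 10)
}

small_sim <- function() {
  if (is.null(.gc_cache$small)) {
    .gc_cache$small <- simulate_gc(small_config(), seed = 7, t_end = 3000)
  }
  .gc_cache$small
}

# mature snapshot time with the largest light-zone population: restricted to
# the second half of the run so both zones are populated
best_lz_time <- function(sim) {
  sn <- sim$snapshots
  sn <- sn[sn$t >= max(sn$t) / 2, ]
  cnt <- stats::aggregate(zone ~ t, sn, sum)
  cnt$t[which.max(cnt$zone)]
}

# dense steady-state solver for the secretion-diffusion-decay equation on a
# small grid with zero-flux boundaries: (k I - D L) c = s
dense_field_solve <- function(nx, ny, src, D, k) {
  n <- nx * ny
  idx <- function(x, y) (y - 1) * nx + x
  A <- matrix(0, n, n)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    i <- idx(x, y)
    nb <- list(c(x - 1, y), c(x + 1, y), c(x, y - 1), c(x, y + 1))
    for (p in nb) {
      if (p[1] >= 1 && p[1] <= nx && p[2] >= 1 && p[2] <= ny) {
        A[i, idx(p[1], p[2])] <- A[i, idx(p[1], p[2])] + D
        A[i, i] <- A[i, i] - D
      }
    }
    A[i, i] <- A[i, i] - k
  }
  c_vec <- solve(-A, as.vector(src))
  matrix(c_vec, nx, ny)
}
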