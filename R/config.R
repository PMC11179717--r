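#' Simulation configuration
#'
#' Builds the configuration object governing one germinal-center run: lattice
#' geometry, stationary-cell and seeder counts, Monte Carlo clock, fate-rule
#' thresholds, Cellular Potts constants, chemokine-field constants, and the
#' kinetic rates of the intracellular network.
#'
#' Defaults reproduce the reference tissue: a 250 x 200 pixel field split at
#' the midline into dark zone (DZ, left) and light zone (LZ, right), with 45
#' CXCL12-expressing reticular cells (CRCs) in the DZ, 45 follicular dendritic
#' cells (FDCs) plus 36 T follicular helper (Tfh) cells in the LZ, and 200
#' seeder B cells of intermediate affinity 5 started between the two zones.
#' One Monte Carlo step (mcs) corresponds to roughly 1/100 hour.
#'
#' @param ... named overrides of any default field, e.g. `grid_x = 125`.
#'   Kinetic rates are overridden through the `rates` field (a named numeric
#'   vector, see [default_rates()]).
#' @return An object of class `gc_config` (a named list).
#' @examples
#' cfg <- gc_config(grid_x = 60, grid_y = 40, n_crc = 2, n_fdc = 2,
#'                  n_tfh = 1, n_seeder = 4)
#' validate_config(cfg)
#' @export
gc_config <- function(...) {
  cfg <- list(
    # --- geometry and counts ---
    grid_x = 250L, grid_y = 200L, grid_z = 1L,
    n_crc = 45L, n_fdc = 45L, n_tfh = 36L, n_seeder = 200L,
    seeder_affinity_mode = "constant-5",
    midline_x = NULL,                 # filled below as grid_x / 2
    stromal_footprint = 5L,           # stationary cells occupy 5 x 5 pixels
    seeder_band = 20L,                # seeder band half-width around midline
    fdc_min_offset = 25L,             # FDC centers start this far into the LZ
    # --- clock ---
    t_end = 72000L, log_every = 15L, bin_width = 600L,
    mcs_per_hour = 100L, rng_seed = 1L,
    # --- fate rules ---
    lethal_mut_prob = 0.3,
    affinity_pc_threshold = 10,
    ap4_threshold = 50,
    timer_initial = 100, timer_threshold = 50, timer_span = 1800,
    growth_delay_first_cycle = 800,
    volume_doubling_time = 500,
    cxcr4_lag = 100,
    pmhc_halflife = 100,
    tfh_signal_max = 150,
    apop_delay = 30,
    blimp_on = 50,
    split_sigma = 0.2,
    # --- Cellular Potts constants ---
    temperature = 10, lambda_vol = 3,
    j_bb = 16, j_bm = 8, j_bs = 16,
    lambda_cxcl12 = 4800, lambda_cxcl13 = 1200,
    target_volume = 30L, cytokinesis_fraction = 0.9,
    # --- chemokine fields ---
    chem_D = 1, chem_decay = 5e-4, chem_secretion = 0.02,
    chem_dt = 0.2, chem_tol = 1e-5, chem_sat = 0.25,
    freeze_fields = TRUE,
    # --- intracellular network ---
    rates = default_rates()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg)))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (is.null(cfg$midline_x)) cfg$midline_x <- cfg$grid_x / 2
  ints <- c("grid_x", "grid_y", "grid_z", "n_crc", "n_fdc", "n_tfh",
            "n_seeder", "t_end", "log_every", "bin_width", "mcs_per_hour",
            "stromal_footprint", "seeder_band", "fdc_min_offset",
            "target_volume")
  for (f in ints) cfg[[f]] <- as.integer(cfg[[f]])
  class(cfg) <- "gc_config"
  cfg
}

#' Default kinetic rates of the intracellular network
#'
#' Rates are per mcs. Decay constants correspond to half-lives (mcs) of:
#' MYC 50, AP4 600, AKT 30, FOXO1 100, cRel 60, CXCR4 150, CD40 30, CXCR5 100,
#' BLIMP1 300, BclxL 200, RelA 200, Casp3 100. Production constants are scaled
#' so that a fully induced species settles near 100 copies; `k_myc` and
#' `k_ap4` set the strength of the selection-triggered MYC pulse and of the
#' AP4 integration of that pulse, which together control burst size.
#'
#' @return Named numeric vector of rate constants.
#' @export
default_rates <- function() {
  hl <- function(h) log(2) / h
  c(k_cd40  = 100 * hl(30), d_cd40  = hl(30),
    k_akt   = 100 * hl(30), d_akt   = hl(30),
    k_foxo  = 100 * hl(100), d_foxo = hl(100),
    g_akt   = 19, K_akt = 50,
    k_crel  = 100 * hl(60), d_crel  = hl(60),
    k_myc   = 28, d_myc = hl(50),
    K_foxo  = 10,
    k_ap4   = 1.85, d_ap4 = hl(600),
    k_cxcr4 = 100 * hl(150) * 4, d_cxcr4 = hl(150),
    K_f2    = 50,
    k_cxcr5 = 100 * hl(100), d_cxcr5 = hl(100),
    k_blimp = 100 * hl(300), d_blimp = hl(300),
    k_bclxl = 100 * hl(200), d_bclxl = hl(200),
    d_rela  = hl(200),
    k_casp  = 100 * hl(100), d_casp  = hl(100),
    d_cxcr4_off = hl(25),
    K_myc_ap4 = 100)
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant of a [gc_config()] object and reports
#' violations without throwing.
#'
#' @param config A `gc_config` object.
#' @return Character vector of human-readable violations; empty if the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character()
  bad <- function(msg) v <<- c(v, msg)
  counts <- c("n_crc", "n_fdc", "n_tfh", "n_seeder")
  for (f in counts)
    if (config[[f]] < 0) bad(sprintf("%s: count must be >= 0", f))
  for (f in c("grid_x", "grid_y", "grid_z"))
    if (config[[f]] < 1) bad(sprintf("%s: must be >= 1", f))
  if (!is.null(config$midline_x) &&
      (config$midline_x <= 0 || config$midline_x >= config$grid_x))
    bad("midline_x: must lie strictly inside (0, grid_x)")
  if (config$lethal_mut_prob < 0 || config$lethal_mut_prob > 1)
    bad("lethal_mut_prob: probability must lie in [0, 1]")
  if (config$cytokinesis_fraction <= 0 || config$cytokinesis_fraction > 1)
    bad("cytokinesis_fraction: must lie in (0, 1]")
  if (config$t_end %% config$log_every != 0)
    bad("t_end: must be a multiple of log_every")
  if (!config$seeder_affinity_mode %in% c("constant-5", "uniform-3-7"))
    bad("seeder_affinity_mode: must be 'constant-5' or 'uniform-3-7'")
  if (config$timer_threshold >= config$timer_initial)
    bad("timer_threshold: must be below timer_initial")
  for (f in c("temperature", "lambda_vol", "chem_D", "chem_decay",
              "chem_secretion", "timer_span", "volume_doubling_time"))
    if (config[[f]] < 0) bad(sprintf("%s: must be >= 0", f))
  if (any(config$rates < 0)) bad("rates: all kinetic constants must be >= 0")
  if (config$chem_dt > 1 / (4 * max(config$chem_D, .Machine$double.eps)))
    bad("chem_dt: violates the explicit-scheme stability bound h^2/(4D)")
  v
}

#' Scale a configuration to a smaller field
#'
#' Shrinks the lattice to `grid_x` x `grid_y` and scales stationary-cell
#' counts by the area ratio, keeping all rates and thresholds unchanged.
#' Used for desk-scale runs.
#'
#' @param config A `gc_config`.
#' @param grid_x,grid_y New lattice dimensions (pixels).
#' @param n_seeder Number of seeder B cells for the scaled run.
#' @return A new `gc_config`.
#' @export
scale_config <- function(config, grid_x, grid_y, n_seeder) {
  f <- (grid_x * grid_y) / (config$grid_x * config$grid_y)
  config$grid_x <- as.integer(grid_x)
  config$grid_y <- as.integer(grid_y)
  config$midline_x <- grid_x / 2
  config$n_crc <- max(1L, as.integer(round(config$n_crc * f)))
  config$n_fdc <- max(1L, as.integer(round(config$n_fdc * f)))
  config$n_tfh <- max(1L, as.integer(round(config$n_tfh * f)))
  config$n_seeder <- as.integer(n_seeder)
  config
}

#' @export
print.gc_config <- function(x, ...) {
  cat(sprintf("<gc_config> %d x %d field, midline at x = %g\n",
              x$grid_x, x$grid_y, x$midline_x))
  cat(sprintf("  cells: %d CRC (DZ) | %d FDC + %d Tfh (LZ) | %d seeder B\n",
              x$n_crc, x$n_fdc, x$n_tfh, x$n_seeder))
  cat(sprintf("  clock: t_end %d mcs, log every %d, bins of %d\n",
              x$t_end, x$log_every, x$bin_width))
  invisible(x)
}

#' Write / read a configuration as a flat key-value YAML file
#'
#' Kinetic rates are flattened under a `rate_` prefix so the file stays a
#' single flat mapping.
#'
#' @param config A `gc_config`.
#' @param path File path.
#' @return `read_config` returns a `gc_config`; `write_config` returns `path`
#'   invisibly.
#' @export
write_config <- function(config, path) {
  flat <- unclass(config)
  rates <- flat$rates
  flat$rates <- NULL
  flat <- c(flat, as.list(stats::setNames(as.numeric(rates),
                                          paste0("rate_", names(rates)))))
  yaml::write_yaml(flat, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  flat <- yaml::read_yaml(path)
  is_rate <- grepl("^rate_", names(flat))
  rates <- unlist(flat[is_rate])
  names(rates) <- sub("^rate_", "", names(rates))
  args <- flat[!is_rate]
  args$rates <- rates[names(default_rates())]
  do.call(gc_config, args)
}
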