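#' Population time series in fixed bins
#'
#' Bins the run into windows of `bin_width` mcs and reports, per bin: B-cell
#' counts by zone and their DZ:LZ ratio (taken at the last logged snapshot of
#' the bin), birth events (two per division), deaths split by cause,
#' plasma-cell exits, the fraction of cells engaged in the cell cycle by
#' zone, and generation/affinity summaries (mean, interquartile range,
#' 2.5-97.5 percentiles, min, max).
#'
#' @param sim A [simulate_gc()] result (or [read_gc_logs()] list).
#' @param bin_width Bin width (mcs), default from the config.
#' @return data.frame, one row per bin.
#' @export
compute_population_series <- function(sim, bin_width = sim$config$bin_width) {
  sn <- sim$snapshots
  ev <- sim$events
  if (is.null(sn) || !nrow(sn)) stop("no snapshots logged for this run")
  tmax <- max(c(sn$t, ev$t, bin_width))
  breaks <- seq(0, ceiling(tmax / bin_width) * bin_width, by = bin_width)
  qs <- function(x) {
    if (!length(x)) return(rep(NA_real_, 7))
    c(mean(x), stats::quantile(x, c(.25, .75, .025, .975)), min(x), max(x))
  }
  out <- lapply(seq_len(length(breaks) - 1L), function(i) {
    lo <- breaks[i]; hi <- breaks[i + 1L]
    tt <- sn$t[sn$t > lo & sn$t <= hi]
    row <- data.frame(bin_start = lo, bin_end = hi)
    if (length(tt)) {
      s <- sn[sn$t == max(tt), ]
      ndz <- sum(s$zone == 0); nlz <- sum(s$zone == 1)
      g <- qs(s$generation); a <- qs(s$affinity)
      row <- cbind(row, data.frame(
        n_total = nrow(s), n_dz = ndz, n_lz = nlz,
        dzlz_ratio = if (nlz > 0) ndz / nlz else NA_real_,
        frac_cycling = mean(s$cycling),
        frac_cycling_dz = if (ndz) mean(s$cycling[s$zone == 0]) else NA_real_,
        frac_cycling_lz = if (nlz) mean(s$cycling[s$zone == 1]) else NA_real_,
        gen_mean = g[1], gen_q25 = g[2], gen_q75 = g[3],
        gen_q025 = g[4], gen_q975 = g[5], gen_min = g[6], gen_max = g[7],
        aff_mean = a[1], aff_q25 = a[2], aff_q75 = a[3],
        aff_q025 = a[4], aff_q975 = a[5], aff_min = a[6], aff_max = a[7]))
    } else {
      row <- cbind(row, data.frame(
        n_total = NA_integer_, n_dz = NA_integer_, n_lz = NA_integer_,
        dzlz_ratio = NA_real_, frac_cycling = NA_real_,
        frac_cycling_dz = NA_real_, frac_cycling_lz = NA_real_,
        gen_mean = NA_real_, gen_q25 = NA_real_, gen_q75 = NA_real_,
        gen_q025 = NA_real_, gen_q975 = NA_real_, gen_min = NA_real_,
        gen_max = NA_real_, aff_mean = NA_real_, aff_q25 = NA_real_,
        aff_q75 = NA_real_, aff_q025 = NA_real_, aff_q975 = NA_real_,
        aff_min = NA_real_, aff_max = NA_real_))
    }
    e <- ev[ev$t > lo & ev$t <= hi, ]
    d <- e[e$type == "death", ]
    row$births <- sum(e$type == "birth")
    row$deaths <- nrow(d)
    row$deaths_lethal <- sum(d$a1 == 1)
    row$deaths_negsel <- sum(d$a1 == 2)
    row$deaths_no_tfh <- sum(d$a1 == 3)
    row$pc_exits <- sum(e$type == "pc_exit")
    row
  })
  do.call(rbind, out)
}

#' Integer accounting closure of a run
#'
#' Checks the exact identity: seeders + divisions - deaths - PC exits =
#' final live count (each division retires the parent id and creates two
#' daughters, so its net contribution is +1).
#'
#' @param sim A [simulate_gc()] result.
#' @return List with the five integers and `closed` (logical).
#' @export
accounting_closure <- function(sim) {
  ev <- sim$events
  seeders <- sum(sim$cells$mother == 0)
  divisions <- sum(ev$type == "cytokinesis")
  deaths <- sum(ev$type == "death")
  pc_exits <- sum(ev$type == "pc_exit")
  final_live <- sum(sim$cells$alive)
  list(seeders = seeders, divisions = divisions, deaths = deaths,
       pc_exits = pc_exits, final_live = final_live,
       closed = seeders + divisions - deaths - pc_exits == final_live)
}

#' Inter-zonal migration times and LZ-entrant fates
#'
#' Per-cell migration legs: `T_DL` from dark-zone cycle exit to the first
#' midline crossing into the light zone; `T_LD` from positive selection to
#' the crossing back into the dark zone; `T_LZ` the whole light-zone
#' residence between those crossings; and the round trip `T_DLD = T_DL +
#' T_LZ`. Cells with incomplete trips are excluded from the trip metrics and
#' counted in the fate fractions.
#'
#' @param sim A [simulate_gc()] result.
#' @return List with `trips` (per round-trip cell data.frame), `fates`
#'   (fractions of LZ entrants: died / selected-returned / became-pc /
#'   still-in-lz), and `n_lz_entrants`.
#' @export
compute_migration_stats <- function(sim) {
  ev <- sim$events
  first_after <- function(sub, t0) {
    ok <- sub$t >= t0
    if (any(ok)) min(sub$t[ok]) else NA_real_
  }
  cross <- ev[ev$type == "zone_cross", ]
  exits <- ev[ev$type == "cycle_exit", ]
  sels <- ev[ev$type == "selection", ]
  mid <- sim$config$midline_x

  cross_in <- split(cross$t[cross$a1 == 1], cross$cell[cross$a1 == 1])
  cross_out <- split(cross$t[cross$a1 == -1], cross$cell[cross$a1 == -1])
  f_after <- function(lst, cell, t0) {
    v <- lst[[as.character(cell)]]
    v <- v[v >= t0]
    if (length(v)) v[1] else NA_real_
  }

  # round-trip legs for cells that exited a cycle in the DZ
  trips <- NULL
  if (nrow(exits)) {
    rows <- lapply(seq_len(nrow(exits)), function(i) {
      cell <- exits$cell[i]; t_exit <- exits$t[i]; x_exit <- exits$x[i]
      if (!is.na(x_exit) && x_exit >= mid) return(NULL)
      t_in <- f_after(cross_in, cell, t_exit)
      if (is.na(t_in)) return(NULL)
      t_sel <- {
        v <- sels$t[sels$cell == cell & sels$t >= t_in]
        if (length(v)) v[1] else NA_real_
      }
      t_out <- if (!is.na(t_sel)) f_after(cross_out, cell, t_sel) else NA_real_
      data.frame(cell = cell, t_exit = t_exit, t_lz_entry = t_in,
                 t_sel = t_sel, t_dz_return = t_out,
                 T_DL = t_in - t_exit,
                 T_LD = t_out - t_sel,
                 T_LZ = t_out - t_in,
                 T_DLD = (t_in - t_exit) + (t_out - t_in))
    })
    trips <- do.call(rbind, rows)
  }
  complete <- if (!is.null(trips)) trips[!is.na(trips$t_dz_return), ] else
    data.frame()

  # fates of all LZ entrants
  entrants <- unique(cross$cell[cross$a1 == 1])
  deaths <- ev[ev$type == "death", ]
  pcs <- ev[ev$type == "pc_exit", ]
  fate <- vapply(entrants, function(cell) {
    t_in <- cross_in[[as.character(cell)]][1]
    if (cell %in% pcs$cell) return("became-pc")
    t_sel <- {
      v <- sels$t[sels$cell == cell & sels$t >= t_in]
      if (length(v)) v[1] else NA_real_
    }
    if (!is.na(t_sel) && !is.na(f_after(cross_out, cell, t_sel)))
      return("selected-returned")
    if (cell %in% deaths$cell) return("died")
    "still-in-lz"
  }, character(1))
  fates <- if (length(fate))
    as.list(table(factor(fate, levels = c("died", "selected-returned",
                                          "became-pc", "still-in-lz"))) /
              length(fate))
  else list(`died` = NA, `selected-returned` = NA, `became-pc` = NA,
            `still-in-lz` = NA)

  list(trips = complete, fates = fates, n_lz_entrants = length(entrants))
}

.affinity_bins <- function(a) {
  cut(a, breaks = c(-Inf, 5, 6, 7, 8, 9, 10, Inf), right = FALSE,
      labels = c("<5", "5-6", "6-7", "7-8", "8-9", "9-10", ">=10"))
}

#' Proliferative-burst statistics by affinity bin
#'
#' A burst is the set of divisions descending from one positive-selection
#' event, delimited by selection and the cycle exit of all progeny. Burst
#' size is the number of cytokinesis events in the episode. Cell-cycle
#' lengths are measured from selection to first cytokinesis (first cycle)
#' and from growth start to cytokinesis (subsequent cycles). Affinity bins
#' are left-closed `[a, b)`: <5, 5-6, 6-7, 7-8, 8-9, 9-10, >=10; the 9-10
#' bin is reported separately rather than dropped. Bursts still open at run
#' end are excluded.
#'
#' @param sim A [simulate_gc()] result.
#' @return List with `bursts` (per-burst data.frame), `cycles` (per-division
#'   cycle lengths), and `by_bin` (per-bin mean and 95th-percentile burst
#'   size).
#' @export
compute_burst_stats <- function(sim) {
  ev <- sim$events
  cyt <- ev[ev$type == "cytokinesis", ]
  sels <- ev[ev$type == "selection", ]
  starts <- ev[ev$type == "cycle_start", ]
  if (!nrow(cyt))
    return(list(bursts = data.frame(), cycles = data.frame(),
                by_bin = data.frame()))

  # open bursts: a live cell still cycling carries the burst id
  live <- sim$cells[sim$cells$alive &
                      sim$cells$phase %in% c("selected-returning",
                                             "cycling-first",
                                             "cycling-subsequent"), ]
  open_ids <- unique(live$burst)
  open_ids <- open_ids[!is.na(open_ids)]

  bursts <- do.call(rbind, lapply(split(cyt, cyt$a1), function(d) {
    data.frame(burst = d$a1[1], size = nrow(d),
               affinity = d$a2[d$a3 == 1][1],
               t_first = min(d$t))
  }))
  bursts <- bursts[!bursts$burst %in% open_ids, , drop = FALSE]
  bursts$bin <- .affinity_bins(bursts$affinity)

  # cycle lengths
  first <- cyt[cyt$a3 == 1, ]
  fc <- merge(first[, c("cell", "t")],
              sels[, c("cell", "t")], by = "cell",
              suffixes = c("_div", "_sel"))
  fc$length <- fc$t_div - fc$t_sel
  sub <- cyt[cyt$a3 == 0, ]
  sc <- merge(sub[, c("cell", "t")],
              starts[, c("cell", "t")], by = "cell",
              suffixes = c("_div", "_start"))
  sc$length <- sc$t_div - sc$t_start
  cycles <- rbind(
    if (nrow(fc)) data.frame(cell = fc$cell, cycle = "first",
                             length = fc$length) else NULL,
    if (nrow(sc)) data.frame(cell = sc$cell, cycle = "subsequent",
                             length = sc$length) else NULL)

  by_bin <- do.call(rbind, lapply(split(bursts, bursts$bin), function(d) {
    if (!nrow(d)) return(NULL)
    data.frame(bin = as.character(d$bin[1]), n = nrow(d),
               mean_size = mean(d$size),
               p95_size = as.numeric(stats::quantile(d$size, 0.95)),
               mean_affinity = mean(d$affinity))
  }))

  list(bursts = bursts, cycles = cycles, by_bin = by_bin)
}

#' Clonal composition over time
#'
#' Per time bin: live-cell count and fraction per seeder clone, the number
#' of surviving clones, and the dominant-clone fraction. The long-format
#' table doubles as a Muller-plot table (time x clone fraction).
#'
#' @param sim A [simulate_gc()] result.
#' @param bin_width Bin width (mcs).
#' @return List with `muller` (long data.frame: bin_end, clone, n, fraction)
#'   and `summary` (per-bin surviving clones and dominance).
#' @export
compute_clonal_composition <- function(sim,
                                       bin_width = sim$config$bin_width) {
  sn <- sim$snapshots
  if (is.null(sn) || !nrow(sn)) stop("no snapshots logged for this run")
  sn$bin <- ceiling(sn$t / bin_width) * bin_width
  last_t <- stats::aggregate(t ~ bin, sn, max)
  keep <- sn[paste(sn$bin, sn$t) %in% paste(last_t$bin, last_t$t), ]
  muller <- do.call(rbind, lapply(split(keep, keep$bin), function(d) {
    tab <- table(d$clone)
    data.frame(bin_end = d$bin[1], clone = as.integer(names(tab)),
               n = as.integer(tab),
               fraction = as.numeric(tab) / nrow(d))
  }))
  summary <- do.call(rbind, lapply(split(muller, muller$bin_end),
                                   function(d) data.frame(
    bin_end = d$bin_end[1], n_clones = nrow(d),
    dominant_clone = d$clone[which.max(d$fraction)],
    dominance = max(d$fraction))))
  rownames(muller) <- rownames(summary) <- NULL
  list(muller = muller, summary = summary)
}

#' Molecular profile of a logged snapshot
#'
#' Per-species distributions split by zone at time `t`, plus the canonical
#' pairwise correlations (FOXO1-AKT, cRel-CD40, MYC-cRel, AP4-MYC,
#' CXCR4-FOXO1). Correlations over degenerate (zero-variance) columns are
#' reported as `NA`.
#'
#' @param sim A [simulate_gc()] result.
#' @param t A logged time (mcs).
#' @param zone Restrict correlations to `"DZ"`, `"LZ"` or `"all"`.
#' @return List with `levels` (long data.frame: species, zone, median, mean,
#'   q25, q75) and `correlations` (named numeric vector).
#' @export
snapshot_molecular_profile <- function(sim, t, zone = "LZ") {
  sn <- sim$snapshots
  if (is.null(sn) || !any(sn$t == t))
    stop("time ", t, " is not present in the snapshot log")
  s <- sn[sn$t == t, ]
  species <- c(.gc_species, "pmhc")
  levels <- do.call(rbind, lapply(species, function(sp) {
    do.call(rbind, lapply(c(0, 1), function(z) {
      v <- s[[sp]][s$zone == z]
      if (!length(v)) return(NULL)
      data.frame(species = sp, zone = c("DZ", "LZ")[z + 1],
                 n = length(v), median = stats::median(v), mean = mean(v),
                 q25 = as.numeric(stats::quantile(v, .25)),
                 q75 = as.numeric(stats::quantile(v, .75)))
    }))
  }))
  sub <- switch(zone, DZ = s[s$zone == 0, ], LZ = s[s$zone == 1, ], s)
  safe_cor <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }
  correlations <- c(
    FOXO1_AKT = safe_cor(sub$FOXO1, sub$AKT),
    cRel_CD40 = safe_cor(sub$cRel, sub$CD40),
    MYC_cRel = safe_cor(sub$MYC, sub$cRel),
    AP4_MYC = safe_cor(sub$AP4, sub$MYC),
    CXCR4_FOXO1 = safe_cor(sub$CXCR4, sub$FOXO1))
  list(levels = levels, correlations = correlations)
}

#' Headline summary of a run
#'
#' The main scalar readouts of a simulation, suitable for JSON export: final
#' and late-run DZ:LZ ratio, LZ-entrant fate fractions, burst size mean/sd,
#' migration-time medians/means/sds, first/subsequent cycle lengths, and
#' final clonal dominance.
#'
#' @param sim A [simulate_gc()] result.
#' @return Nested list of scalars.
#' @export
gc_summary <- function(sim) {
  pop <- compute_population_series(sim)
  pop <- pop[!is.na(pop$n_total), ]
  mig <- compute_migration_stats(sim)
  bur <- compute_burst_stats(sim)
  late <- pop[pop$bin_end > max(pop$bin_end) * 0.75, ]
  leg <- function(v) if (length(v) && any(!is.na(v)))
    list(median = stats::median(v, na.rm = TRUE), mean = mean(v, na.rm = TRUE),
         sd = stats::sd(v, na.rm = TRUE)) else
    list(median = NA, mean = NA, sd = NA)
  cyc <- bur$cycles
  list(
    n_final = pop$n_total[nrow(pop)],
    dzlz_ratio_final = pop$dzlz_ratio[nrow(pop)],
    dzlz_ratio_late = mean(late$dzlz_ratio, na.rm = TRUE),
    frac_cycling_late = mean(late$frac_cycling, na.rm = TRUE),
    fates = mig$fates,
    n_lz_entrants = mig$n_lz_entrants,
    T_DL = leg(mig$trips$T_DL), T_LD = leg(mig$trips$T_LD),
    T_LZ = leg(mig$trips$T_LZ), T_DLD = leg(mig$trips$T_DLD),
    burst_size = if (nrow(bur$bursts))
      list(mean = mean(bur$bursts$size), sd = stats::sd(bur$bursts$size),
           min = min(bur$bursts$size), max = max(bur$bursts$size),
           n = nrow(bur$bursts)) else NULL,
    first_cycle = leg(cyc$length[cyc$cycle == "first"]),
    subsequent_cycle = leg(cyc$length[cyc$cycle == "subsequent"]),
    pcs = nrow(sim$pcs))
}
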