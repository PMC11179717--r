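# Growing record buffer for the event stream and snapshots ------------------

.rec_new <- function(ncol, cap = 4096L) {
  e <- new.env(parent = emptyenv())
  e$mat <- matrix(NA_real_, cap, ncol)
  e$n <- 0L
  e
}

.rec_add <- function(e, rows) {
  if (is.null(dim(rows))) rows <- matrix(rows, 1)
  k <- nrow(rows)
  while (e$n + k > nrow(e$mat)) {
    newmat <- matrix(NA_real_, 2L * nrow(e$mat), ncol(e$mat))
    newmat[seq_len(e$n), ] <- e$mat[seq_len(e$n), ]
    e$mat <- newmat
  }
  e$mat[e$n + seq_len(k), ] <- rows
  e$n <- e$n + k
  invisible(e)
}

.rec_df <- function(e, names) {
  m <- e$mat[seq_len(e$n), , drop = FALSE]
  colnames(m) <- names
  as.data.frame(m)
}

.event_types <- c("birth", "death", "selection", "mutation", "zone_cross",
                  "cycle_exit", "cytokinesis", "pc_exit", "cycle_start")
.death_causes <- c("lethal-mutation", "negatively-selected", "no-Tfh-access")
.phase_labels <- c("migrating-to-LZ", "LZ-resident", "selected-returning",
                   "cycling-first", "cycling-subsequent", "apoptotic", "pc")

#' Run a germinal-center simulation
#'
#' The full multiscale loop: the tissue is laid out and the two chemokine
#' fields are equilibrated and frozen; then for every Monte Carlo step the
#' Cellular Potts dynamics move and grow the B cells, cell-cell contacts are
#' extracted, the fate rules fire (FDC contact sets pMHCII and the RelA
#' switch, Tfh contact runs selection trials, the death timer advances,
#' AP4-gated divisions with somatic hypermutation occur, plasma cells exit),
#' and each B cell's intracellular network is advanced by one mcs of
#' stochastic simulation.
#'
#' @param config A [gc_config()].
#' @param seed Integer seed; defaults to `config$rng_seed`.
#' @param t_end Override of `config$t_end` (mcs).
#' @param log_every Snapshot interval (mcs), default `config$log_every`.
#' @param keep_fields Keep the equilibrated chemokine fields in the result.
#' @param progress Print a line every 1000 mcs.
#' @return A `gc_sim` object: list with `config`, `seed`, `snapshots`
#'   (one row per live B cell per logged mcs), `events` (the event stream),
#'   `cells` (per-cell lineage table), `pcs` (plasma-cell output),
#'   `layout`, optionally `fields`, and `counters`.
#' @export
simulate_gc <- function(config, seed = config$rng_seed,
                        t_end = config$t_end,
                        log_every = config$log_every,
                        keep_fields = FALSE, progress = FALSE) {
  cfg <- config
  stopifnot(t_end >= 1)
  layout <- build_layout(cfg, seed = seed)
  fields <- fields_from_layout(layout)
  f12 <- fields$cxcl12$conc
  f13 <- fields$cxcl13$conc

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  lattice <- gc_lattice(layout)
  lat <- lattice$lat
  J <- lattice$J
  mid <- cfg$midline_x
  rates <- .rate_vector(cfg$rates)
  V0 <- cfg$target_volume
  V2 <- 2 * V0
  div_vol <- ceiling(cfg$cytokinesis_fraction * V2)
  growth_rate <- V0 / cfg$volume_doubling_time
  timer_rate <- (cfg$timer_initial - cfg$timer_threshold) / cfg$timer_span
  pmhc_step <- 2^(-1 / cfg$pmhc_halflife)
  mol0 <- molecular_state(cfg$rates)

  # --- per-id state vectors ------------------------------------------------
  n0 <- nrow(layout$cells)
  cap <- max(256L, 2L * n0)
  num <- function(x = NA_real_) rep(x, cap)
  S <- new.env(parent = emptyenv())
  S$alive <- rep(FALSE, cap)
  S$typecode <- integer(cap)
  S$vol <- integer(cap); S$tvol <- numeric(cap)
  S$clone <- integer(cap); S$mother <- integer(cap); S$gen <- integer(cap)
  S$aff <- num(); S$phase <- integer(cap)
  S$committed <- rep(FALSE, cap); S$first_cycle <- rep(FALSE, cap)
  S$timer_on <- rep(FALSE, cap); S$timer <- num(0)
  S$had_trial <- rep(FALSE, cap)
  S$pmhc <- num(0); S$pmhc_set <- rep(FALSE, cap)
  S$pmhc_decaying <- rep(FALSE, cap)
  S$rela_fired <- rep(FALSE, cap)
  S$in_tfh <- rep(FALSE, cap); S$in_lz <- rep(FALSE, cap)
  S$sel_time <- num(-Inf); S$growth_start <- num(Inf)
  S$gate_until <- num(-Inf); S$death_at <- num(Inf)
  S$cycle_start <- num(NA); S$burst <- num(NA)
  S$birth_t <- num(NA); S$death_cause <- integer(cap)
  S$M <- matrix(0, cap, 12)
  S$lam12 <- numeric(cap); S$lam13 <- numeric(cap)

  grow_cap <- function(n) {
    while (n > length(S$alive)) {
      k <- length(S$alive)
      pad_l <- rep(FALSE, k); pad_i <- integer(k); pad_n <- rep(NA_real_, k)
      S$alive <- c(S$alive, pad_l); S$typecode <- c(S$typecode, pad_i)
      S$vol <- c(S$vol, pad_i); S$tvol <- c(S$tvol, numeric(k))
      S$clone <- c(S$clone, pad_i); S$mother <- c(S$mother, pad_i)
      S$gen <- c(S$gen, pad_i); S$aff <- c(S$aff, pad_n)
      S$phase <- c(S$phase, pad_i)
      S$committed <- c(S$committed, pad_l)
      S$first_cycle <- c(S$first_cycle, pad_l)
      S$timer_on <- c(S$timer_on, pad_l); S$timer <- c(S$timer, numeric(k))
      S$had_trial <- c(S$had_trial, pad_l)
      S$pmhc <- c(S$pmhc, numeric(k)); S$pmhc_set <- c(S$pmhc_set, pad_l)
      S$pmhc_decaying <- c(S$pmhc_decaying, pad_l)
      S$rela_fired <- c(S$rela_fired, pad_l)
      S$in_tfh <- c(S$in_tfh, pad_l); S$in_lz <- c(S$in_lz, pad_l)
      S$sel_time <- c(S$sel_time, rep(-Inf, k))
      S$growth_start <- c(S$growth_start, rep(Inf, k))
      S$gate_until <- c(S$gate_until, rep(-Inf, k))
      S$death_at <- c(S$death_at, rep(Inf, k))
      S$cycle_start <- c(S$cycle_start, pad_n)
      S$burst <- c(S$burst, pad_n); S$birth_t <- c(S$birth_t, pad_n)
      S$death_cause <- c(S$death_cause, pad_i)
      S$M <- rbind(S$M, matrix(0, k, 12))
      S$lam12 <- c(S$lam12, numeric(k)); S$lam13 <- c(S$lam13, numeric(k))
    }
  }

  # initialise from the layout
  for (i in seq_len(n0)) {
    id <- layout$cells$id[i]
    S$typecode[id] <- c(B = 1L, CRC = 2L, FDC = 3L, TFH = 4L)[[
      layout$cells$type[i]]]
    S$alive[id] <- TRUE
    S$vol[id] <- nrow(layout$pixels[[id]])
    S$tvol[id] <- if (S$typecode[id] == 1L) V0 else S$vol[id]
  }
  bseed <- layout$cells$id[layout$cells$type == "B"]
  S$clone[bseed] <- layout$cells$clone[layout$cells$type == "B"]
  S$aff[bseed] <- layout$cells$affinity[layout$cells$type == "B"]
  S$mother[bseed] <- 0L; S$gen[bseed] <- 0L
  S$phase[bseed] <- 1L                     # migrating-to-LZ
  S$timer_on[bseed] <- TRUE                # default fate is apoptosis
  S$timer[bseed] <- cfg$timer_initial
  S$birth_t[bseed] <- 0
  S$M[bseed, ] <- matrix(mol0, length(bseed), 12, byrow = TRUE)
  next_id <- max(c(0L, layout$cells$id)) + 1L
  next_burst <- 1L
  ib <- bseed                               # live B-cell ids
  maxid <- next_id - 1L

  ev <- .rec_new(7L)     # t, type, cell, x, a1, a2, a3
  snap <- list()
  pcs <- .rec_new(3L)    # t, cell, affinity
  n_lastpix <- 0
  stationary <- which(S$typecode >= 2L & S$alive)

  add_event <- function(t, type, cell, x = NA, a1 = NA, a2 = NA, a3 = NA)
    .rec_add(ev, cbind(t, type, cell, x, a1, a2, a3))

  remove_cells <- function(ids) {
    if (!length(ids)) return()
    lat[lat %in% ids] <<- 0L
    S$alive[ids] <- FALSE
    S$vol[ids] <- 0L
    S$lam12[ids] <- 0; S$lam13[ids] <- 0
    ib <<- setdiff(ib, ids)
  }

  # --- main loop -----------------------------------------------------------
  for (t in seq_len(t_end)) {
    # chemotaxis strengths from receptor levels
    S$lam12[ib] <- cfg$lambda_cxcl12 * pmin(S$M[ib, 8], 150) / 100
    S$lam13[ib] <- cfg$lambda_cxcl13 * pmin(S$M[ib, 9], 150) / 100

    res <- .cpp_cpm_sweep(lat, S$vol, S$tvol, S$typecode,
                          S$lam12, S$lam13, f12, f13, J,
                          cfg$temperature, cfg$lambda_vol, length(lat),
                          cfg$chem_sat, cfg$chem_sat)
    n_lastpix <- n_lastpix + res$lastpixel_rejects

    scan <- .cpp_lattice_scan(lat, maxid)
    cx <- scan$cx; cy <- scan$cy

    # zone bookkeeping and crossing events
    if (length(ib)) {
      lz <- cx[ib] >= mid
      crossed <- which(lz != S$in_lz[ib])
      for (j in crossed) {
        id <- ib[j]
        add_event(t, 5L, id, cx[id], if (lz[j]) 1 else -1)
        if (lz[j] && S$phase[id] == 1L) S$phase[id] <- 2L
      }
      S$in_lz[ib] <- lz
    }

    # contacts
    a <- scan$pair_a; b <- scan$pair_b
    ta <- S$typecode[a]; tb <- S$typecode[b]
    fdcC <- unique(c(a[ta == 1L & tb == 3L], b[tb == 1L & ta == 3L]))
    tfhC <- unique(c(a[ta == 1L & tb == 4L], b[tb == 1L & ta == 4L]))

    # FDC contact: antigen capture in the LZ for uncommitted cells. BCR
    # signalling (AKT production, FOXO1 dip) persists while the cell stays
    # antigen-armed (pMHCII set) and uncommitted in the LZ.
    cand <- fdcC[S$alive[fdcC] & S$in_lz[fdcC] & !S$committed[fdcC] &
                   S$phase[fdcC] %in% c(1L, 2L)]
    if (length(cand)) {
      S$pmhc[cand] <- selection_probability(S$aff[cand])
      S$pmhc_set[cand] <- TRUE
      S$pmhc_decaying[cand] <- FALSE
      fire <- cand[S$aff[cand] >= cfg$affinity_pc_threshold &
                     !S$rela_fired[cand]]
      if (length(fire)) { S$M[fire, 5] <- 100; S$rela_fired[fire] <- TRUE }
    }
    fdc_sig <- integer(length(S$alive))
    armed <- ib[S$pmhc_set[ib] & !S$committed[ib] & S$in_lz[ib]]
    fdc_sig[armed] <- 1L

    # Tfh contact: one selection trial per new contact episode
    now_tfh <- logical(length(S$alive)); now_tfh[tfhC] <- TRUE
    cand <- tfhC[S$alive[tfhC] & S$phase[tfhC] == 2L & S$pmhc_set[tfhC] &
                   !S$committed[tfhC] & !S$in_tfh[tfhC]]
    for (id in cand) {
      S$had_trial[id] <- TRUE
      if (stats::runif(1) < S$pmhc[id]) {
        S$committed[id] <- TRUE
        S$timer_on[id] <- FALSE
        S$timer[id] <- cfg$timer_initial
        S$phase[id] <- 3L                       # selected-returning
        S$first_cycle[id] <- TRUE
        S$sel_time[id] <- t
        S$growth_start[id] <- t + cfg$growth_delay_first_cycle
        S$cycle_start[id] <- t
        S$burst[id] <- next_burst; next_burst <- next_burst + 1L
        S$pmhc_decaying[id] <- TRUE
        add_event(t, 3L, id, cx[id], S$aff[id])
      }
    }
    S$in_tfh[ib] <- now_tfh[ib]

    # advance the intracellular networks by 1 mcs
    if (length(ib)) {
      Msub <- S$M[ib, , drop = FALSE]
      # CD40 signalling runs as a fixed-length episode from selection,
      # emulating the prolonged B-Tfh entanglement
      tfh_sig <- as.integer(S$committed[ib] &
                              t <= S$sel_time[ib] + cfg$tfh_signal_max)
      gate <- as.integer(S$committed[ib] | t < S$gate_until[ib])
      apo <- as.integer(S$phase[ib] == 6L)
      .cpp_ssa_advance(Msub, S$aff[ib], S$pmhc[ib], fdc_sig[ib], tfh_sig,
                       gate, apo, 1.0, rates)
      S$M[ib, ] <- Msub
    }

    # pMHCII downregulation after selection or on DZ residence
    dec <- ib[S$pmhc[ib] > 0 & (S$pmhc_decaying[ib] | !S$in_lz[ib])]
    if (length(dec)) {
      S$pmhc[dec] <- S$pmhc[dec] * pmhc_step
      z <- dec[S$pmhc[dec] < 0.01]
      S$pmhc[z] <- 0; S$pmhc_set[z] <- FALSE
    }

    # death timer
    ton <- ib[S$timer_on[ib]]
    if (length(ton)) {
      S$timer[ton] <- S$timer[ton] - timer_rate
      fired <- ton[S$timer[ton] < cfg$timer_threshold]
      for (id in fired) {
        cause <- if (S$had_trial[id]) 2L else 3L
        S$death_cause[id] <- cause
        add_event(t, 2L, id, cx[id], cause)
      }
      remove_cells(fired)
    }

    # scheduled apoptosis of lethally mutated cells
    doomed <- ib[S$death_at[ib] <= t]
    if (length(doomed)) {
      S$death_cause[doomed] <- 1L
      for (id in doomed) add_event(t, 2L, id, cx[id], 1L)
      remove_cells(doomed)
    }

    # growth of committed cells past their growth-start time
    gr <- ib[S$committed[ib] & t >= S$growth_start[ib] & S$tvol[ib] < V2]
    if (length(gr)) S$tvol[gr] <- pmin(V2, S$tvol[gr] + growth_rate)

    # cytokinesis, in random order: fires once the growth program has
    # completed its ramp and the volume has reached the pre-cytokinesis
    # threshold (cycle lengths are targeted as a constant)
    dividing <- ib[S$committed[ib] & S$vol[ib] >= div_vol &
                     t >= S$growth_start[ib] + cfg$volume_doubling_time]
    if (length(dividing) > 1) dividing <- sample(dividing)
    for (id in dividing) {
      px <- which(lat == id, arr.ind = TRUE)
      if (nrow(px) < 2) next
      d1 <- split_pixels(px, cfg$split_sigma)
      grow_cap(next_id + 1L)
      kids <- c(next_id, next_id + 1L)
      next_id <- next_id + 2L
      maxid <- max(maxid, kids)
      lat[px[d1, , drop = FALSE]] <- kids[1]
      lat[px[!d1, , drop = FALSE]] <- kids[2]
      add_event(t, 7L, id, cx[id], S$burst[id],
                S$aff[id], as.integer(S$first_cycle[id]))
      mother_M <- S$M[id, ]
      mut <- mutate_bcr(S$aff[id], cfg$lethal_mut_prob, n = 2L)
      vols <- c(sum(d1), sum(!d1))
      for (k in 1:2) {
        kid <- kids[k]
        S$alive[kid] <- TRUE; S$typecode[kid] <- 1L
        S$vol[kid] <- vols[k]; S$tvol[kid] <- V0
        S$clone[kid] <- S$clone[id]; S$mother[kid] <- id
        S$gen[kid] <- S$gen[id] + 1L
        S$M[kid, ] <- mother_M
        S$in_lz[kid] <- S$in_lz[id]
        S$birth_t[kid] <- t
        S$pmhc[kid] <- 0; S$pmhc_set[kid] <- FALSE
        add_event(t, 1L, kid, cx[id], S$clone[kid], S$gen[kid])
        add_event(t, 4L, kid, cx[id],
                  as.integer(mut$lethal[k]), mut$delta[k])
        if (mut$lethal[k]) {
          S$aff[kid] <- -1
          S$phase[kid] <- 6L                     # apoptotic
          S$death_at[kid] <- t + cfg$apop_delay
        } else {
          S$aff[kid] <- mut$affinity[k]
          if (mother_M[7] >= cfg$ap4_threshold) { # continue the burst
            S$committed[kid] <- TRUE
            S$phase[kid] <- 5L                   # cycling-subsequent
            S$growth_start[kid] <- t
            S$cycle_start[kid] <- t
            S$burst[kid] <- S$burst[id]
            S$sel_time[kid] <- S$sel_time[id]
            add_event(t, 9L, kid, cx[id], S$burst[kid], 0)
          } else {                               # exit the cycle
            S$committed[kid] <- FALSE
            S$phase[kid] <- 1L                   # migrating-to-LZ
            S$gate_until[kid] <- t + cfg$cxcr4_lag
            S$timer_on[kid] <- TRUE
            S$timer[kid] <- cfg$timer_initial
            S$had_trial[kid] <- FALSE
            add_event(t, 6L, kid, cx[id])
          }
        }
      }
      S$alive[id] <- FALSE; S$vol[id] <- 0L
      S$lam12[id] <- 0; S$lam13[id] <- 0
      ib <- c(setdiff(ib, id), kids)
    }

    # plasma-cell differentiation and GC exit
    pc <- ib[S$in_lz[ib] & S$rela_fired[ib] &
               S$aff[ib] >= cfg$affinity_pc_threshold &
               S$M[ib, 10] >= cfg$blimp_on]
    if (length(pc)) {
      for (id in pc) {
        add_event(t, 8L, id, cx[id], S$aff[id])
        .rec_add(pcs, cbind(t, id, S$aff[id]))
        S$phase[id] <- 7L
      }
      remove_cells(pc)
    }

    # snapshot logging
    if (t %% log_every == 0 && length(ib)) {
      o <- ib[order(ib)]
      snap[[length(snap) + 1L]] <- cbind(
        t = t, id = o, mother = S$mother[o], generation = S$gen[o],
        clone = S$clone[o], x = cx[o], y = cy[o],
        zone = as.integer(S$in_lz[o]), volume = S$vol[o],
        affinity = S$aff[o], phase = S$phase[o], pmhc = S$pmhc[o],
        timer = ifelse(S$timer_on[o], S$timer[o], NA_real_),
        cycling = as.integer(S$committed[o]), S$M[o, , drop = FALSE])
    }
    if (progress && t %% 1000 == 0)
      message(sprintf("mcs %d: %d B cells", t, length(ib)))
  }

  snapshots <- if (length(snap)) {
    m <- do.call(rbind, snap)
    colnames(m)[15:26] <- .gc_species
    as.data.frame(m)
  } else NULL

  events <- .rec_df(ev, c("t", "type", "cell", "x", "a1", "a2", "a3"))
  events$type <- .event_types[events$type]

  allid <- seq_len(maxid)
  bsel <- S$typecode[allid] == 1L
  cells <- data.frame(id = allid[bsel], mother = S$mother[allid][bsel],
                      generation = S$gen[allid][bsel],
                      clone = S$clone[allid][bsel],
                      affinity = S$aff[allid][bsel],
                      birth_t = S$birth_t[allid][bsel],
                      burst = S$burst[allid][bsel],
                      alive = S$alive[allid][bsel],
                      phase = .phase_labels[pmax(1L, S$phase[allid][bsel])],
                      death_cause = c(.death_causes, "")[ifelse(
                        S$death_cause[allid][bsel] == 0L, 4L,
                        S$death_cause[allid][bsel])])

  out <- list(config = cfg, seed = seed, t_end = t_end,
              snapshots = snapshots, events = events, cells = cells,
              pcs = .rec_df(pcs, c("t", "cell", "affinity")),
              layout = layout,
              counters = list(lastpixel_rejects = n_lastpix,
                              final_live = length(ib)))
  if (keep_fields) out$fields <- fields
  class(out) <- "gc_sim"
  out
}

#' @export
print.gc_sim <- function(x, ...) {
  cat(sprintf("<gc_sim> %d mcs, seed %d: %d live B cells, %d events, %d PCs\n",
              x$t_end, x$seed, x$counters$final_live, nrow(x$events),
              nrow(x$pcs)))
  invisible(x)
}
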