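# minimal hand-built gc_sim objects for exercising the analysis layer
fake_sim <- function(snapshots = NULL, events = NULL, cells = NULL,
                     pcs = NULL, cfg = gc_config()) {
  ev0 <- data.frame(t = numeric(), type = character(), cell = numeric(),
                    x = numeric(), a1 = numeric(), a2 = numeric(),
                    a3 = numeric())
  structure(list(config = cfg, snapshots = snapshots,
                 events = if (is.null(events)) ev0 else events,
                 cells = cells,
                 pcs = if (is.null(pcs))
                   data.frame(t = numeric(), cell = numeric(),
                              affinity = numeric()) else pcs),
            class = "gc_sim")
}

snap_row <- function(t, id, zone, clone = 1, cycling = 0, gen = 1, aff = 5) {
  data.frame(t = t, id = id, mother = 0, generation = gen, clone = clone,
             x = if (zone) 75 else 25, y = 50, zone = zone, volume = 30,
             affinity = aff, phase = 2, pmhc = 0, timer = NA,
             cycling = cycling, CD40 = 0, AKT = 0, FOXO1 = 100, cRel = 0,
             RelA = 0, MYC = 0, AP4 = 0, CXCR4 = 0, CXCR5 = 100,
             BLIMP1 = 0, BclxL = 0, Casp3 = 0)
}

test_that("population series counts zones, births and death causes", {
  sn <- rbind(snap_row(600, 1, 0), snap_row(600, 2, 0), snap_row(600, 3, 0),
              snap_row(600, 4, 1))
  sim <- fake_sim(snapshots = sn)
  pop <- compute_population_series(sim, bin_width = 600)
  expect_equal(pop$n_dz[1], 3)
  expect_equal(pop$n_lz[1], 1)
  expect_equal(pop$dzlz_ratio[1], 3)
  expect_equal(pop$births[1], 0)
  expect_equal(pop$deaths[1], 0)

  ev <- data.frame(t = c(100, 100, 200, 300, 400),
                   type = c("birth", "birth", "death", "death", "death"),
                   cell = 1:5, x = 10, a1 = c(1, 2, 1, 2, 3), a2 = NA,
                   a3 = NA)
  sim2 <- fake_sim(snapshots = sn, events = ev)
  pop2 <- compute_population_series(sim2, bin_width = 600)
  expect_equal(pop2$births[1], 2)
  expect_equal(pop2$deaths[1], 3)
  expect_equal(c(pop2$deaths_lethal[1], pop2$deaths_negsel[1],
                 pop2$deaths_no_tfh[1]), c(1, 1, 1))
})

test_that("migration legs are measured from hand-built trajectories", {
  ev <- rbind(
    data.frame(t = 100, type = "cycle_exit", cell = 1, x = 60, a1 = NA,
               a2 = NA, a3 = NA),
    data.frame(t = 500, type = "zone_cross", cell = 1, x = 50, a1 = 1,
               a2 = NA, a3 = NA),
    data.frame(t = 1000, type = "selection", cell = 1, x = 70, a1 = 5,
               a2 = NA, a3 = NA),
    data.frame(t = 1600, type = "zone_cross", cell = 1, x = 50, a1 = -1,
               a2 = NA, a3 = NA))
  sim <- fake_sim(events = ev)
  mig <- compute_migration_stats(sim)
  expect_equal(nrow(mig$trips), 1)
  expect_equal(mig$trips$T_DL, 400)
  expect_equal(mig$trips$T_LD, 600)
  expect_equal(mig$trips$T_LZ, 1100)
  expect_equal(mig$trips$T_DLD, mig$trips$T_DL + mig$trips$T_LZ)
  expect_equal(mig$fates$`selected-returned`, 1, ignore_attr = TRUE)
})

test_that("burst sizes and cycle lengths come from the event stream", {
  ev <- rbind(
    data.frame(t = 0, type = "selection", cell = 10, x = 70, a1 = 5,
               a2 = NA, a3 = NA),
    data.frame(t = 1400, type = "cytokinesis", cell = 10, x = 40, a1 = 1,
               a2 = 5, a3 = 1),
    data.frame(t = 1400, type = "cycle_start", cell = 11, x = 40, a1 = 1,
               a2 = 0, a3 = NA),
    data.frame(t = 1900, type = "cytokinesis", cell = 11, x = 40, a1 = 1,
               a2 = 5.25, a3 = 0),
    data.frame(t = 1450, type = "cycle_start", cell = 12, x = 40, a1 = 1,
               a2 = 0, a3 = NA),
    data.frame(t = 2000, type = "cytokinesis", cell = 12, x = 40, a1 = 1,
               a2 = 4.75, a3 = 0))
  cells <- data.frame(id = c(10, 11, 12), alive = FALSE,
                      phase = "migrating-to-LZ", burst = 1)
  sim <- fake_sim(events = ev, cells = cells)
  bs <- compute_burst_stats(sim)
  expect_equal(nrow(bs$bursts), 1)
  expect_equal(bs$bursts$size, 3)
  expect_equal(as.character(bs$bursts$bin), "5-6")
  fc <- bs$cycles[bs$cycles$cycle == "first", ]
  expect_equal(fc$length, 1400)
  sc <- bs$cycles[bs$cycles$cycle == "subsequent", ]
  expect_equal(sort(sc$length), c(500, 550))

  # an open burst (still-cycling carrier) is excluded
  cells_open <- within(cells, {alive[2] <- TRUE; phase[2] <- "cycling-subsequent"})
  bs2 <- compute_burst_stats(fake_sim(events = ev, cells = cells_open))
  expect_equal(nrow(bs2$bursts), 0)
})

test_that("clonal composition normalises and finds dominance", {
  sn <- do.call(rbind, lapply(1:10, function(i) snap_row(600, i, 0,
                                                         clone = 1)))
  cc <- compute_clonal_composition(fake_sim(snapshots = sn), 600)
  expect_equal(cc$summary$dominance, 1)
  expect_equal(cc$summary$n_clones, 1)

  sn2 <- do.call(rbind, lapply(1:10, function(i)
    snap_row(600, i, 0, clone = c(rep(1, 6), 2, 2, 3, 3)[i])))
  cc2 <- compute_clonal_composition(fake_sim(snapshots = sn2), 600)
  expect_equal(cc2$summary$dominance, 0.6)
  expect_equal(cc2$summary$n_clones, 3)
  expect_equal(sum(cc2$muller$fraction), 1, tolerance = 1e-9)
})

test_that("degenerate molecular snapshots report NA correlations", {
  sn <- rbind(snap_row(600, 1, 1), snap_row(600, 2, 1), snap_row(600, 3, 1))
  prof <- snapshot_molecular_profile(fake_sim(snapshots = sn), 600, "LZ")
  expect_true(all(is.na(prof$correlations)))
  expect_error(snapshot_molecular_profile(fake_sim(snapshots = sn), 615),
               "not present")
})

test_that("full-run statistics satisfy the structural invariants", {
  sims <- scaled_sims()
  for (sim in sims) {
    # exact integer accounting closure
    acc <- accounting_closure(sim)
    expect_true(acc$closed)
    # zone counts partition the population in every bin
    pop <- compute_population_series(sim)
    ok <- !is.na(pop$n_total)
    expect_equal(pop$n_dz[ok] + pop$n_lz[ok], pop$n_total[ok])
    expect_equal(pop$deaths_lethal + pop$deaths_negsel + pop$deaths_no_tfh,
                 pop$deaths)
    # migration identities
    tr <- compute_migration_stats(sim)$trips
    expect_true(all(tr$T_LZ >= tr$T_LD))
    expect_equal(tr$T_DLD, tr$T_DL + tr$T_LZ)
    # clone fractions sum to one in every bin
    mull <- compute_clonal_composition(sim)$muller
    sums <- tapply(mull$fraction, mull$bin_end, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    # no pMHCII in the DZ at a mature snapshot
    tt <- best_lz_time(sim)
    s <- sim$snapshots[sim$snapshots$t == tt, ]
    expect_equal(stats::median(s$pmhc[s$zone == 0]), 0)
  }

  # 95th-percentile burst size rises with affinity bin (pooled)
  allb <- do.call(rbind, lapply(sims, function(s) compute_burst_stats(s)$bursts))
  bb <- do.call(rbind, lapply(split(allb, allb$bin), function(d)
    if (nrow(d) >= 5) data.frame(p95 = stats::quantile(d$size, .95)) else NULL))
  expect_gte(nrow(bb), 3)
  expect_gt(stats::cor(seq_len(nrow(bb)), bb$p95, method = "spearman"), 0)
})
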