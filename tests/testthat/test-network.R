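test_that("a single birth-death species reaches the analytic stationary law", {
  # only constitutive CXCR5 active: production a = 2, decay d = 0.02,
  # stationary mean a/d = 100 with Poisson variance
  r <- default_rates()
  r[] <- 0
  r["k_cxcr5"] <- 2; r["d_cxcr5"] <- 0.02
  s0 <- stats::setNames(numeric(12), names(molecular_state()))
  s0["CXCR5"] <- 100
  set.seed(1)
  finals <- replicate(200, {
    advance_network(s0, signals = list(), duration = 500, rates = r)[["CXCR5"]]
  })
  se <- sqrt(100) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 100), 3 * se)
  # variance consistent with Poisson (generous factor-two bracket)
  expect_gt(stats::var(finals), 100 / 2)
  expect_lt(stats::var(finals), 100 * 2)
})

test_that("a dead network never moves", {
  r <- default_rates()
  r[] <- 0
  s0 <- molecular_state()
  out <- advance_network(s0, list(fdc_contact = 1, tfh_contact = 1,
                                  affinity = 8, pmhc = 0.8),
                         duration = 1000, rates = r)
  expect_equal(out, s0)
  expect_error(advance_network(s0, list(), duration = 0), "duration")
})

test_that("a CD40 pulse produces the MYC-then-AP4 ordering of the ODE oracle", {
  r <- default_rates()
  r["k_foxo"] <- 0  # FOXO1 held low so the MYC gate is open
  pulse <- 50
  horizon <- pulse + 600

  # deterministic oracle: same rate equations integrated with deSolve
  rhs <- function(t, y, p) {
    tfh <- as.numeric(t < pulse)
    with(as.list(y), {
      dCD40 <- p[["k_cd40"]] * tfh - p[["d_cd40"]] * CD40
      dcRel <- p[["k_crel"]] * CD40 / 100 - p[["d_crel"]] * cRel
      dMYC <- p[["k_myc"]] * (cRel / 100) *
        p[["K_foxo"]] / (p[["K_foxo"]] + 0) - p[["d_myc"]] * MYC
      dAP4 <- p[["k_ap4"]] * MYC / (p[["K_myc_ap4"]] + MYC) -
        p[["d_ap4"]] * AP4
      list(c(dCD40, dcRel, dMYC, dAP4))
    })
  }
  times <- seq(0, horizon, 5)
  ode <- deSolve::ode(c(CD40 = 0, cRel = 0, MYC = 0, AP4 = 0),
                      times, rhs, r)
  ode <- as.data.frame(ode)
  expect_gt(ode$time[which.max(ode$AP4)], pulse)           # AP4 peaks after the pulse
  expect_lt(ode$time[which.max(ode$MYC)], ode$time[which.max(ode$AP4)])
  expect_gt(ode$AP4[ode$time == pulse + 500],
            ode$MYC[ode$time == pulse + 500])

  # stochastic runs reproduce the same ordering in nearly all replicates
  set.seed(2)
  okay <- 0
  for (i in 1:50) {
    s <- stats::setNames(numeric(12), names(molecular_state()))
    traj <- matrix(0, 0, 2)
    for (tt in seq(10, horizon, 10)) {
      sig <- list(tfh_contact = as.integer(tt <= pulse), pmhc = 1)
      s <- advance_network(s, sig, duration = 10, rates = r)
      traj <- rbind(traj, c(s[["MYC"]], s[["AP4"]]))
    }
    tgrid <- seq(10, horizon, 10)
    myc_pk <- tgrid[which.max(traj[, 1])]
    ap4_pk <- tgrid[which.max(traj[, 2])]
    at_tail <- traj[tgrid == pulse + 500, ]
    if (ap4_pk > pulse && myc_pk < ap4_pk && at_tail[2] > at_tail[1])
      okay <- okay + 1
  }
  expect_gte(okay, 45)
})

test_that("FDC contact sets pMHCII proportionally and fires the RelA switch", {
  out <- apply_fdc_contact(molecular_state(), affinity = 5)
  expect_equal(out$pmhc, 0.5)
  expect_false(out$rela_fired)
  expect_equal(apply_fdc_contact(molecular_state(), 0)$pmhc, 0)
  hi <- apply_fdc_contact(molecular_state(), 12)
  expect_equal(hi$pmhc, 1)
  expect_true(hi$rela_fired)
  expect_equal(hi$molecular[["RelA"]], 100)
})

test_that("pMHCII downregulation has a 100-mcs half-life and clamps to zero", {
  expect_equal(decay_pmhc(1.0, 100), 0.5)
  expect_equal(decay_pmhc(0, 50), 0)
  expect_equal(decay_pmhc(1.0, 700), 0)  # below reporting threshold
  expect_gt(decay_pmhc(1.0, 600), 0)
})

test_that("the reaction list serialises the full network", {
  rx <- network_reactions()
  expect_true(all(c("MYC", "AP4", "CXCR4", "BLIMP1") %in% rx$species))
  expect_setequal(unique(rx$stoich), c(1, -1))
  p <- tempfile()
  write_reactions(path = p)
  back <- utils::read.table(p, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(rx))
})

test_that("molecular snapshots show the expected signalling structure", {
  sims <- scaled_sims()
  # FOXO1 and AKT are strongly anticorrelated across the LZ population
  lz <- do.call(rbind, lapply(sims, function(sim) {
    sn <- sim$snapshots
    sn[sn$t == best_lz_time(sim) & sn$zone == 1, ]
  }))
  expect_gt(nrow(lz), 15)
  expect_lt(stats::cor(lz$FOXO1, lz$AKT), -0.5)

  # AP4 persists above threshold for at least 1000 mcs after selection
  ok <- 0; tot <- 0
  for (sim in sims) {
    ev <- sim$events
    sn <- sim$snapshots
    sel <- ev[ev$type == "selection", ]
    for (i in seq_len(nrow(sel))) {
      tt <- ceiling((sel$t[i] + 1000) / sim$config$log_every) *
        sim$config$log_every
      row <- sn[sn$id == sel$cell[i] & sn$t == tt, ]
      if (nrow(row)) {
        tot <- tot + 1
        ok <- ok + (row$AP4 >= sim$config$ap4_threshold)
      }
    }
  }
  expect_gt(tot, 50)
  expect_gte(ok / tot, 0.9)

  # high CXCR4 is confined to cycle-committed cells or the brief exit lag
  sn <- sims[[1]]$snapshots
  hi <- sn[sn$CXCR4 >= 100, ]
  expect_gt(mean(hi$cycling), 0.8)
})
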