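test_that("the SHM sampler reproduces its printed probabilities", {
  set.seed(1)
  n <- 1e6
  m <- mutate_bcr(5, n = n)
  # lethal fraction 0.30
  p <- 0.3
  expect_lt(abs(mean(m$lethal) - p), 3 * sqrt(p * (1 - p) / n))
  # non-lethal deltas: symmetric around zero
  d <- m$delta[!m$lethal]
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(length(d)))
  # P(delta = +0.25) = 1/3 * 1/2 = 1/6 among non-lethal draws
  p6 <- 1 / 6
  expect_lt(abs(mean(d == 0.25) - p6),
            3 * sqrt(p6 * (1 - p6) / length(d)))
  # affinity floor at zero, lethal sentinel -1
  low <- mutate_bcr(0.1, n = 1e4)
  expect_gte(min(low$affinity[!low$lethal]), 0)
  expect_true(all(low$affinity[low$lethal] == -1))
})

test_that("division-outcome arithmetic matches the closed forms", {
  probs <- division_outcome_probs(0.3)
  expect_equal(unname(probs), c(0.49, 0.42, 0.09))
  expect_equal(sum(probs), 1)
  # Monte Carlo over paired daughter mutations
  set.seed(2)
  n <- 1e6
  l1 <- mutate_bcr(5, n = n)$lethal
  l2 <- mutate_bcr(5, n = n)$lethal
  both <- mean(!l1 & !l2); one <- mean(xor(l1, l2)); none <- mean(l1 & l2)
  expect_lt(abs(both - 0.49), 3 * sqrt(0.49 * 0.51 / n))
  expect_lt(abs(one - 0.42), 3 * sqrt(0.42 * 0.58 / n))
  expect_lt(abs(none - 0.09), 3 * sqrt(0.09 * 0.91 / n))
})

test_that("growth-threshold arithmetic gives the printed burst-size bounds", {
  expect_equal(round(min_burst_size(0.36), 2), 1.47)
  expect_equal(round(min_burst_size(0.10), 2), 3.32)
  expect_equal(min_burst_size(1), 0)
})

test_that("selection probability is pMHCII-proportional with saturation", {
  expect_equal(selection_probability(5), 0.5)
  expect_equal(selection_probability(10), 1)
  expect_equal(selection_probability(12), 1)
  expect_equal(selection_probability(0), 0)
  expect_equal(selection_probability(-1), 0)

  set.seed(3)
  n <- 1e5
  cell <- list(pmhc = 0.5, timer_on = TRUE, timer = 80, committed = FALSE)
  hits <- sum(replicate(n, tfh_selection(cell)$selected))
  expect_lt(abs(hits / n - 0.5), 3 * sqrt(0.25 / n))
  sure <- list(pmhc = 1); never <- list(pmhc = 0)
  expect_true(all(replicate(100, tfh_selection(sure)$selected)))
  expect_false(any(replicate(100, tfh_selection(never)$selected)))
  expect_error(tfh_selection(list(pmhc = NA)), "pMHCII unset")
})

test_that("selection resets the death timer and commits the cycle", {
  set.seed(4)
  cell <- list(pmhc = 1, timer_on = TRUE, timer = 62, committed = FALSE)
  out <- tfh_selection(cell)
  expect_true(out$selected)
  expect_false(out$timer_on)
  expect_equal(out$timer, 100)
  expect_true(out$committed)
  expect_equal(out$growth_delay, 800)
})

test_that("the death timer decays linearly and partitions causes", {
  cell <- list(timer_on = TRUE, timer = 50 + 1e-9, had_trial = FALSE)
  fired <- update_death_timer(cell, dt = 1)
  expect_true(fired$apoptosis)
  expect_equal(fired$death_cause, "no-Tfh-access")
  cell$had_trial <- TRUE
  expect_equal(update_death_timer(cell, 1)$death_cause,
               "negatively-selected")
  # linear closed form: from 100 at rate r, the threshold is hit at 50/r
  r <- 50 / 1800
  cell <- list(timer_on = TRUE, timer = 100, had_trial = FALSE)
  at_edge <- update_death_timer(cell, dt = 50 / r, rate = r)
  expect_false(at_edge$apoptosis)           # exactly at the boundary
  expect_true(update_death_timer(at_edge, 1, rate = r)$apoptosis)
  # inactive timers never fire
  off <- update_death_timer(list(timer_on = FALSE, timer = 10), 1000)
  expect_false(off$apoptosis)
})

test_that("AP4 gates burst continuation and the brute-force oracle agrees", {
  expect_equal(burst_step(list(ap4 = 49)), "exit-cycle")
  expect_equal(burst_step(list(ap4 = 1000)), "continue-cycling")
  st <- molecular_state(); st["AP4"] <- 50
  expect_equal(burst_step(list(molecular = st)), "continue-cycling")

  # deterministic lineage depth: iterate {grow 500 mcs, divide, decay AP4,
  # test threshold}; the rule-based path must match the explicit oracle
  depth_via_rule <- function(a0) {
    ap4 <- a0; n <- 0
    repeat {
      n <- n + 1                       # guaranteed first division
      ap4 <- ap4 * 2^(-500 / 600)     # AP4 decays over one 500-mcs cycle
      if (burst_step(list(ap4 = ap4)) == "exit-cycle") break
    }
    n
  }
  oracle_depth <- function(a0) {
    # closed form: divisions continue while a0 * 2^(-500 k / 600) >= 50
    1 + max(0, floor(log2(a0 / 50) * 600 / 500 + 1e-12))
  }
  for (a0 in c(51, 90, 150, 320, 700))
    expect_lt(abs(depth_via_rule(a0) - oracle_depth(a0)), 0.1)
})

test_that("plasma-cell differentiation requires the full trigger set", {
  pc_cell <- function(aff, rela = TRUE, blimp = 80, zone = "LZ")
    list(affinity = aff, rela_fired = rela, blimp1 = blimp, zone = zone)
  expect_equal(pc_differentiation(pc_cell(10.25)), "exit-as-PC")
  expect_equal(pc_differentiation(pc_cell(9.75)), "remain")
  expect_equal(pc_differentiation(pc_cell(10.25, rela = FALSE)), "remain")
  expect_equal(pc_differentiation(pc_cell(10.25, blimp = 10)), "remain")
  expect_equal(pc_differentiation(pc_cell(10.25, zone = "DZ")), "remain")
})

test_that("simulated death events carry exactly one cause and PCs are mature", {
  sims <- scaled_sims()
  for (sim in sims) {
    d <- sim$events[sim$events$type == "death", ]
    expect_true(all(d$a1 %in% 1:3))
    dead <- sim$cells[sim$cells$id %in% d$cell, ]
    expect_true(all(dead$death_cause %in%
                      c("lethal-mutation", "negatively-selected",
                        "no-Tfh-access")))
    # every recorded plasma cell is at or above the affinity threshold
    if (nrow(sim$pcs))
      expect_true(all(sim$pcs$affinity >= sim$config$affinity_pc_threshold))
  }
})
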