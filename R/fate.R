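#' Somatic hypermutation of one daughter cell
#'
#' Called once per daughter immediately after cytokinesis. With probability
#' `lethal_prob` (default 0.3) the mutation is damaging and kills the cell in
#' the dark zone. A non-lethal mutation leaves the affinity unchanged with
#' probability 1/3, or moves it by +/- 0.25 or +/- 0.5 (each direction with
#' probability 1/3, each magnitude with probability 1/2, i.e. each non-zero
#' step with probability 1/6). Affinity is floored at 0.
#'
#' @param affinity Current BCR affinity.
#' @param lethal_prob Damaging-mutation probability.
#' @param n Number of independent draws (vectorised for Monte Carlo use).
#' @return data.frame with `lethal`, `delta`, `affinity` (new affinity; -1
#'   sentinel for lethal outcomes).
#' @export
mutate_bcr <- function(affinity, lethal_prob = 0.3, n = 1L) {
  lethal <- stats::runif(n) < lethal_prob
  dir <- sample(c(-1, 0, 1), n, replace = TRUE)
  mag <- sample(c(0.25, 0.5), n, replace = TRUE)
  delta <- dir * mag
  new_aff <- pmax(0, affinity + delta)
  data.frame(lethal = lethal,
             delta = ifelse(lethal, NA_real_, delta),
             affinity = ifelse(lethal, -1, new_aff))
}

#' pMHCII-proportional positive-selection probability
#'
#' The probability that a light-zone B cell in contact with a Tfh cell is
#' positively selected equals its pMHCII level, which is proportional to BCR
#' affinity: `min(affinity / 10, 1)`. An intermediate affinity of 5 gives
#' 50%; affinities at or above 10 give 100%.
#'
#' @param affinity BCR affinity (vectorised).
#' @return Selection probability in `[0, 1]`.
#' @export
selection_probability <- function(affinity) {
  pmin(pmax(affinity, 0) / 10, 1)
}

#' Tfh-contact selection trial
#'
#' One Bernoulli trial with success probability equal to the cell's pMHCII
#' level; at most one trial per continuous Tfh-contact episode. On success
#' the running death timer is terminated and reset, the cell cycle is
#' committed, and DZ re-entry is initiated, with cell growth delayed by
#' `growth_delay` mcs in the first cycle.
#'
#' @param cell List with at least `pmhc` (set by a prior FDC contact),
#'   `timer_on`, `timer`, `committed`.
#' @param growth_delay First-cycle growth delay (mcs), default 800.
#' @param timer_initial Reset value of the death timer.
#' @return The cell with `selected` set, and on success `committed = TRUE`,
#'   `timer_on = FALSE`, `timer = timer_initial`, `growth_delay` recorded.
#' @export
tfh_selection <- function(cell, growth_delay = 800, timer_initial = 100) {
  if (is.null(cell$pmhc) || is.na(cell$pmhc))
    stop("selection trial without a prior FDC contact (pMHCII unset)")
  cell$selected <- stats::runif(1) < cell$pmhc
  if (cell$selected) {
    cell$timer_on <- FALSE
    cell$timer <- timer_initial
    cell$committed <- TRUE
    cell$growth_delay <- growth_delay
  }
  cell
}

#' Advance the death timer
#'
#' The timer starts at `timer_initial` when a cell exits the cell cycle in
#' the dark zone and decays linearly; apoptosis fires when it drops below
#' `threshold`. The death cause is `no-Tfh-access` if the cell never had a
#' selection trial since the timer started, else `negatively-selected`.
#' Firing can occur in either zone.
#'
#' @param cell List with `timer_on`, `timer`, `had_trial`.
#' @param dt Elapsed time (mcs).
#' @param rate Linear decay rate (units/mcs); the default walks the timer
#'   from 100 to the threshold of 50 over 1800 mcs.
#' @param threshold Apoptosis threshold, default 50.
#' @return The cell, with `apoptosis` and (if fired) `death_cause` set.
#' @export
update_death_timer <- function(cell, dt, rate = 50 / 1800, threshold = 50) {
  if (isTRUE(cell$timer_on)) {
    cell$timer <- cell$timer - rate * dt
    if (cell$timer < threshold) {
      cell$apoptosis <- TRUE
      cell$death_cause <- if (isTRUE(cell$had_trial)) "negatively-selected"
                          else "no-Tfh-access"
    } else cell$apoptosis <- FALSE
  } else cell$apoptosis <- FALSE
  cell
}

#' Burst continuation decision after cytokinesis
#'
#' Daughters re-enter growth as long as AP4 stays at or above the threshold;
#' otherwise the cell exits the cycle: the death timer starts, CXCR4
#' downregulation begins after a lag, and the cell migrates to the light
#' zone. Positively selected cells are guaranteed their first division: this
#' decision is only evaluated for daughters.
#'
#' @param cell List with molecular state in `molecular` (named vector) or an
#'   `ap4` entry.
#' @param threshold AP4 threshold, default 50.
#' @return `"continue-cycling"` or `"exit-cycle"`.
#' @export
burst_step <- function(cell, threshold = 50) {
  ap4 <- if (!is.null(cell$ap4)) cell$ap4 else cell$molecular[["AP4"]]
  if (ap4 >= threshold) "continue-cycling" else "exit-cycle"
}

#' Plasma-cell differentiation decision
#'
#' A light-zone B cell whose affinity has reached the plasma-cell threshold
#' (which fires the RelA switch on FDC contact) terminally differentiates
#' once BLIMP1 passes its on-level; the cell is then recorded with its
#' antibody affinity and removed from the simulation.
#'
#' @param cell List with `affinity`, `zone`, `rela_fired`, and `molecular`
#'   (or a `blimp1` entry).
#' @param threshold Affinity threshold, default 10.
#' @param blimp_on BLIMP1 on-level, default 50.
#' @return `"exit-as-PC"` or `"remain"`.
#' @export
pc_differentiation <- function(cell, threshold = 10, blimp_on = 50) {
  blimp <- if (!is.null(cell$blimp1)) cell$blimp1
           else cell$molecular[["BLIMP1"]]
  ok <- cell$affinity >= threshold && isTRUE(cell$rela_fired) &&
    blimp >= blimp_on && identical(cell$zone, "LZ")
  if (ok) "exit-as-PC" else "remain"
}

#' Closed-form division-outcome probabilities
#'
#' With an independent damaging-mutation probability `p` per daughter, one
#' division doubles the B-cell count with probability `(1-p)^2`, keeps it
#' constant with probability `2 p (1-p)`, and eliminates the lineage with
#' probability `p^2`. At the default `p = 0.3` these are 49%, 42% and 9%.
#'
#' @param p Per-daughter lethal-mutation probability.
#' @return Named numeric vector `c(double, hold, eliminate)`.
#' @export
division_outcome_probs <- function(p = 0.3) {
  c(double = (1 - p)^2, hold = 2 * p * (1 - p), eliminate = p^2)
}

#' Minimal mean burst size required for GC growth
#'
#' If a fraction `p` of LZ entrants re-enters the dark zone, the mean number
#' of divisions per burst must exceed `log2(1 / p)` for the population to
#' grow in the absence of DZ death: a re-entry fraction of 0.36 needs 1.47
#' divisions, 0.10 needs 3.32.
#'
#' @param reentry_fraction DZ re-entry probability in `(0, 1]`.
#' @return Minimal mean burst size (divisions).
#' @export
min_burst_size <- function(reentry_fraction) {
  log2(1 / reentry_fraction)
}
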