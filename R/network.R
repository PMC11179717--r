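# Species column order of the molecular state matrix; kept in lock-step with
# the compiled SSA kernel.
.gc_species <- c("CD40", "AKT", "FOXO1", "cRel", "RelA", "MYC", "AP4",
                 "CXCR4", "CXCR5", "BLIMP1", "BclxL", "Casp3")

# Fixed rate-vector order expected by the compiled kernel.
.rate_order <- c("k_cd40", "d_cd40", "k_akt", "d_akt", "k_foxo", "d_foxo",
                 "g_akt", "K_akt", "k_crel", "d_crel", "k_myc", "d_myc",
                 "K_foxo", "k_ap4", "d_ap4", "k_cxcr4", "d_cxcr4", "K_f2",
                 "k_cxcr5", "d_cxcr5", "k_blimp", "d_blimp", "k_bclxl",
                 "d_bclxl", "d_rela", "k_casp", "d_casp", "d_cxcr4_off",
                 "K_myc_ap4")

.rate_vector <- function(rates) {
  missing <- setdiff(.rate_order, names(rates))
  if (length(missing))
    stop("missing rate constant(s): ", paste(missing, collapse = ", "))
  as.numeric(rates[.rate_order])
}

#' Initial molecular state of one B cell
#'
#' All induced species start at zero; FOXO1 and CXCR5 start at their
#' constitutive steady states (about 100 copies). pMHCII and the death timer
#' are carried alongside the copy-number state as continuous variables.
#'
#' @param rates Named rate vector, see [default_rates()].
#' @return Named numeric vector over the 12 network species.
#' @export
molecular_state <- function(rates = default_rates()) {
  s <- stats::setNames(numeric(12), .gc_species)
  s["FOXO1"] <- round(rates[["k_foxo"]] / rates[["d_foxo"]])
  s["CXCR5"] <- round(rates[["k_cxcr5"]] / rates[["d_cxcr5"]])
  s
}

#' Advance the intracellular network of one B cell
#'
#' Exact stochastic simulation (Gillespie's direct method) of the B-cell
#' network for `duration` mcs with the signal inputs held constant. The
#' wiring: BCR signalling on FDC contact produces AKT in proportion to
#' affinity; AKT accelerates FOXO1 turnover; CD40 signalling on Tfh contact
#' (weighted by pMHCII) produces cRel; cRel with low FOXO1 produces MYC;
#' MYC produces AP4, whose long half-life integrates the MYC pulse; FOXO1
#' with cell-cycle commitment produces CXCR4; cRel produces BclxL; CXCR5 is
#' constitutive; every species decays first-order.
#'
#' @param state Named numeric vector from [molecular_state()].
#' @param signals List with logical/numeric entries `fdc_contact`,
#'   `tfh_contact`, `affinity`, `pmhc`, `cxcr4_gate` (cell-cycle commitment
#'   gate), `apoptotic`.
#' @param duration Time to advance (mcs), > 0.
#' @param rates Named rate vector.
#' @return The updated state vector.
#' @export
advance_network <- function(state, signals, duration,
                            rates = default_rates()) {
  if (duration <= 0) stop("duration must be > 0")
  sig <- function(nm, default = 0) {
    v <- signals[[nm]]
    if (is.null(v)) default else as.numeric(v)
  }
  M <- matrix(as.numeric(state[.gc_species]), 1, 12)
  .cpp_ssa_advance(M,
                   aff = sig("affinity"),
                   pmhc = sig("pmhc", 1),
                   fdc = as.integer(sig("fdc_contact") > 0),
                   tfh = as.integer(sig("tfh_contact") > 0),
                   cxcr4_gate = as.integer(sig("cxcr4_gate") > 0),
                   apo = as.integer(sig("apoptotic") > 0),
                   dt = duration, r = .rate_vector(rates))
  stats::setNames(M[1, ], .gc_species)
}

#' Apply an FDC contact to a B cell's state
#'
#' On contact with an FDC in the light zone, the pMHCII level is set
#' proportional to BCR affinity (`min(affinity / 10, 1)`); if affinity is at
#' or above the plasma-cell threshold, the RelA switch fires (set to its high
#' level of 100), which drives BLIMP1 production in the network.
#'
#' @param state Named molecular state vector (with a `pmhc` attribute managed
#'   by the caller) or a list with `molecular` and `pmhc` entries.
#' @param affinity BCR affinity.
#' @param pc_threshold Affinity threshold for the RelA switch, default 10.
#' @return List with `molecular` (state vector), `pmhc`, and `rela_fired`.
#' @export
apply_fdc_contact <- function(state, affinity, pc_threshold = 10) {
  mol <- if (is.list(state)) state$molecular else state
  pmhc <- min(max(affinity, 0) / 10, 1)
  fired <- affinity >= pc_threshold
  if (fired) mol["RelA"] <- 100
  list(molecular = mol, pmhc = pmhc, rela_fired = fired)
}

#' First-order pMHCII downregulation
#'
#' After positive selection or DZ entry, pMHCII decays with a 100-mcs
#' half-life; values below 0.01 are reported as exactly zero, so DZ-resident
#' cells show no pMHCII after roughly 700 mcs.
#'
#' @param pmhc Current pMHCII level in `[0, 1]`.
#' @param dt Elapsed time (mcs).
#' @param halflife Half-life (mcs), default 100.
#' @return Updated pMHCII level.
#' @export
decay_pmhc <- function(pmhc, dt, halflife = 100) {
  out <- pmhc * 2^(-dt / halflife)
  ifelse(out < 0.01, 0, out)
}

#' Reaction list of the B-cell network
#'
#' A serialisable description of the hard-wired reaction set: one row per
#' reaction with its species, stoichiometry, rate-law identifier and
#' parameters. Written/read as tab-separated text so alternate kinetics can
#' be inspected or re-parameterised without touching code.
#'
#' @param rates Named rate vector.
#' @return data.frame with columns `species`, `stoich`, `law`, `params`.
#' @export
network_reactions <- function(rates = default_rates()) {
  r <- function(sp, st, law, ...) {
    p <- c(...)
    data.frame(species = sp, stoich = st, law = law,
               params = paste(sprintf("%s=%g", names(p), unlist(p)),
                              collapse = ","),
               stringsAsFactors = FALSE)
  }
  g <- function(nm) rates[[nm]]
  do.call(rbind, list(
    r("CD40", +1, "tfh_pmhc", k = g("k_cd40")),
    r("CD40", -1, "linear", d = g("d_cd40")),
    r("AKT", +1, "fdc_bcr", k = g("k_akt")),
    r("AKT", -1, "linear", d = g("d_akt")),
    r("FOXO1", +1, "constant", k = g("k_foxo")),
    r("FOXO1", -1, "akt_boosted", d = g("d_foxo"), g = g("g_akt"),
      K = g("K_akt")),
    r("cRel", +1, "driven_by_CD40", k = g("k_crel")),
    r("cRel", -1, "linear", d = g("d_crel")),
    r("RelA", -1, "linear", d = g("d_rela")),
    r("MYC", +1, "crel_and_low_foxo1", k = g("k_myc"), K = g("K_foxo")),
    r("MYC", -1, "linear", d = g("d_myc")),
    r("AP4", +1, "driven_by_MYC", k = g("k_ap4")),
    r("AP4", -1, "linear", d = g("d_ap4")),
    r("CXCR4", +1, "foxo1_gated_commit", k = g("k_cxcr4"), K = g("K_f2")),
    r("CXCR4", -1, "linear", d = g("d_cxcr4")),
    r("CXCR5", +1, "constant", k = g("k_cxcr5")),
    r("CXCR5", -1, "linear", d = g("d_cxcr5")),
    r("BLIMP1", +1, "driven_by_RelA", k = g("k_blimp")),
    r("BLIMP1", -1, "linear", d = g("d_blimp")),
    r("BclxL", +1, "driven_by_cRel", k = g("k_bclxl")),
    r("BclxL", -1, "linear", d = g("d_bclxl")),
    r("Casp3", +1, "apoptotic_flag", k = g("k_casp")),
    r("Casp3", -1, "linear", d = g("d_casp"))))
}

#' @rdname network_reactions
#' @param path File path for the tab-separated reaction list.
#' @export
write_reactions <- function(rates = default_rates(), path) {
  utils::write.table(network_reactions(rates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
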