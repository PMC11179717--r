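---
title: "A multiscale Potts-model germinal center: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale Potts-model germinal center}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcpotts)
```

## The model

`gcpotts` simulates a germinal center (GC) as three coupled layers.

**Tissue.** A 2-D lattice (default 250 x 200 pixels, about 1 um per pixel)
split at the midline into a dark zone (DZ, left) and light zone (LZ, right).
Stationary cells occupy fixed 5 x 5 footprints: CXCL12-expressing reticular
cells (CRCs) scattered over the DZ, follicular dendritic cells (FDCs) over
the LZ interior, and T follicular helper (Tfh) cells placed within a
2-pixel ring of randomly chosen FDCs, so that some FDCs have no adjacent
Tfh — Tfh availability is the limiting resource for positive selection.
CRCs secrete CXCL12 and FDCs secrete CXCL13; both fields obey forward-Euler
secretion-diffusion-decay with zero-flux boundaries, are equilibrated
before the cellular dynamics start, rescaled to a peak concentration of 1,
and then frozen (the sources are stationary, so the gradients are
quasi-static; a live-update mode exists via `freeze_fields = FALSE`).

**Cells.** B cells are multi-pixel agents of a Cellular Potts Model. Each
Monte Carlo step (mcs, roughly 1/100 hour) attempts one pixel copy per
lattice site; a copy changes the Hamiltonian by a contact-energy term, a
volume-constraint term `lambda_vol * (v - V_target)^2`, and a chemotaxis
term for the invading B cell, and is accepted with probability
`min(1, exp(-dH / T))`. Chemotaxis is saturable (log-sensing):
`dH_chem = -lambda * (c_target - c_source) / (K_sat + c_source)`, which
keeps the bias roughly uniform across an exponentially decaying field. The
CXCL13 response is constitutive (CXCR5); the CXCL12 response scales with
the cell's current CXCR4 copy number, coupling motion to the molecular
layer. Stationary-cell pixels never move, and a copy that would remove a
cell's last pixel is rejected (a crowded Potts lattice can otherwise make
small dividing cells vanish; we prevent it and count the rejections).

**Molecules.** Every B cell carries a stochastic reaction network (CD40,
AKT, FOXO1, cRel, RelA, MYC, AP4, CXCR4, CXCR5, BLIMP1, Bcl-xL, caspase-3)
advanced one mcs at a time with Gillespie's direct method, with contact
signals held constant within each window. The wiring: antigen capture at an
FDC sets pMHCII proportional to BCR affinity (`min(affinity/10, 1)`) and
drives AKT, which accelerates FOXO1 turnover; CD40 engagement at a Tfh cell
(scaled by pMHCII) drives cRel; cRel with FOXO1 low induces a MYC pulse;
AP4, with a 600-mcs half-life against MYC's 50, integrates the pulse and
sustains the proliferative burst; FOXO1 recovery plus cell-cycle commitment
gates CXCR4; RelA switches on (rule-based) when affinity reaches 10 and
drives BLIMP1.

**Fates.** A Tfh contact of an antigen-armed LZ cell triggers one Bernoulli
selection trial per contact episode with success probability pMHCII.
Selection cancels the death timer, commits the cell cycle, and delays
growth by 800 mcs so the first division completes after DZ re-entry. Growth
doubles the target volume linearly over 500 mcs; cytokinesis fires once the
ramp completes and the volume reaches 90% of the doubled target, so cycle
lengths are targeted as a constant (subsequent cycles ~500-580 mcs, first
cycles ~1300-1500 mcs). Each daughter mutates independently: lethal with
probability 0.3 (affinity set to the sentinel -1, caspase-3 induced, death
30 mcs later), otherwise the affinity steps by 0, +/-0.25 or +/-0.5 with
probabilities 1/3, 1/6 each, floored at 0. Daughters keep cycling while AP4
is at or above 50; below it they exit, start the death timer (100, linear
decay, apoptosis below 50 after 1800 mcs if never rescued) and return to
the LZ. Cells whose affinity reaches 10 become plasma cells once BLIMP1
passes 50 in the LZ and are removed and logged.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `lethal_mut_prob` | 0.3 | — | per-daughter damaging-mutation probability; fixes the 49/42/9% division outcomes |
| `ap4_threshold` | 50 | copies | burst-termination threshold |
| `timer_initial` / `timer_threshold` / `timer_span` | 100 / 50 / 1800 | — / — / mcs | death-timer start, firing level, and time-to-threshold; only the threshold 50 is anchored, the span is our calibration of LZ dwell |
| `growth_delay_first_cycle` | 800 | mcs | keeps first cytokinesis out of the LZ |
| `volume_doubling_time` | 500 | mcs | sets the ~6 h subsequent cycle |
| `lambda_cxcl12` / `lambda_cxcl13` | 4800 / 1200 | energy | CXCR4-weighted DZ pull must dominate the constitutive CXCR5 pull for returning cells |
| `chem_decay` | 5e-4 | 1/mcs | decay length ~45 px so each gradient spans its hemisphere |
| `k_myc`, `k_ap4`, `K_myc_ap4` | 28, 1.85, 100 | per mcs / copies | size of the selection-triggered MYC pulse and its (saturable) AP4 integral; these set mean burst size (~2.2) and its 1-6 range |
| `d_cxcr4_off` | ln2/25 | 1/mcs | active CXCR4 downregulation after cycle exit; without it cells linger in the DZ |

None of the kinetic constants are measured quantities; they were chosen
once so that the emergent statistics (burst size, cycle lengths, LZ
residence, migration legs) sit near published germinal-center values, and
are not meant to be tuned per run.

## Design choices in genuinely open territory

- **Persistent BCR signal while armed.** Antigen capture is modelled as
  arming the cell (pMHCII set) with BCR/AKT signalling active until
  selection or pMHCII decay, rather than only during literal pixel contact
  with an FDC. Contact episodes in a Potts model are short and erratic;
  arming keeps FOXO1 low while the cell seeks a Tfh, which is what makes
  the CD40-cRel-MYC axis fire on selection. Similarly CD40 signalling runs
  as a fixed 150-mcs episode from the moment of selection, emulating the
  prolonged B-Tfh entanglement.
- **Seeders.** Placed as 4 x 4 blocks on jittered slots in a +/-20-pixel
  band around the midline (they grow to the 30-pixel target volume within
  the first ~100 mcs); they start with an active death timer, since
  apoptosis is the default fate of any cell that is never positively
  selected.
- **Division.** Pixels are split by a random plane through the centroid;
  daughter 1's volume fraction is `L/(1+L)` with `L ~ lognormal(0, 0.2)`
  (the spread parameter is unreported; 0.2 gives mild asymmetry). The
  parent id retires and two birth events are logged per division.
- **2-D tissue.** The GC slice is modelled as a single lattice layer; a
  thin-3D slab (~11 µm) would itself only be a computational economy
  relative to a real GC's 20-50 µm thickness, and none of the tracked
  statistics depend on the z extent. `grid_z` is carried in the
  configuration for forward compatibility.
- **One RNG stream.** All randomness (placement, Potts dynamics, SSA, fate
  draws) flows from one seeded stream; runs are bit-reproducible given
  `(config, seed)` because the per-mcs schedule is deterministic.

## Numerical choices

Diffusion uses dt = 0.2 mcs against the 2-D stability bound h^2/(4D) =
0.25; equilibration stops when the relative change per 100 mcs falls below
1e-5. SSA propensities are guarded against 0/0 in the saturation terms
(defined as 0) and any non-finite propensity raises an error. Cytokinesis
candidates are processed in random order each mcs. Percentiles use linear
interpolation; affinity bins are left-closed `[a, b)` with the 9-10 bin
reported separately rather than silently dropped. Cells still cycling at
run end leave their burst open; open bursts are excluded from burst
statistics, and LZ entrants with incomplete trips are reported as
still-in-LZ.

## Problem sizes

Routine runs and the bundled checks use a desk-scale condition: a 125 x 100
field with 50 seeder B cells and stationary-cell counts scaled by area
(11 CRC, 11 FDC, 9 Tfh), run for 15,000 mcs over three seeds. At this scale
the population turns over through hundreds of selection-burst episodes while
a run stays near a minute. The full-scale condition (250 x 200, 200
seeders, 72,000 mcs) is exercised by `scripts/fullscale.R`, which wraps the
long-running test in `tests/longtests/`.

## What the desk-scale condition does and does not show

The scaled runs preserve the per-cell program — selection probabilities,
cycle timing, burst termination, death causes — so cycle lengths and burst
sizes transfer to full scale; they were indeed calibrated against the
reference values at this scale. They do not reproduce crowding phenomena: a
population of tens to low hundreds leaves Tfh access largely uncontested,
so the realized selected fraction of LZ entrants (~0.5-0.7) is above the
~0.37 expected of a crowded, mature GC, and the return leg T_LD does not
yet exceed the outbound leg T_DL as it does in a packed GC. Those
statistics are checked only in the long test. Nothing here is real data:
affinity is a scalar, antigen is never depleted, memory B cells and
cytokine fields are out of scope, so agreement with the target statistics
validates the implementation, not the biology.

## Known limitations

Cell fragments are not forced to stay connected (standard Potts behaviour);
fragmentation is possible at extreme chemotaxis strengths. The frozen-field
default ignores chemokine consumption and any feedback of cell density on
the gradients. The death timer uses linear decay; only its firing threshold is anchored,
not the decay law. Affinity-dependent S-phase
shortening and asymmetric pMHCII segregation are deliberately not modelled.

## A quick run

```{r quickrun, eval = FALSE}
cfg <- scale_config(gc_config(), grid_x = 125, grid_y = 100, n_seeder = 50)
sim <- simulate_gc(cfg, seed = 1, t_end = 15000)
bs <- compute_burst_stats(sim)
mean(bs$bursts$size)
gc_summary(sim)
```
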