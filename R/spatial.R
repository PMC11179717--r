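#' Construct a Potts lattice from a tissue layout
#'
#' Paints every cell's pixel footprint onto an integer owner matrix (0 =
#' medium) and initialises the per-cell bookkeeping used by the Metropolis
#' dynamics: pixel counts, target volumes, type codes and the contact-energy
#' matrix.
#'
#' Type codes: 0 medium, 1 B cell, 2 CRC, 3 FDC, 4 Tfh.
#'
#' @param layout A [build_layout()] result.
#' @return A `gc_lattice`: list with `lat` (owner matrix), `vol`, `tvol`,
#'   `typecode` (per-id vectors), `J`, `temperature`, `lambda_vol`, `config`.
#' @export
gc_lattice <- function(layout) {
  cfg <- layout$config
  lat <- matrix(0L, cfg$grid_x, cfg$grid_y)
  n <- nrow(layout$cells)
  typecode <- integer(n); vol <- integer(n); tvol <- numeric(n)
  code <- c(B = 1L, CRC = 2L, FDC = 3L, TFH = 4L)
  for (i in seq_len(n)) {
    id <- layout$cells$id[i]
    px <- layout$pixels[[id]]
    lat[cbind(px[, 1], px[, 2])] <- id
    typecode[id] <- code[[layout$cells$type[i]]]
    vol[id] <- nrow(px)
    tvol[id] <- if (typecode[id] == 1L) cfg$target_volume else nrow(px)
  }
  structure(list(lat = lat, vol = vol, tvol = tvol, typecode = typecode,
                 J = contact_energy_matrix(cfg),
                 temperature = cfg$temperature, lambda_vol = cfg$lambda_vol,
                 config = cfg),
            class = "gc_lattice")
}

#' Contact-energy matrix indexed by type code (medium, B, CRC, FDC, Tfh)
#' @param config A [gc_config()].
#' @return 5 x 5 numeric matrix.
#' @export
contact_energy_matrix <- function(config) {
  J <- matrix(0, 5, 5)
  J[1, 2] <- J[2, 1] <- config$j_bm          # B - medium
  J[2, 2] <- config$j_bb                     # B - B
  J[2, 3:5] <- J[3:5, 2] <- config$j_bs      # B - stromal
  J
}

#' One Monte Carlo step of the Cellular Potts dynamics
#'
#' Performs as many random pixel-copy attempts as there are lattice sites.
#' Each attempt proposes copying the owner of a random pixel into a random
#' 8-neighbour and accepts with probability `min(1, exp(-dH / T))`, where
#' `dH` sums contact-energy, volume-constraint and chemotaxis terms (the
#' invading B cell is biased up its CXCL12 gradient in proportion to its
#' CXCR4 level and up its CXCL13 gradient through constitutive CXCR5).
#' Stationary-cell pixels never move, and copies that would annihilate a
#' cell's last pixel are rejected.
#'
#' @param lattice A [gc_lattice()].
#' @param fields List with `cxcl12` and `cxcl13` [chemokine_field()]s.
#' @param lam12,lam13 Per-cell chemotaxis strengths, indexed by cell id;
#'   defaults put full-strength CXCR5 taxis and no CXCR4 taxis on every B
#'   cell.
#' @param nsteps Number of Monte Carlo steps to run.
#' @return The updated lattice (invisibly also reports the acceptance count
#'   in attribute `"accepted"`).
#' @export
mcs_step <- function(lattice, fields, lam12 = NULL, lam13 = NULL,
                     nsteps = 1L) {
  nid <- length(lattice$vol)
  if (is.null(lam12)) lam12 <- numeric(nid)
  if (is.null(lam13))
    lam13 <- ifelse(lattice$typecode == 1L, lattice$config$lambda_cxcl13, 0)
  lat <- lattice$lat + 0L
  vol <- lattice$vol + 0L
  acc <- 0
  for (i in seq_len(nsteps)) {
    res <- .cpp_cpm_sweep(lat, vol, lattice$tvol, lattice$typecode,
                          lam12, lam13,
                          fields$cxcl12$conc, fields$cxcl13$conc,
                          lattice$J, lattice$temperature,
                          lattice$lambda_vol, length(lat),
                          lattice$config$chem_sat, lattice$config$chem_sat)
    acc <- acc + res$accepted
  }
  lattice$lat <- lat
  lattice$vol <- vol
  attr(lattice, "accepted") <- acc
  lattice
}

#' Linear target-volume growth
#'
#' Growing cells double their target volume over `doubling_time` mcs via a
#' linear ramp of `V0 / doubling_time` pixels per mcs, capped at `2 V0`.
#'
#' @param geom List with `target_volume` and `v0` (the phase-entry volume).
#' @param dt Elapsed time (mcs).
#' @param doubling_time Volume doubling time (mcs), default 500.
#' @return The updated geometry.
#' @export
grow_cell <- function(geom, dt, doubling_time = 500) {
  geom$target_volume <- min(2 * geom$v0,
                            geom$target_volume + geom$v0 * dt / doubling_time)
  geom
}

#' Partition a cell's pixels into two daughter masses
#'
#' Pixels are split by a plane through the centroid with uniform random
#' orientation; the volume fraction of daughter 1 is `f = L / (1 + L)` with
#' `L ~ lognormal(0, sigma)`, so splits are symmetric on average with mild
#' asymmetry.
#'
#' @param px 2-column pixel matrix.
#' @param sigma Lognormal sigma of the volume-split ratio.
#' @return Logical vector: `TRUE` marks daughter-1 pixels.
#' @export
split_pixels <- function(px, sigma = 0.2) {
  n <- nrow(px)
  if (n < 2) stop("cannot divide a cell with fewer than 2 pixels")
  f <- stats::rlnorm(1, 0, sigma)
  f <- f / (1 + f)
  theta <- stats::runif(1, 0, pi)
  proj <- px[, 1] * cos(theta) + px[, 2] * sin(theta)
  k <- max(1L, min(n - 1L, round(f * n)))
  rank(proj, ties.method = "first") <= k
}

#' Divide a cell on the lattice
#'
#' Splits the pixels of `cell_id` into two daughters (see [split_pixels()]),
#' assigns two fresh ids, and retires the parent id. Two birth events are
#' implied by each division; the caller records them.
#'
#' @param lattice A [gc_lattice()].
#' @param cell_id Id of the dividing cell.
#' @param sigma Volume-split lognormal sigma.
#' @return List with `lattice`, `daughters` (the two new ids).
#' @export
divide_cell <- function(lattice, cell_id, sigma = 0.2) {
  px <- which(lattice$lat == cell_id, arr.ind = TRUE)
  d1 <- split_pixels(px, sigma)
  id1 <- length(lattice$vol) + 1L
  id2 <- id1 + 1L
  lattice$vol <- c(lattice$vol, sum(d1), sum(!d1))
  lattice$tvol <- c(lattice$tvol, rep(lattice$config$target_volume, 2))
  lattice$typecode <- c(lattice$typecode, 1L, 1L)
  lattice$lat[px[d1, , drop = FALSE]] <- id1
  lattice$lat[px[!d1, , drop = FALSE]] <- id2
  lattice$vol[cell_id] <- 0L
  lattice
  list(lattice = lattice, daughters = c(id1, id2))
}

#' Neighbouring cells of a cell
#'
#' All distinct cells sharing a 4-neighbourhood pixel boundary with
#' `cell_id`.
#'
#' @param lattice A [gc_lattice()].
#' @param cell_id Cell id.
#' @return data.frame with columns `neighbor_id` and `neighbor_type`.
#' @export
contacts_of <- function(lattice, cell_id) {
  if (cell_id < 1 || cell_id > length(lattice$vol) ||
      lattice$vol[cell_id] == 0)
    stop("unknown or dead cell id: ", cell_id)
  scan <- .cpp_lattice_scan(lattice$lat, length(lattice$vol))
  a <- scan$pair_a; b <- scan$pair_b
  nb <- c(b[a == cell_id], a[b == cell_id])
  types <- c("B", "CRC", "FDC", "TFH")[lattice$typecode[nb]]
  data.frame(neighbor_id = nb, neighbor_type = types,
             stringsAsFactors = FALSE)
}

#' Per-cell centroids and pixel counts
#'
#' @param lattice A [gc_lattice()].
#' @return data.frame with `id`, `count`, `cx`, `cy` for live ids.
#' @export
lattice_cells <- function(lattice) {
  scan <- .cpp_lattice_scan(lattice$lat, length(lattice$vol))
  keep <- scan$count > 0
  data.frame(id = which(keep), count = scan$count[keep],
             cx = scan$cx[keep], cy = scan$cy[keep])
}
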