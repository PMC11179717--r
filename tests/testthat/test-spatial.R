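# hand-built single/multi-cell lattices for engine tests
bare_lattice <- function(cfg, painter) {
  lat <- matrix(0L, cfg$grid_x, cfg$grid_y)
  info <- painter(lat)
  structure(list(lat = info$lat, vol = info$vol,
                 tvol = info$tvol, typecode = info$typecode,
                 J = contact_energy_matrix(cfg),
                 temperature = cfg$temperature, lambda_vol = cfg$lambda_vol,
                 config = cfg),
            class = "gc_lattice")
}

zero_fields <- function(cfg) {
  list(cxcl12 = chemokine_field("CXCL12", c(cfg$grid_x, cfg$grid_y)),
       cxcl13 = chemokine_field("CXCL13", c(cfg$grid_x, cfg$grid_y)))
}

one_cell_lattice <- function(cfg, x0 = 20, y0 = 20) {
  bare_lattice(cfg, function(lat) {
    lat[x0:(x0 + 4), y0:(y0 + 5)] <- 1L
    list(lat = lat, vol = 30L, tvol = cfg$target_volume, typecode = 1L)
  })
}

test_that("Metropolis acceptance matches the closed form", {
  set.seed(1)
  # favourable flips always accepted in the T -> 0+ limit
  expect_equal(gcpotts:::.cpp_metropolis_trials(-1, 1e-12, 1e4), 1e4)
  # dH = 2, T = 1: acceptance within 3 sigma of exp(-2)
  n <- 1e5
  p <- exp(-2)
  acc <- gcpotts:::.cpp_metropolis_trials(2, 1, n)
  expect_lt(abs(acc / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the volume constraint holds a cell near its target volume", {
  cfg <- gc_config(grid_x = 40, grid_y = 40)
  lt <- one_cell_lattice(cfg)
  flds <- zero_fields(cfg)
  set.seed(2)
  vols <- numeric(0)
  for (i in 1:100) {
    lt <- mcs_step(lt, flds, nsteps = 20L)
    vols <- c(vols, lt$vol[1])
  }
  expect_lt(abs(mean(vols) - cfg$target_volume) / cfg$target_volume, 0.10)
  expect_gte(min(lt$vol[1]), 1)
})

test_that("pixels are conserved and cells never vanish during sweeps", {
  lay <- build_layout(small_config(), seed = 9)
  lt <- gc_lattice(lay)
  flds <- zero_fields(small_config())
  n_cell0 <- sum(lt$lat > 0)
  set.seed(3)
  lt <- mcs_step(lt, flds, nsteps = 200L)
  expect_equal(sum(lt$vol), sum(lt$lat > 0))
  expect_equal(length(lt$lat), sum(lt$lat > 0) + sum(lt$lat == 0))
  expect_true(all(lt$vol >= 1))
  # stationary cells kept their exact footprints
  stat <- which(lt$typecode >= 2)
  expect_equal(lt$vol[stat], rep(25L, length(stat)))
})

test_that("a field-free cell shows no systematic drift", {
  cfg <- gc_config(grid_x = 60, grid_y = 60)
  flds <- zero_fields(cfg)
  set.seed(4)
  disp <- replicate(20, {
    lt <- one_cell_lattice(cfg, 28, 27)
    x0 <- lattice_cells(lt)$cx
    lt <- mcs_step(lt, flds, nsteps = 600L)
    lattice_cells(lt)$cx - x0
  })
  se <- stats::sd(disp) / sqrt(length(disp))
  expect_lt(abs(mean(disp)), 3 * se + 1e-9)
})

test_that("chemotaxis pulls lone cells toward their attractant", {
  cfg <- scaled_config()
  lay <- build_layout(cfg, seed = 2)
  flds <- fields_from_layout(lay)
  nid <- 1L
  run_one <- function(lam12, lam13, x0) {
    lt <- one_cell_lattice(cfg, x0, 48)
    lt <- mcs_step(lt, flds, lam12 = lam12, lam13 = lam13, nsteps = 800L)
    lattice_cells(lt)$cx
  }
  set.seed(5)
  # CXCR5-driven: toward the LZ (x increases)
  right <- replicate(20, run_one(0, cfg$lambda_cxcl13, 30) > 30 + 5)
  expect_gte(sum(right), 18)
  # CXCR4-driven: toward the DZ (x decreases) against constitutive CXCR5
  left <- replicate(20, run_one(cfg$lambda_cxcl12, cfg$lambda_cxcl13, 95) <
                      95 - 5)
  expect_gte(sum(left), 18)
})

test_that("cell growth follows the linear doubling ramp", {
  g <- list(target_volume = 30, v0 = 30)
  expect_equal(grow_cell(g, 500)$target_volume, 60)
  expect_equal(grow_cell(g, 0)$target_volume, 30)
  expect_equal(grow_cell(g, 250)$target_volume, 45)
  # capped at the doubled volume
  expect_equal(grow_cell(g, 2000)$target_volume, 60)
})

test_that("division partitions pixels and splits volume symmetrically", {
  cfg <- gc_config(grid_x = 40, grid_y = 40)
  lt <- bare_lattice(cfg, function(lat) {
    lat[11:20, 11:20] <- 1L  # 100-pixel cell
    list(lat = lat, vol = 100L, tvol = 100, typecode = 1L)
  })
  set.seed(6)
  res <- divide_cell(lt, 1L)
  expect_equal(sum(res$lattice$vol[res$daughters]), 100)
  expect_equal(res$lattice$vol[1], 0)

  # minimal 2-pixel case
  lt2 <- bare_lattice(cfg, function(lat) {
    lat[5, 5:6] <- 1L
    list(lat = lat, vol = 2L, tvol = 2, typecode = 1L)
  })
  res2 <- divide_cell(lt2, 1L)
  expect_equal(sort(res2$lattice$vol[res2$daughters]), c(1L, 1L))
  expect_error(split_pixels(matrix(c(1, 1), 1, 2)), "fewer than 2")

  # Monte-Carlo check of the lognormal volume split around 1/2
  set.seed(7)
  px <- which(matrix(TRUE, 10, 10), arr.ind = TRUE)
  fr <- replicate(1e4, mean(split_pixels(px, sigma = 0.2)))
  expect_lt(abs(mean(fr) - 0.5), 3 * stats::sd(fr) / sqrt(length(fr)))
})

test_that("contacts are symmetric, typed, and empty for isolated cells", {
  cfg <- gc_config(grid_x = 30, grid_y = 30)
  lt <- bare_lattice(cfg, function(lat) {
    lat[5:8, 5:8] <- 1L      # B cell
    lat[9:12, 5:8] <- 2L     # flush B cell
    lat[20:24, 20:24] <- 3L  # isolated FDC footprint
    lat[5:8, 9:12] <- 4L     # FDC flush against cell 1
    list(lat = lat, vol = c(16L, 16L, 25L, 16L),
         tvol = c(16, 16, 25, 16), typecode = c(1L, 1L, 3L, 3L))
  })
  c1 <- contacts_of(lt, 1L)
  expect_setequal(c1$neighbor_id, c(2L, 4L))
  expect_true("FDC" %in% c1$neighbor_type)
  expect_true(1L %in% contacts_of(lt, 2L)$neighbor_id)
  expect_equal(nrow(contacts_of(lt, 3L)), 0)
  expect_error(contacts_of(lt, 99L), "unknown or dead")
})
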