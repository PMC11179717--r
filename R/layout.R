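#' Generate the initial tissue layout
#'
#' Places the stationary cells and seeder B cells on the lattice: CRCs are
#' scattered over the left half of the field (the future dark zone), FDCs over
#' the right half (the future light zone) starting `fdc_min_offset` pixels
#' past the midline, each Tfh cell is placed within a 2-pixel ring of a
#' uniformly chosen FDC, and seeder B cells occupy a band of half-width
#' `seeder_band` around the midline. Stationary cells have fixed square
#' footprints and never move; seeders start as 4 x 4 blocks and grow to their
#' target volume once the Potts dynamics run.
#'
#' Layout generation is a pure function of `(config, seed)`.
#'
#' @param config A [gc_config()].
#' @param seed Integer seed for the placement random stream; defaults to
#'   `config$rng_seed`.
#' @return A `gc_layout`: list with `cells` (data.frame: id, type, cx, cy,
#'   affinity, clone) and `pixels` (list of 2-column pixel matrices per cell).
#' @export
build_layout <- function(config, seed = config$rng_seed) {
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  gx <- config$grid_x; gy <- config$grid_y
  mid <- config$midline_x
  fp <- config$stromal_footprint
  h <- fp %/% 2
  occ <- matrix(FALSE, gx, gy)

  cells <- list(); pixels <- list(); id <- 0L

  claim <- function(x0, x1, y0, y1) {
    if (x0 < 1 || y0 < 1 || x1 > gx || y1 > gy) return(NULL)
    if (any(occ[x0:x1, y0:y1])) return(NULL)
    occ[x0:x1, y0:y1] <<- TRUE
    as.matrix(expand.grid(x = x0:x1, y = y0:y1))
  }
  place_square <- function(type, xlo, xhi, ylo = 1 + h, yhi = gy - h,
                           tries = 4000L) {
    for (i in seq_len(tries)) {
      cx <- sample(seq.int(ceiling(xlo), floor(xhi)), 1L)
      cy <- sample(seq.int(ylo, yhi), 1L)
      px <- claim(cx - h, cx + h, cy - h, cy + h)
      if (!is.null(px)) {
        id <<- id + 1L
        cells[[id]] <<- data.frame(id = id, type = type,
                                   cx = cx, cy = cy,
                                   affinity = NA_real_, clone = NA_integer_)
        pixels[[id]] <<- px
        return(invisible(TRUE))
      }
    }
    stop(sprintf("could not place a %s cell without overlap on a %dx%d grid",
                 type, gx, gy))
  }

  # CRCs: left half, centroid strictly in the DZ
  for (i in seq_len(config$n_crc))
    place_square("CRC", 1 + h, mid - h - 1)

  # FDCs: right half, offset into the LZ
  fdc_ids <- integer(0)
  for (i in seq_len(config$n_fdc)) {
    place_square("FDC", max(mid + h + 1, mid + config$fdc_min_offset),
                 gx - h)
    fdc_ids <- c(fdc_ids, id)
  }

  # Tfh cells: within a 2-pixel ring of a uniformly chosen FDC
  for (i in seq_len(config$n_tfh)) {
    placed <- FALSE
    for (try in seq_len(4000L)) {
      f <- cells[[sample(fdc_ids, 1L)]]
      gap <- sample(0:2, 1L)
      d <- fp + gap  # center-to-center Chebyshev distance
      side <- sample(1:4, 1L)
      off <- sample(seq.int(-d, d), 1L)
      dxy <- switch(side, c(d, off), c(-d, off), c(off, d), c(off, -d))
      cx <- f$cx + dxy[1]; cy <- f$cy + dxy[2]
      if (cx - h <= mid) next  # keep the Tfh centroid in the LZ
      px <- claim(cx - h, cx + h, cy - h, cy + h)
      if (!is.null(px)) {
        id <- id + 1L
        cells[[id]] <- data.frame(id = id, type = "TFH", cx = cx, cy = cy,
                                  affinity = NA_real_, clone = NA_integer_)
        pixels[[id]] <- px
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place a TFH cell adjacent to an FDC without overlap")
  }

  # Seeder B cells: jittered slots in the band around the midline so high
  # packing densities remain feasible
  if (config$n_seeder > 0) {
    half <- config$seeder_band
    x0 <- max(1, ceiling(mid - half)); x1 <- min(gx, floor(mid + half))
    slot <- 5L
    sx <- seq.int(x0, x1 - slot + 1L, by = slot)
    sy <- seq.int(1L, gy - slot + 1L, by = slot)
    slots <- as.matrix(expand.grid(sx = sx, sy = sy))
    free <- vapply(seq_len(nrow(slots)), function(i) {
      !any(occ[slots[i, 1] + 0:(slot - 1), slots[i, 2] + 0:(slot - 1)])
    }, logical(1))
    slots <- slots[free, , drop = FALSE]
    if (nrow(slots) < config$n_seeder)
      stop(sprintf(
        "cannot place %d seeder B cells in the midline band (%d free slots)",
        config$n_seeder, nrow(slots)))
    pick <- slots[sample.int(nrow(slots), config$n_seeder), , drop = FALSE]
    affs <- switch(config$seeder_affinity_mode,
                   "constant-5" = rep(5, config$n_seeder),
                   "uniform-3-7" = stats::runif(config$n_seeder, 3, 7))
    for (i in seq_len(config$n_seeder)) {
      jx <- pick[i, 1] + sample(0:1, 1L); jy <- pick[i, 2] + sample(0:1, 1L)
      px <- claim(jx, jx + 3L, jy, jy + 3L)  # 4 x 4 starting footprint
      if (is.null(px)) px <- claim(pick[i, 1], pick[i, 1] + 3L,
                                   pick[i, 2], pick[i, 2] + 3L)
      id <- id + 1L
      cells[[id]] <- data.frame(id = id, type = "B",
                                cx = mean(px[, 1]), cy = mean(px[, 2]),
                                affinity = affs[i], clone = i)
      pixels[[id]] <- px
    }
  }

  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(id = integer(), type = character(), cx = numeric(),
               cy = numeric(), affinity = numeric(), clone = integer())
  structure(list(config = config, cells = cells, pixels = pixels),
            class = "gc_layout")
}

#' @export
print.gc_layout <- function(x, ...) {
  tab <- table(x$cells$type)
  cat("<gc_layout>", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Export / import a layout as a pixel-map text file
#'
#' One tab-separated row per pixel: `id`, `type`, `x`, `y` — a plain-text
#' Potts initialisation format.
#'
#' @param layout A `gc_layout`.
#' @param path File path.
#' @return `write_pif` returns `path` invisibly; `read_pif` returns a
#'   data.frame of pixels.
#' @export
write_pif <- function(layout, path) {
  rows <- lapply(seq_len(nrow(layout$cells)), function(i) {
    px <- layout$pixels[[layout$cells$id[i]]]
    data.frame(id = layout$cells$id[i], type = layout$cells$type[i],
               x = px[, 1], y = px[, 2])
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pif
#' @export
read_pif <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# save/restore the global RNG state so layout generation does not disturb
# the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
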