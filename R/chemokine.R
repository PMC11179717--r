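#' Chemokine concentration field
#'
#' A scalar concentration lattice for one ligand (CXCL12, secreted by CRCs in
#' the dark zone, or CXCL13, secreted by FDCs in the light zone), evolved by
#' forward-Euler secretion-diffusion-decay with zero-flux boundaries.
#'
#' @param ligand `"CXCL12"` or `"CXCL13"`.
#' @param dim Integer vector `c(grid_x, grid_y)`.
#' @param D Diffusion coefficient (pixels^2 / mcs).
#' @param decay First-order decay rate (1/mcs).
#' @param secretion Secretion rate per source pixel (units/mcs).
#' @return A `chemokine_field` object.
#' @export
chemokine_field <- function(ligand = c("CXCL12", "CXCL13"), dim,
                            D = 1, decay = 0.01, secretion = 0.02) {
  ligand <- match.arg(ligand)
  structure(list(ligand = ligand,
                 conc = matrix(0, dim[1], dim[2]),
                 D = D, decay = decay, secretion = secretion),
            class = "chemokine_field")
}

#' Advance a chemokine field
#'
#' Forward-Euler update `c <- c + dt * (D * lap(c) - k * c + s * 1[source])`
#' with zero-flux (Neumann) boundaries. The time step must satisfy the 2-D
#' explicit-scheme stability bound `dt <= h^2 / (4 D)` (h = 1 pixel).
#'
#' @param field A [chemokine_field()].
#' @param source_pixels 2-column matrix of (x, y) source pixels, or `NULL`.
#' @param dt Time step (mcs); `steps` substeps of length `dt` are taken.
#' @param steps Number of substeps.
#' @return The updated field.
#' @export
step_field <- function(field, source_pixels, dt, steps = 1L) {
  if (dt > 1 / (4 * field$D) + 1e-12)
    stop(sprintf("dt = %g violates the stability bound h^2/(4D) = %g",
                 dt, 1 / (4 * field$D)))
  src <- matrix(0, nrow(field$conc), ncol(field$conc))
  if (!is.null(source_pixels) && nrow(source_pixels) > 0)
    src[cbind(source_pixels[, 1], source_pixels[, 2])] <- field$secretion
  conc <- field$conc + 0  # force a copy; the C++ kernel works in place
  .cpp_diffuse_steps(conc, src, field$D, field$decay, dt, as.integer(steps))
  field$conc <- conc
  field
}

#' Run a field to its quasi-steady state
#'
#' Steps the field until the relative change over a 100-mcs window falls
#' below `tol`, then returns it. With stationary sources the gradients are
#' quasi-static, so the equilibrated field can be frozen for the rest of a
#' simulation.
#'
#' @param field A [chemokine_field()].
#' @param source_pixels 2-column matrix of source pixels.
#' @param dt Substep (mcs), must satisfy the stability bound.
#' @param tol Relative-change convergence tolerance per 100 mcs.
#' @param max_mcs Upper bound on equilibration time.
#' @return The equilibrated field.
#' @export
equilibrate_field <- function(field, source_pixels, dt = 0.2, tol = 1e-5,
                              max_mcs = 5000) {
  window <- max(1L, as.integer(round(100 / dt)))
  elapsed <- 0
  repeat {
    prev <- field$conc
    field <- step_field(field, source_pixels, dt, steps = window)
    elapsed <- elapsed + window * dt
    denom <- max(prev, 1e-12)
    if (max(abs(field$conc - prev)) / denom < tol || elapsed >= max_mcs)
      break
  }
  field
}

#' Concentration gradient at a pixel
#'
#' Central differences in the interior, one-sided at the boundaries.
#'
#' @param field A [chemokine_field()].
#' @param pixel Integer vector `c(x, y)`.
#' @return Numeric 2-vector `(d/dx, d/dy)`.
#' @export
gradient_at <- function(field, pixel) {
  gx <- nrow(field$conc); gy <- ncol(field$conc)
  x <- pixel[1]; y <- pixel[2]
  if (x < 1 || x > gx || y < 1 || y > gy)
    stop("pixel outside the grid")
  c0 <- field$conc
  dx <- if (x == 1) c0[2, y] - c0[1, y]
        else if (x == gx) c0[gx, y] - c0[gx - 1, y]
        else (c0[x + 1, y] - c0[x - 1, y]) / 2
  dy <- if (y == 1) c0[x, 2] - c0[x, 1]
        else if (y == gy) c0[x, gy] - c0[x, gy - 1]
        else (c0[x, y + 1] - c0[x, y - 1]) / 2
  c(dx, dy)
}

#' Equilibrated chemokine fields for a tissue layout
#'
#' Builds the CXCL12 field from the CRC footprints and the CXCL13 field from
#' the FDC footprints and equilibrates both, producing the two opposing
#' gradients that polarise the germinal center.
#'
#' @param layout A [build_layout()] result.
#' @return List with elements `cxcl12` and `cxcl13`.
#' @export
fields_from_layout <- function(layout) {
  cfg <- layout$config
  dims <- c(cfg$grid_x, cfg$grid_y)
  src_of <- function(type) {
    ids <- layout$cells$id[layout$cells$type == type]
    if (!length(ids)) return(matrix(0L, 0, 2))
    do.call(rbind, lapply(layout$pixels[ids], function(p) p[, 1:2]))
  }
  f12 <- chemokine_field("CXCL12", dims, cfg$chem_D, cfg$chem_decay,
                         cfg$chem_secretion)
  f13 <- chemokine_field("CXCL13", dims, cfg$chem_D, cfg$chem_decay,
                         cfg$chem_secretion)
  max_mcs <- 4 / max(cfg$chem_decay, 1e-6)
  f12 <- equilibrate_field(f12, src_of("CRC"), dt = cfg$chem_dt,
                           tol = cfg$chem_tol, max_mcs = max_mcs)
  f13 <- equilibrate_field(f13, src_of("FDC"), dt = cfg$chem_dt,
                           tol = cfg$chem_tol, max_mcs = max_mcs)
  if (isTRUE(cfg$freeze_fields)) {
    # frozen fields are rescaled to peak 1 so that the chemotaxis strengths
    # and the saturation constant have a fixed concentration scale
    if (max(f12$conc) > 0) f12$conc <- f12$conc / max(f12$conc)
    if (max(f13$conc) > 0) f13$conc <- f13$conc / max(f13$conc)
  }
  list(cxcl12 = f12, cxcl13 = f13)
}

#' Write / read a field as plain matrix text with a small header
#'
#' @param field A [chemokine_field()].
#' @param path File path.
#' @return `read_field` returns a `chemokine_field`.
#' @export
write_field <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ligand=%s nx=%d ny=%d D=%g decay=%g secretion=%g",
                     field$ligand, nrow(field$conc), ncol(field$conc),
                     field$D, field$decay, field$secretion), con)
  utils::write.table(field$conc, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- strsplit(sub("^# ", "", hdr), " ")[[1]]
  kv <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  conc <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(conc) <- NULL
  f <- chemokine_field(kv[["ligand"]],
                       c(as.integer(kv[["nx"]]), as.integer(kv[["ny"]])),
                       as.numeric(kv[["D"]]), as.numeric(kv[["decay"]]),
                       as.numeric(kv[["secretion"]]))
  f$conc <- conc
  f
}
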