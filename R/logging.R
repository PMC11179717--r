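# registry used to keep write_snapshot idempotent per (cell, t) and sink
.snapshot_registry <- new.env(parent = emptyenv())

# Column set of a per-cell trajectory row; order is fixed and versioned by
# the header line of every log file.
.log_columns <- c("t", "id", "mother", "generation", "clone", "x", "y",
                  "zone", "volume", "affinity", "phase", "pmhc", "timer",
                  "cycling", "CD40", "AKT", "FOXO1", "cRel", "RelA", "MYC",
                  "AP4", "CXCR4", "CXCR5", "BLIMP1", "BclxL", "Casp3")

#' Lineage file key of a cell
#'
#' Cells are keyed `generation_motherid_cellid`, the naming convention used
#' for per-cell trajectory files so that lineage trees can be reconstructed
#' from a directory listing.
#'
#' @param generation,mother,id Integer scalars (vectorised).
#' @return Character key(s), e.g. `"3_7_42"`.
#' @export
lineage_key <- function(generation, mother, id) {
  sprintf("%d_%d_%d", as.integer(generation), as.integer(mother),
          as.integer(id))
}

#' Append one snapshot of live cells to a consolidated log
#'
#' Appends one row per live B cell at time `t` (which must be a multiple of
#' `log_every`) to a tab-separated sink file; re-appending the same `(cell,
#' t)` pair is a no-op.
#'
#' @param cells data.frame of per-cell rows carrying at least `id`; missing
#'   log columns are filled with `NA`.
#' @param t Current time (mcs).
#' @param sink Path of the consolidated log file.
#' @param log_every Logging interval (mcs), default 15.
#' @return Number of rows appended, invisibly.
#' @export
write_snapshot <- function(cells, t, sink, log_every = 15) {
  if (t %% log_every != 0)
    stop(sprintf("t = %d is not a multiple of log_every = %d", t, log_every))
  key <- normalizePath(sink, mustWork = FALSE)
  seen <- .snapshot_registry[[key]]
  if (is.null(seen)) seen <- character(0)
  rows <- cells
  rows$t <- t
  for (cc in setdiff(.log_columns, names(rows))) rows[[cc]] <- NA
  rows <- rows[, .log_columns]
  tags <- paste(t, rows$id, sep = "_")
  rows <- rows[!tags %in% seen, , drop = FALSE]
  if (nrow(rows)) {
    fresh <- !file.exists(sink)
    ok <- try(utils::write.table(rows, sink, sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = fresh,
                                 append = !fresh), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("snapshot write failed for sink ", sink)
    .snapshot_registry[[key]] <- c(seen, paste(t, rows$id, sep = "_"))
  }
  invisible(nrow(rows))
}

#' Write the structured logs of a simulation
#'
#' Writes the consolidated trajectory table (`snapshots.tsv`), the event
#' stream (`events.tsv`), the per-cell lineage table (`cells.tsv`), the
#' plasma-cell output (`pcs.tsv`) and the configuration (`config.yaml`) as
#' tab-separated/flat text. With `per_cell = TRUE`, additionally writes one
#' trajectory file per cell named by its [lineage_key()] under
#' `dir/cells/`.
#'
#' @param sim A [simulate_gc()] result.
#' @param dir Output directory (created if needed).
#' @param per_cell Also write one file per cell.
#' @return `dir`, invisibly.
#' @export
write_gc_logs <- function(sim, dir, per_cell = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$snapshots)) w(sim$snapshots, "snapshots.tsv")
  w(sim$events, "events.tsv")
  w(sim$cells, "cells.tsv")
  w(sim$pcs, "pcs.tsv")
  write_config(sim$config, file.path(dir, "config.yaml"))
  if (per_cell && !is.null(sim$snapshots)) {
    cdir <- file.path(dir, "cells")
    dir.create(cdir, showWarnings = FALSE)
    sp <- split(sim$snapshots, sim$snapshots$id)
    for (df in sp) {
      i <- df$id[1]
      key <- lineage_key(df$generation[1], df$mother[1], i)
      utils::write.table(df, file.path(cdir, paste0(key, ".txt")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read logs written by [write_gc_logs()]
#'
#' @param dir Log directory.
#' @return List with `snapshots`, `events`, `cells`, `pcs`, `config`.
#' @export
read_gc_logs <- function(dir) {
  r <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p))
      utils::read.table(p, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    else NULL
  }
  out <- list(snapshots = r("snapshots.tsv"), events = r("events.tsv"),
              cells = r("cells.tsv"), pcs = r("pcs.tsv"),
              config = read_config(file.path(dir, "config.yaml")))
  class(out) <- "gc_sim"
  out
}

#' Reconstruct the lineage forest from per-cell log files
#'
#' Reads a directory of per-cell trajectory files named
#' `generation_motherid_cellid.txt` and assembles the forest in which the
#' children of a node are the cells whose mother id equals that node's id.
#' Roots are cells with mother id 0. An orphan (a non-root whose mother has
#' no file) raises an error naming the offending key.
#'
#' @param log_dir Directory of per-cell files (e.g. `dir/cells` from
#'   [write_gc_logs()]).
#' @return A `gc_forest`: list with `nodes` (named by cell id: `key`, `id`,
#'   `mother`, `generation`, `children`, `trajectory`) and `roots`.
#' @export
read_lineage_forest <- function(log_dir) {
  files <- list.files(log_dir, pattern = "^\\d+_\\d+_\\d+\\.txt$",
                      full.names = TRUE)
  nodes <- list()
  for (f in files) {
    key <- sub("\\.txt$", "", basename(f))
    parts <- as.integer(strsplit(key, "_")[[1]])
    traj <- utils::read.table(f, header = TRUE, sep = "\t")
    nodes[[as.character(parts[3])]] <-
      list(key = key, id = parts[3], mother = parts[2],
           generation = parts[1], children = integer(0), trajectory = traj)
  }
  for (nm in names(nodes)) {
    n <- nodes[[nm]]
    if (n$mother != 0) {
      mk <- as.character(n$mother)
      if (is.null(nodes[[mk]]))
        stop(sprintf("orphan lineage record %s: mother %d has no log file",
                     n$key, n$mother))
      nodes[[mk]]$children <- c(nodes[[mk]]$children, n$id)
    }
  }
  roots <- vapply(nodes, function(n) n$mother == 0, logical(1))
  structure(list(nodes = nodes,
                 roots = as.integer(names(nodes)[roots])),
            class = "gc_forest")
}

#' @export
print.gc_forest <- function(x, ...) {
  cat(sprintf("<gc_forest> %d cells in %d lineages\n",
              length(x$nodes), length(x$roots)))
  invisible(x)
}
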