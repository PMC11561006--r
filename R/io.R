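#' Read and write river masks
#'
#' Two plain-text dialects: `cells`, a CSV of the `(row, col)` coordinates
#' (0-based) of the river cells, and `raster`, a 0/1 grid with one
#' space-separated line per row. `read_river_mask` auto-detects the dialect
#' from the first line.
#'
#' @param path File path.
#' @param n_rows,n_cols Grid dimensions (required for the `cells` dialect).
#' @return Logical matrix.
#' @export
read_river_mask <- function(path, n_rows = NULL, n_cols = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("row", first, fixed = TRUE)) {
    df <- utils::read.csv(path)
    stopifnot(all(c("row", "col") %in% names(df)))
    if (is.null(n_rows) || is.null(n_cols))
      stop("cells dialect needs n_rows and n_cols")
    mask <- matrix(FALSE, n_rows, n_cols)
    mask[cbind(df$row + 1L, df$col + 1L)] <- TRUE
    mask
  } else {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
    m == 1
  }
}

#' @rdname read_river_mask
#' @param mask Logical matrix.
#' @param dialect `"cells"` or `"raster"`.
#' @export
write_river_mask <- function(mask, path, dialect = c("cells", "raster")) {
  dialect <- match.arg(dialect)
  if (dialect == "cells") {
    idx <- which(mask, arr.ind = TRUE)
    utils::write.csv(data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L),
                     path, row.names = FALSE)
  } else {
    utils::write.table(mask * 1L, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read and write density states
#'
#' CSV dialect: columns `row`, `col` (0-based), `omega`, listing only
#' domain cells; raster dialect: a dense real-valued grid with `NA`
#' off-domain. Writers emit full precision.
#'
#' @param path File path.
#' @param n_rows,n_cols Grid dimensions (CSV dialect).
#' @return Density state matrix.
#' @export
read_state <- function(path, n_rows = NULL, n_cols = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("omega", first, fixed = TRUE)) {
    df <- utils::read.csv(path)
    if (is.null(n_rows) || is.null(n_cols))
      stop("CSV dialect needs n_rows and n_cols")
    s <- matrix(NA_real_, n_rows, n_cols)
    s[cbind(df$row + 1L, df$col + 1L)] <- df$omega
    s
  } else {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
    m
  }
}

#' @rdname read_state
#' @param state Density state matrix.
#' @param dialect `"cells"` (CSV) or `"raster"`.
#' @export
write_state <- function(state, path, dialect = c("cells", "raster")) {
  dialect <- match.arg(dialect)
  if (dialect == "cells") {
    idx <- which(!is.na(state), arr.ind = TRUE)
    df <- data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                     omega = format(state[idx], digits = 17))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(format(state, digits = 17), path,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export a chain's energy trace
#'
#' @param chain A [run_chain()] result.
#' @param path CSV path; columns `sweep`, `energy`.
#' @export
write_energy_trace <- function(chain, path) {
  stopifnot(inherits(chain, "chain_result"))
  utils::write.csv(data.frame(sweep = seq_along(chain$energy_trace),
                              energy = chain$energy_trace),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' Configurations are nested key-value YAML files; see the packaged example
#' under `extdata`. [run_calibrate()] and [run_map()] accept either a path
#' or an already-parsed list.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config Named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Resolve the geometry a config asks for: a mask file or a synthetic river.
.config_geometry <- function(config) {
  gs <- config$grid
  grid <- grid_spec(gs$n_rows, gs$n_cols,
                    cell_size_m = if (is.null(gs$cell_size_m)) 5 else gs$cell_size_m)
  riv <- config$river
  if (!is.null(riv$file)) {
    mask <- read_river_mask(riv$file, grid$n_rows, grid$n_cols)
  } else if (!is.null(riv$synthetic)) {
    sr <- riv$synthetic
    mask <- make_river(grid$n_rows, grid$n_cols,
                       width = if (is.null(sr$width)) 1 else sr$width,
                       bifurcate = isTRUE(sr$bifurcate),
                       seed = sr$seed)
  } else {
    stop("config must provide river$file or river$synthetic")
  }
  label_regions(mask, grid)
}

.config_parcels <- function(config) {
  p <- config$parcels
  if (is.null(p)) stop("config is missing the 'parcels' section")
  if (is.null(p$cells)) stop("config parcels section is missing 'cells'")
  cells <- do.call(rbind, p$cells)
  parcel_set(cells,
             total_year_count = if (is.null(p$total_year_count)) NA else p$total_year_count,
             n_trips = if (is.null(p$n_trips)) 10 else p$n_trips)
}

#' Calibration pipeline
#'
#' Config-driven wrapper over [select_T1()] and [estimate_g()]: derives
#' `K` from the transect section (or takes it verbatim), selects the first
#' temperature from the configured candidates, calibrates `g` against the
#' parcel target, and writes a JSON calibration report plus a YAML config
#' echo into `out_dir`.
#'
#' @param config Path to a YAML config or an equivalent list. Sections:
#'   `grid`, `river`, `parcels`, `transect` (or `K`), `chain` (`n_sweeps`,
#'   `tail_sweeps`, `seed`), `temperatures` (`candidates` or `T1`, plus
#'   `T2` or `ratio`).
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing files.
#' @return The [estimate_g()] result, with the T1-selection table attached
#'   as attribute `t1_table`.
#' @export
run_calibrate <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  geom <- .config_geometry(config)
  parcels <- .config_parcels(config)
  K <- if (!is.null(config$K)) config$K else {
    tr <- config$transect
    if (is.null(tr)) stop("config needs either 'K' or a 'transect' section")
    compute_K(tr$total_count, transect_cells(tr$length_m, geom$grid$cell_size_m),
              tr$n_trips)
  }
  ch <- config$chain
  n_sweeps <- if (is.null(ch$n_sweeps)) 3000 else ch$n_sweeps
  tail_sweeps <- if (is.null(ch$tail_sweeps)) 300 else ch$tail_sweeps
  seed <- if (is.null(ch$seed)) 1L else as.integer(ch$seed)
  region_id <- if (is.null(config$region)) 1L else config$region

  tcfg <- config$temperatures
  t1_table <- NULL
  if (!is.null(tcfg$T1)) {
    T1 <- tcfg$T1
  } else {
    cand <- unlist(tcfg$candidates)
    if (is.null(cand)) stop("config temperatures section needs T1 or candidates")
    sel <- select_T1(cand, geom, region_id, K, n_sweeps, tail_sweeps, seed)
    T1 <- sel$T1
    t1_table <- sel$table
  }
  T2 <- if (!is.null(tcfg$T2)) tcfg$T2 else
    T1 / (if (is.null(tcfg$ratio)) 100 else tcfg$ratio)

  target <- if (!is.null(config$target)) config$target else
    parcels$total_year_count / parcels$n_trips
  if (is.na(target)) stop("config is missing a parcel target")

  cal <- estimate_g(target, parcels, geom, region_id, K, T1, T2,
                    n_sweeps = n_sweeps, tail_sweeps = tail_sweeps,
                    seed = seed,
                    tol = if (is.null(config$tol)) 0.01 else config$tol)
  attr(cal, "t1_table") <- t1_table

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(config, file.path(out_dir, "config_echo.yml"))
    report <- list(K = K, T1 = cal$T1, T2 = cal$T2, g_hat = cal$g_hat,
                   target = cal$target_parcel_expectation,
                   achieved = cal$achieved_parcel_expectation,
                   n_evaluations = cal$n_evaluations, seed = seed,
                   t1_candidates = t1_table,
                   evaluations = cal$evaluations)
    jsonlite::write_json(report, file.path(out_dir, "calibration_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  cal
}

#' Mapping pipeline
#'
#' Config-driven wrapper over [fit_density_map()]: fits the density surface
#' on every region with the configured (or calibrated) parameters, then
#' writes the surface (CSV + raster), the heat-map bins and PNG, and `k`
#' whole-year and single-trip realizations each into `out_dir`, along with
#' a YAML config echo. `dry_run` only echoes the config.
#'
#' @param config Path to a YAML config or an equivalent list; as
#'   [run_calibrate()] plus `params` (`g`, `T1`, `T2`) and optionally
#'   `realizations` (count `k`, default 5) and `trips`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param dry_run Echo the config and return without running chains.
#' @return List with `omega_hat`, per-region fits, `bins`, and the
#'   realization lists.
#' @export
run_map <- function(config, out_dir = NULL, dry_run = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(config, file.path(out_dir, "config_echo.yml"))
  }
  if (dry_run) return(invisible(list(config = config)))

  geom <- .config_geometry(config)
  K <- config$K
  if (is.null(K)) {
    tr <- config$transect
    if (is.null(tr)) stop("config needs either 'K' or a 'transect' section")
    K <- compute_K(tr$total_count,
                   transect_cells(tr$length_m, geom$grid$cell_size_m),
                   tr$n_trips)
  }
  pp <- config$params
  if (is.null(pp$g) || is.null(pp$T1) || is.null(pp$T2))
    stop("config params section needs g, T1, T2")
  ch <- config$chain
  n_sweeps <- if (is.null(ch$n_sweeps)) 3000 else ch$n_sweeps
  tail_sweeps <- if (is.null(ch$tail_sweeps)) 300 else ch$tail_sweeps
  seed <- if (is.null(ch$seed)) 1L else as.integer(ch$seed)
  k <- if (is.null(config$realizations$k)) 5L else as.integer(config$realizations$k)
  trips <- if (is.null(config$trips)) 10L else as.integer(config$trips)

  fit <- fit_density_map(geom, K, pp$g, pp$T1, pp$T2,
                         n_sweeps, tail_sweeps, seed)
  bins <- heatmap_bins(fit$omega_hat, K)
  years <- lapply(seq_len(k), function(i) year_counts(fit$omega_hat, trips,
                                                      seed = seed + 1000L + i))
  tripr <- lapply(seq_len(k), function(i) trip_presence(fit$omega_hat,
                                                        seed = seed + 2000L + i))

  if (!is.null(out_dir)) {
    write_state(fit$omega_hat, file.path(out_dir, "omega_hat.csv"))
    write_state(fit$omega_hat, file.path(out_dir, "omega_hat_raster.txt"),
                dialect = "raster")
    idx <- which(!is.na(bins$bin), arr.ind = TRUE)
    utils::write.csv(data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                                bin = bins$bin[idx]),
                     file.path(out_dir, "heatmap_bins.csv"), row.names = FALSE)
    render_heatmap(fit$omega_hat, geom, K,
                   file = file.path(out_dir, "heatmap.png"))
    for (i in seq_len(k)) {
      yc <- years[[i]]$counts
      iy <- which(!is.na(yc), arr.ind = TRUE)
      utils::write.csv(data.frame(row = iy[, 1] - 1L, col = iy[, 2] - 1L,
                                  count = yc[iy]),
                       file.path(out_dir, sprintf("year_realization_%d.csv", i)),
                       row.names = FALSE)
      tp <- tripr[[i]]$presence
      it <- which(!is.na(tp), arr.ind = TRUE)
      utils::write.csv(data.frame(row = it[, 1] - 1L, col = it[, 2] - 1L,
                                  presence = tp[it]),
                       file.path(out_dir, sprintf("trip_realization_%d.csv", i)),
                       row.names = FALSE)
    }
    for (i in seq_len(geom$n_regions))
      write_energy_trace(fit$regions[[i]]$chain2,
                         file.path(out_dir, sprintf("energy_region_%d.csv", i)))
  }
  list(omega_hat = fit$omega_hat, regions = fit$regions, bins = bins,
       year_realizations = years, trip_realizations = tripr)
}

#' Read survey parcels from CSV
#'
#' Accepts either grid coordinates (columns `row`, `col`, 0-based) or UTM
#' coordinates (columns `easting`, `northing`, converted through the grid's
#' anchor). Optional columns `total_year_count` and `n_trips` (read from the
#' first row) carry the year count; they default to `NA` and 10.
#'
#' @param path CSV file.
#' @param grid A [grid_spec()], required for UTM input.
#' @return A [parcel_set()].
#' @export
read_parcels <- function(path, grid = NULL) {
  df <- utils::read.csv(path)
  if (all(c("row", "col") %in% names(df))) {
    cells <- cbind(df$row, df$col)
  } else if (all(c("easting", "northing") %in% names(df))) {
    if (is.null(grid)) stop("UTM parcel input needs a grid with an anchor")
    cells <- utm_to_grid(df$easting, df$northing, grid)
  } else {
    stop("parcel CSV needs columns row,col or easting,northing")
  }
  parcel_set(cells,
             total_year_count = if ("total_year_count" %in% names(df))
               df$total_year_count[1] else NA_integer_,
             n_trips = if ("n_trips" %in% names(df)) df$n_trips[1] else 10)
}
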