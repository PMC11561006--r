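#' Generate a synthetic river mask
#'
#' Draws a random monotone lattice path crossing the grid from the top row
#' to the bottom row, dilated to the requested width, and 4-connected (a
#' diagonal step inserts the intermediate cell). Without a fork the band
#' splits the grid into exactly 2 off-river regions; with `bifurcate` the
#' path forks once partway down and encloses a middle region, giving 3 (or
#' more, depending on geometry) regions. The real study river is published
#' only as a figure, so all end-to-end testing runs on these masks.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param width River width in cells (default 1). `width >= n_cols` floods
#'   the whole grid (0 regions).
#' @param bifurcate Fork the river once (default `FALSE`).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Logical matrix, `TRUE` on river cells.
#' @export
make_river <- function(n_rows, n_cols, width = 1, bifurcate = FALSE,
                       seed = NULL) {
  stopifnot(n_rows >= 2, n_cols >= 1, width >= 1)
  if (width >= n_cols) return(matrix(TRUE, n_rows, n_cols))
  margin <- width + 1L
  if (n_cols < 2L * margin + width + 2L)
    stop("grid too narrow to host a crossing river band of this width")
  if (bifurcate && (n_cols < 2L * margin + 2L * width + 6L || n_rows < 8L))
    stop("grid too small for a bifurcating river")
  if (!is.null(seed)) set.seed(as.integer(seed))

  lo <- margin                                 # 0-based column bounds
  hi <- n_cols - 1L - margin - (width - 1L)
  step <- function(c0) max(lo, min(hi, c0 + sample(c(-1L, 0L, 1L), 1L)))
  mask <- matrix(FALSE, n_rows, n_cols)
  paint <- function(r, c0) {
    cols <- (c0:(c0 + width - 1L)) + 1L        # to 1-based
    mask[r + 1L, cols] <<- TRUE
  }
  connect <- function(r, c_old, c_new) {
    # keep the band 4-connected across a diagonal step
    if (c_new != c_old) paint(r, c_old)
  }

  start <- sample(seq(lo, hi), 1L)
  fork_row <- if (bifurcate) floor(n_rows * 0.4) else n_rows  # 0-based
  cc <- start
  paint(0L, cc)
  r <- 1L
  while (r < fork_row && r < n_rows) {
    nc <- step(cc)
    connect(r, cc, nc)
    cc <- nc
    paint(r, cc)
    r <- r + 1L
  }
  if (bifurcate && r < n_rows) {
    a <- cc; b <- cc                           # left and right branches
    gap_needed <- width + 2L
    for (rr in r:(n_rows - 1L)) {
      na <- max(lo, a + sample(c(-1L, 0L), 1L))
      nb <- min(hi, b + sample(c(0L, 1L), 1L))
      if (nb - na < gap_needed) {              # force the branches apart
        na <- max(lo, a - 1L)
        nb <- min(hi, b + 1L)
      }
      connect(rr, a, na); a <- na
      connect(rr, b, nb); b <- nb
      paint(rr, a); paint(rr, b)
    }
  }
  mask
}

#' Reference constants of the Tacana field study
#'
#' The published constants of the case study (a near-threatened spikethumb
#' frog surveyed near the Tacana volcano): grid anchoring, transect counts,
#' the density cap, parcel coordinates, and the calibrated temperatures and
#' coupling. These are reference values only — the study's river raster is
#' not published, so they cannot be recomputed here; synthetic geometries
#' stand in for testing.
#'
#' @return List with `grid` ([grid_spec()] with UTM anchors), `K`,
#'   `n_trips`, `transect_length_m`, `river_count`, `transect_cells`,
#'   `parcels` ([parcel_set()] from the published survey table),
#'   `parcel_target` (expected parcel count, total/trips), `T1`, `T2`,
#'   `g_hat`, and `note`.
#' @export
tacana_preset <- function() {
  grid <- grid_spec(192, 202, 5,
                    utm_sw = c(594378, 1668578),
                    utm_ne = c(595383, 1669533))
  parcel_cells <- rbind(c(133, 126), c(126, 134), c(117, 138),
                        c(112, 147), c(107, 157))
  list(grid = grid,
       K = compute_K(17, transect_cells(75, 5), 10),
       n_trips = 10L,
       transect_length_m = 75,
       river_count = 17L,
       transect_cells = transect_cells(75, 5),
       parcels = parcel_set(parcel_cells, total_year_count = 3, n_trips = 10),
       parcel_target = 3 / 10,
       T1 = 4.75e-6,
       T2 = 2e-8,
       g_hat = 3.25e-7,
       note = paste("reference values from the published study;",
                    "the river raster is not included"))
}

#' Build a planted-truth scenario
#'
#' Generates a synthetic geometry, plants parcels in its largest region,
#' and runs the production two-stage chain at a known coupling `g_true` to
#' produce a ground-truth density surface. The parcel expectation of that
#' surface can then serve as a calibration target, closing the loop for
#' parameter-recovery tests of [estimate_g()].
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param g_true Planted coupling constant.
#' @param T1 First-stage temperature; `T2` defaults to `T1 / 100`.
#' @param seed Integer seed (drives the river shape, the parcel placement,
#'   and the reference chain).
#' @param K Density cap (default the case-study 0.113).
#' @param width River width (cells).
#' @param bifurcate Fork the river.
#' @param n_parcels Number of planted parcels.
#' @param n_sweeps,tail_sweeps Reference-chain configuration.
#' @param T2 Second-stage temperature.
#' @return List with `geom`, `parcels`, `omega_hat` (reference surface on
#'   the largest region), `true_params` (`K`, `g`, `T1`, `T2`), `seed`.
#' @export
planted_scenario <- function(n_rows, n_cols, g_true, T1, seed,
                             K = 0.113, width = 1, bifurcate = FALSE,
                             n_parcels = 3, n_sweeps = 3000,
                             tail_sweeps = 300, T2 = T1 / 100) {
  mask <- make_river(n_rows, n_cols, width = width, bifurcate = bifurcate,
                     seed = seed)
  geom <- label_regions(mask, grid_spec(n_rows, n_cols))
  stopifnot(geom$n_regions >= 1)
  # plant parcels in the largest region (region 1 by the size ordering)
  cells1 <- which(geom$label == 1L)
  set.seed(as.integer(seed) + 1L)
  picked <- sample(cells1, n_parcels)
  M <- geom$grid$n_rows
  parcels <- parcel_set(cbind((picked - 1L) %% M, (picked - 1L) %/% M),
                        n_trips = 10)
  fit <- two_stage_chain(geom, 1L, K, g_true, T1, T2,
                         n_sweeps, tail_sweeps, seed = as.integer(seed) + 2L)
  list(geom = geom, parcels = parcels, omega_hat = fit$omega_hat,
       true_params = list(K = K, g = g_true, T1 = T1, T2 = T2),
       seed = as.integer(seed))
}
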