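#' Year-average per-cell density on the river
#'
#' The density cap `K` of the model: total individuals recorded on the
#' river transect over the year, divided by the number of transect cells
#' times the number of field trips. The case study (17 individuals, 15
#' cells, 10 trips) gives 0.113 (to three decimals).
#'
#' @param total_river_count Total individuals observed on the transect over
#'   the year.
#' @param n_river_cells Number of grid cells covering the transect.
#' @param n_trips Number of field trips in the year.
#' @return Full-precision density (individuals per cell per trip); use
#'   [format_density()] for the conventional 3-decimal report.
#' @export
compute_K <- function(total_river_count, n_river_cells, n_trips) {
  stopifnot(length(total_river_count) == 1, length(n_river_cells) == 1,
            length(n_trips) == 1)
  if (total_river_count < 0 || total_river_count != round(total_river_count))
    stop("total_river_count must be a nonnegative integer")
  if (n_river_cells < 1 || n_trips < 1)
    stop("n_river_cells and n_trips must be positive")
  total_river_count / (n_river_cells * n_trips)
}

#' @rdname compute_K
#' @param x Density value.
#' @param digits Decimals in the report (default 3).
#' @export
format_density <- function(x, digits = 3) {
  formatC(x, format = "f", digits = digits)
}

#' Number of grid cells covering a transect
#'
#' @param transect_length_m Transect length in meters.
#' @param cell_size_m Cell side length in meters.
#' @return Integer cell count. A non-integral ratio (beyond 1e-9) is
#'   rounded down with a warning.
#' @export
transect_cells <- function(transect_length_m, cell_size_m) {
  if (transect_length_m <= 0 || cell_size_m <= 0)
    stop("lengths must be positive")
  r <- transect_length_m / cell_size_m
  if (abs(r - round(r)) < 1e-9) {
    as.integer(round(r))
  } else {
    warning(sprintf("transect length is not a whole number of cells (%.6g); rounding down", r))
    as.integer(floor(r))
  }
}

#' Expected number of individuals on the parcels
#'
#' Sum of the fitted per-cell expected density over the parcel cells: the
#' model's counterpart of the year-average parcel count, the quantity
#' matched during calibration of `g`.
#'
#' @param state Density state matrix (typically a tail average).
#' @param parcels A [parcel_set()].
#' @return Nonnegative scalar.
#' @export
parcel_expectation <- function(state, parcels) {
  stopifnot(inherits(parcels, "parcel_set"), is.matrix(state))
  r <- parcels$cells[, "row"] + 1L
  c <- parcels$cells[, "col"] + 1L
  if (any(r < 1 | r > nrow(state) | c < 1 | c > ncol(state)))
    stop("parcel outside the grid")
  v <- state[cbind(r, c)]
  if (anyNA(v)) stop("parcel outside the state's region")
  sum(v)
}

#' Select the first annealing temperature
#'
#' Free-case (`g = 0`) calibration: for each candidate temperature, run a
#' chain from the zero state and record the mean energy of its tail sweeps;
#' the candidate with the smallest tail energy wins. In the free case the
#' minimizer is known (the constant boundary state at energy 0), which is
#' what makes this stage usable as a calibration instrument. The winning
#' chain's tail average is returned as warm start for the second stage.
#'
#' @param candidates Vector of candidate temperatures (>= 1).
#' @param geom A `river_geometry`.
#' @param region_id Region used for calibration (the data-bearing one).
#' @param K Density cap.
#' @param n_sweeps,tail_sweeps,seed Chain configuration; every candidate
#'   uses the same seed.
#' @param boundary River boundary (default `K`).
#' @return List with `T1`, `warm_state` (tail average of the winning
#'   chain), and `table` (data frame of candidate vs tail energy).
#' @export
select_T1 <- function(candidates, geom, region_id, K,
                      n_sweeps = 3000, tail_sweeps = 300, seed = 1,
                      boundary = K) {
  if (length(candidates) < 1) stop("need at least one candidate temperature")
  stopifnot(all(candidates > 0))
  dist <- distance_field(geom)
  ordering <- make_ordering(geom, region_id)
  tail_energy <- numeric(length(candidates))
  chains <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    ch <- run_chain(geom, region_id, model_params(K, 0, candidates[i]),
                    n_sweeps, tail_sweeps, seed,
                    boundary = boundary, dist = dist, ordering = ordering)
    tail_energy[i] <- mean(utils::tail(ch$energy_trace, tail_sweeps))
    chains[[i]] <- ch
  }
  best <- which.min(tail_energy)
  list(T1 = candidates[best],
       warm_state = chains[[best]]$tail_average,
       table = data.frame(T = candidates, tail_energy = tail_energy))
}

#' Calibrate the coupling constant g
#'
#' Finds the attraction strength at which the model's expected number of
#' individuals on the surveyed parcels matches the observed year-average
#' parcel count. Each evaluation runs the two-stage annealed chain
#' ([two_stage_chain()]) on a fixed seed and reads off the parcel
#' expectation of its tail average. Stage A scans g upward from 0 (doubling
#' from a geometry-scaled start) until the expectation first drops below
#' the target, bracketing the root; stage B bisects the bracket. The
#' expectation is assumed (and checked) to be non-increasing in g: stronger
#' attraction pulls density off the parcels and onto the river.
#'
#' @param target Target expected parcel count (observed total / trips).
#' @param parcels A [parcel_set()]; must lie in `region_id`.
#' @param geom A `river_geometry`.
#' @param region_id Calibration region.
#' @param K Density cap.
#' @param T1,T2 The two annealing temperatures, `T2 <= T1`.
#' @param n_sweeps,tail_sweeps,seed Chain configuration (per stage).
#' @param tol Absolute matching tolerance on the parcel expectation
#'   (default 0.01 expected individuals).
#' @param rtol Relative bracket width at which bisection stops.
#' @param mono_tol Tolerated Monte-Carlo wiggle when checking that the
#'   expectation decreases in g; default 10% of the free-case expectation.
#' @param max_doublings Stage-A safety cap.
#' @return Object of class `calibration_result`: `g_hat`, `T1`, `T2`,
#'   `achieved_parcel_expectation`, `target_parcel_expectation`,
#'   `n_evaluations`, `seeds`, `evaluations` (data frame of every (g,
#'   expectation) pair), `K`.
#' @export
estimate_g <- function(target, parcels, geom, region_id, K, T1, T2,
                       n_sweeps = 3000, tail_sweeps = 300, seed = 1,
                       tol = 0.01, rtol = 1e-3, mono_tol = NULL,
                       max_doublings = 80) {
  stopifnot(target >= 0, T2 <= T1)
  dist <- distance_field(geom)
  ordering <- make_ordering(geom, region_id)
  evals <- data.frame(g = numeric(0), expectation = numeric(0))
  ev <- function(g) {
    fit <- two_stage_chain(geom, region_id, K, g, T1, T2,
                           n_sweeps, tail_sweeps, seed,
                           dist = dist, ordering = ordering)
    e <- parcel_expectation(fit$omega_hat, parcels)
    evals[nrow(evals) + 1L, ] <<- c(g, e)
    e
  }

  e0 <- ev(0)
  if (is.null(mono_tol)) mono_tol <- 0.1 * max(e0, .Machine$double.eps)
  if (target > e0 + tol)
    stop(sprintf(paste0("infeasible target: the free-case parcel expectation ",
                        "(%.4g) is below the target (%.4g); attraction to the ",
                        "river can only reduce it"), e0, target))

  done <- function(g, e) {
    structure(list(g_hat = g, T1 = T1, T2 = T2,
                   achieved_parcel_expectation = e,
                   target_parcel_expectation = target,
                   n_evaluations = nrow(evals), seeds = seed,
                   evaluations = evals, K = K),
              class = "calibration_result")
  }
  if (abs(e0 - target) <= tol) return(done(0, e0))

  # stage A: doubling scan to bracket the matching g
  g_scale <- 2^-14 / max(dist$d[geom$label == region_id]^2)
  g_lo <- 0; e_lo <- e0
  g_hi <- g_scale
  e_hi <- ev(g_hi)
  n_doubles <- 0
  while (e_hi > target && n_doubles < max_doublings) {
    if (e_hi > e_lo + mono_tol)
      stop(paste0("parcel expectation increased with g beyond Monte-Carlo ",
                  "tolerance; evaluation trace:\n",
                  paste(utils::capture.output(print(evals)), collapse = "\n")))
    g_lo <- g_hi; e_lo <- e_hi
    g_hi <- 2 * g_hi
    e_hi <- ev(g_hi)
    n_doubles <- n_doubles + 1
  }
  if (e_hi > target)
    stop("could not bracket the target expectation: g scan exhausted")
  if (abs(e_hi - target) <= tol) return(done(g_hi, e_hi))

  # stage B: bisection within [g_lo, g_hi]
  repeat {
    g_mid <- (g_lo + g_hi) / 2
    e_mid <- ev(g_mid)
    if (abs(e_mid - target) <= tol) return(done(g_mid, e_mid))
    if (e_mid > target) { g_lo <- g_mid; e_lo <- e_mid }
    else { g_hi <- g_mid; e_hi <- e_mid }
    if ((g_hi - g_lo) < rtol * g_hi) {
      # bracket exhausted within Monte-Carlo noise: report the closer end
      if (abs(e_hi - target) < abs(e_mid - target)) return(done(g_hi, e_hi))
      return(done(g_mid, e_mid))
    }
  }
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> g_hat = %.6g (T1 = %g, T2 = %g)\n",
              x$g_hat, x$T1, x$T2))
  cat(sprintf("  parcel expectation %.4f (target %.4f), %d chain evaluations\n",
              x$achieved_parcel_expectation, x$target_parcel_expectation,
              x$n_evaluations))
  invisible(x)
}
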