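#' Layered cell ordering of a region
#'
#' Orders the cells of one region by breadth-first layers grown from the
#' river: layer 0 holds every region cell 4-adjacent to the river, layer
#' l+1 the still unvisited neighbours of layers up to l. Within a layer the
#' order is row-major. One period of the ordering visits every region cell
#' exactly once; sweeping in this order lets boundary information propagate
#' inward quickly, which is what makes the short two-temperature annealing
#' effective.
#'
#' @param geom A `river_geometry`.
#' @param region_id Region to order.
#' @return Object of class `cell_ordering`: `cells` (m x 2 matrix of
#'   0-based coordinates in sweep order), `layer` (integer per cell),
#'   `m` (period = region size), `region_id`.
#' @export
make_ordering <- function(geom, region_id) {
  stopifnot(inherits(geom, "river_geometry"),
            region_id >= 1, region_id <= geom$n_regions)
  M <- geom$grid$n_rows; N <- geom$grid$n_cols
  idx <- which(geom$label == region_id)
  layer <- rep(NA_integer_, length(idx))       # indexed by position in idx
  pos <- integer(M * N); pos[idx] <- seq_along(idx)

  # layer 0: region cells adjacent to the river
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  touches_river <- rep(FALSE, length(idx))
  for (s in shifts) {
    nb <- .nbr_idx(idx, M, N, s[1], s[2])
    touches_river <- touches_river | (nb > 0L & geom$river[ifelse(nb > 0L, nb, 1L)])
  }
  if (!any(touches_river))
    stop(sprintf("region %d has no river-adjacent cell: the model requires a boundary",
                 region_id))
  frontier <- idx[touches_river]
  layer[pos[frontier]] <- 0L
  lev <- 0L
  while (anyNA(layer)) {
    nxt <- integer(0)
    for (s in shifts) {
      nb <- .nbr_idx(frontier, M, N, s[1], s[2])
      nb <- nb[nb > 0L]
      nb <- nb[pos[nb] > 0L]               # in this region
      nb <- nb[is.na(layer[pos[nb]])]
      nxt <- c(nxt, nb)
    }
    nxt <- unique(nxt)
    if (length(nxt) == 0L)
      stop(sprintf("region %d is not connected to its river-adjacent cells",
                   region_id))
    lev <- lev + 1L
    layer[pos[nxt]] <- lev
    frontier <- nxt
  }

  rows <- (idx - 1L) %% M
  cols <- (idx - 1L) %/% M
  ord <- order(layer, rows, cols)
  structure(list(cells = cbind(row = rows[ord], col = cols[ord]),
                 layer = layer[ord],
                 m = length(idx), region_id = region_id),
            class = "cell_ordering")
}

# Precompute the C++ chain inputs for one ordered region:
# in-region neighbour slots, river-boundary sums, squared distances.
.chain_inputs <- function(geom, ordering, boundary, dist) {
  M <- geom$grid$n_rows; N <- geom$grid$n_cols
  b <- .boundary_matrix(geom, boundary)
  cells <- ordering$cells
  lin <- cells[, 2] * M + cells[, 1] + 1L        # linear matrix index
  posn <- integer(M * N)
  posn[lin] <- seq_along(lin)                    # 1-based position in sweep order
  m <- ordering$m
  nbr <- matrix(-1L, m, 4)
  n_river <- integer(m); sb <- numeric(m); ssb <- numeric(m)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (k in seq_along(shifts)) {
    nb <- .nbr_idx(lin, M, N, shifts[[k]][1], shifts[[k]][2])
    ok <- nb > 0L
    riv <- ok & geom$river[ifelse(ok, nb, 1L)]
    n_river <- n_river + as.integer(riv)
    sb <- sb + ifelse(riv, b[ifelse(riv, nb, 1L)], 0)
    ssb <- ssb + ifelse(riv, b[ifelse(riv, nb, 1L)]^2, 0)
    inreg <- ok & !riv & posn[ifelse(ok, nb, 1L)] > 0L
    nbr[inreg, k] <- posn[nb[inreg]] - 1L        # 0-based for C++
  }
  list(lin = lin, nbr = nbr, n_river = n_river, sb = sb, ssb = ssb,
       d2 = dist$d[lin]^2)
}

#' Run the single-site Metropolis chain on one region
#'
#' One sweep visits every region cell once, in the layered ordering. At
#' each cell a proposal is drawn uniformly on `[0, K]`; it is accepted
#' outright if it lowers the Hamiltonian, and otherwise with probability
#' `exp(-dH/T)` against an independent uniform draw (generated only when
#' needed, so the RNG stream is proposal-first). All randomness comes from
#' R's generator: the chain is bit-reproducible given `seed`.
#'
#' @param geom A `river_geometry`.
#' @param region_id Region to sample.
#' @param params A [model_params()].
#' @param n_sweeps Total sweeps (each = one pass over the region).
#' @param tail_sweeps Number of final sweeps averaged into `tail_average`,
#'   the estimate of the per-cell expected density.
#' @param seed Integer seed.
#' @param initial Initial state: scalar in `[0, K]` or a state matrix
#'   covering the region (default 0, the empty landscape).
#' @param boundary River boundary values (scalar or matrix; default `K`).
#' @param dist Optional precomputed [distance_field()].
#' @param ordering Optional precomputed [make_ordering()].
#' @param record_states Keep the end-of-sweep state of every sweep (only
#'   sensible for tiny regions; used by the stationarity diagnostics).
#' @return Object of class `chain_result` with `final_state` and
#'   `tail_average` (full-grid matrices, `NA` off-region), `energy_trace`
#'   (one total energy per sweep), `acceptance_rate`, `n_sweeps`,
#'   `tail_sweeps`, `seed`, and optionally `states` (m x n_sweeps).
#' @export
run_chain <- function(geom, region_id, params, n_sweeps, tail_sweeps, seed,
                      initial = 0, boundary = params$K, dist = NULL,
                      ordering = NULL, record_states = FALSE) {
  stopifnot(inherits(params, "model_params"),
            n_sweeps >= tail_sweeps, tail_sweeps >= 1)
  if (is.null(dist)) dist <- distance_field(geom)
  if (is.null(ordering)) ordering <- make_ordering(geom, region_id)
  ci <- .chain_inputs(geom, ordering, boundary, dist)

  if (is.matrix(initial)) {
    init <- initial[ci$lin]
  } else {
    stopifnot(length(initial) == 1)
    init <- rep(as.numeric(initial), ordering$m)
  }
  if (anyNA(init) || any(init < 0) || any(init > params$K))
    stop("initial state must cover the region with values in [0, K]")

  set.seed(as.integer(seed))
  res <- .chain_cpp(init, ci$nbr, ci$n_river, ci$sb, ci$ssb, ci$d2,
                    params$K, params$g, params$T,
                    as.integer(n_sweeps), as.integer(tail_sweeps),
                    isTRUE(record_states))

  unpack <- function(v) {
    s <- matrix(NA_real_, geom$grid$n_rows, geom$grid$n_cols)
    s[ci$lin] <- v
    s
  }
  structure(list(final_state = unpack(res$final_state),
                 tail_average = unpack(res$tail_average),
                 energy_trace = res$energy_trace,
                 acceptance_rate = res$acceptance_rate,
                 n_sweeps = as.integer(n_sweeps),
                 tail_sweeps = as.integer(tail_sweeps),
                 seed = as.integer(seed),
                 region_id = region_id,
                 params = params,
                 ordering = ordering,
                 states = res$states),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf(
    "<chain_result> region %d: %d sweeps (tail %d), acceptance %.3f\n",
    x$region_id, x$n_sweeps, x$tail_sweeps, x$acceptance_rate))
  cat(sprintf("  final energy %.6g, T = %g, g = %g, seed %d\n",
              x$energy_trace[x$n_sweeps], x$params$T, x$params$g, x$seed))
  invisible(x)
}

#' Tail average of a chain
#'
#' The mean of the last `tail_sweeps` end-of-sweep states, accumulated as a
#' running mean during the run (state history is never stored). This is the
#' chain's estimate of the per-cell expected year-average density.
#'
#' @param chain A [run_chain()] result.
#' @return Density state matrix.
#' @export
tail_average <- function(chain) {
  stopifnot(inherits(chain, "chain_result"))
  chain$tail_average
}

#' Two-stage annealed density estimate for one region
#'
#' The production recipe for a region's density surface: a first chain at
#' temperature `T1` started from the zero state, whose tail average then
#' warm-starts a second chain at the lower temperature `T2`; the result is
#' the second chain's tail average. A single temperature drop is enough
#' here because the layered ordering already produces a sharp energy
#' descent.
#'
#' @inheritParams run_chain
#' @param K,g,T1,T2 Model parameters; `T2 <= T1`.
#' @return List with `omega_hat` (density state matrix), `chain1`, `chain2`.
#' @export
two_stage_chain <- function(geom, region_id, K, g, T1, T2,
                            n_sweeps, tail_sweeps, seed,
                            boundary = K, dist = NULL, ordering = NULL) {
  stopifnot(T2 <= T1)
  if (is.null(dist)) dist <- distance_field(geom)
  if (is.null(ordering)) ordering <- make_ordering(geom, region_id)
  c1 <- run_chain(geom, region_id, model_params(K, g, T1),
                  n_sweeps, tail_sweeps, seed,
                  initial = 0, boundary = boundary,
                  dist = dist, ordering = ordering)
  c2 <- run_chain(geom, region_id, model_params(K, g, T2),
                  n_sweeps, tail_sweeps, seed + 1L,
                  initial = c1$tail_average, boundary = boundary,
                  dist = dist, ordering = ordering)
  list(omega_hat = c2$tail_average, chain1 = c1, chain2 = c2)
}

#' Fit the density map over all regions
#'
#' Runs the two-stage annealed chain independently on every region (the
#' river boundary decouples them) and merges the tail averages into one
#' full-grid surface. River cells stay `NA` in the merged map; they carry
#' the fixed boundary density and are rendered separately.
#'
#' @inheritParams two_stage_chain
#' @param geom A `river_geometry` with at least one region.
#' @param seed Base seed; region i uses `seed + 100 * i` so regions can be
#'   computed in any order with identical results.
#' @return List with `omega_hat` (full-grid matrix) and `regions` (list of
#'   per-region [two_stage_chain()] results).
#' @export
fit_density_map <- function(geom, K, g, T1, T2, n_sweeps, tail_sweeps, seed,
                            boundary = K) {
  stopifnot(geom$n_regions >= 1)
  dist <- distance_field(geom)
  omega <- matrix(NA_real_, geom$grid$n_rows, geom$grid$n_cols)
  regions <- vector("list", geom$n_regions)
  for (i in seq_len(geom$n_regions)) {
    fit <- two_stage_chain(geom, i, K, g, T1, T2, n_sweeps, tail_sweeps,
                           seed + 100L * i, boundary = boundary, dist = dist)
    sel <- geom$label == i
    omega[sel] <- fit$omega_hat[sel]
    regions[[i]] <- fit
  }
  list(omega_hat = omega, regions = regions)
}
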