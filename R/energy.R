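#' Model parameters
#'
#' @param K Density cap: the observed year-average density of individuals
#'   per cell on the river, assumed maximal there. States take values in
#'   `[0, K]`. The case study uses 0.113.
#' @param g Coupling constant of the potential well (attraction strength to
#'   the river), nonnegative.
#' @param T Temperature of the Gibbs measure; low values concentrate the
#'   measure on low-energy states.
#' @return Object of class `model_params`.
#' @export
model_params <- function(K, g = 0, T = 1e-6) {
  stopifnot(length(K) == 1, length(g) == 1, length(T) == 1)
  if (K <= 0) stop("K must be positive")
  if (g < 0) stop("g must be nonnegative")
  if (T <= 0) stop("T must be positive")
  structure(list(K = K, g = g, T = T), class = "model_params")
}

#' Build a density state
#'
#' A density state assigns to each cell of its domain a value in `[0, K]`,
#' the year-average density of individuals on that cell. The state is
#' stored as a full-grid matrix with `NA` outside the domain (river cells
#' and, when `region` is given, all other regions).
#'
#' @param geom A `river_geometry`.
#' @param value Scalar or matrix of initial values.
#' @param region Region id, or `NULL` for all off-river cells.
#' @return Numeric matrix (the state).
#' @export
state_constant <- function(geom, value, region = NULL) {
  stopifnot(inherits(geom, "river_geometry"))
  dom <- .domain_mask(geom, region)
  s <- matrix(NA_real_, geom$grid$n_rows, geom$grid$n_cols)
  s[dom] <- value
  s
}

.domain_mask <- function(geom, region = NULL) {
  if (is.null(region)) {
    !geom$river
  } else {
    stopifnot(length(region) == 1, region >= 1, region <= geom$n_regions)
    geom$label == region
  }
}

# The domain of a state is its non-NA support. It must be a union of whole
# off-river regions; energies are undefined otherwise.
.check_domain <- function(state, geom) {
  if (!is.matrix(state) || nrow(state) != geom$grid$n_rows ||
      ncol(state) != geom$grid$n_cols)
    stop("state dimensions do not match the grid")
  dom <- !is.na(state)
  if (any(dom & geom$river))
    stop("state assigns values on river cells; the river is fixed boundary data")
  ids <- unique(geom$label[dom])
  for (i in ids)
    if (any(geom$label == i & !dom))
      stop(sprintf("state covers region %d only partially", i))
  dom
}

.boundary_matrix <- function(geom, boundary) {
  if (is.matrix(boundary)) {
    stopifnot(nrow(boundary) == geom$grid$n_rows,
              ncol(boundary) == geom$grid$n_cols)
    boundary
  } else {
    stopifnot(length(boundary) == 1)
    matrix(boundary, geom$grid$n_rows, geom$grid$n_cols)
  }
}

# shift a matrix by (dr, dc), padding with `fill`
.shift_mat <- function(m, dr, dc, fill = NA) {
  M <- nrow(m); N <- ncol(m)
  out <- matrix(fill, M, N)
  rs <- seq_len(M) - dr; cs <- seq_len(N) - dc
  ok_r <- rs >= 1 & rs <= M; ok_c <- cs >= 1 & cs <= N
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Spreading (free) energy with river boundary conditions
#'
#' Sum of squared density differences over all unordered pairs of
#' 4-adjacent cells inside the state's domain, plus one term
#' `(omega_t - boundary_s)^2` for every incidence of a domain cell `t` with
#' an adjacent river cell `s`. A cell touching the river on two sides
#' contributes two boundary terms. This term is minimized by constant
#' states and therefore promotes spreading.
#'
#' @param state Density state (matrix, `NA` off-domain); see
#'   [state_constant()].
#' @param geom A `river_geometry`.
#' @param boundary River boundary values: scalar or full-grid matrix (only
#'   river cells are read). The case study fixes the river at `K`.
#' @return Nonnegative scalar.
#' @export
free_energy <- function(state, geom, boundary) {
  dom <- .check_domain(state, geom)
  b <- .boundary_matrix(geom, boundary)
  s0 <- state; s0[!dom] <- 0
  e <- 0
  # interior cliques, each unordered pair once (right and down shifts)
  for (shift in list(c(0L, 1L), c(1L, 0L))) {
    sh <- .shift_mat(s0, shift[1], shift[2], fill = 0)
    pair <- dom & .shift_mat(dom, shift[1], shift[2], fill = FALSE)
    e <- e + sum(((s0 - sh)[pair])^2)
  }
  # boundary incidences, all four directions
  for (shift in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    riv <- .shift_mat(geom$river, shift[1], shift[2], fill = FALSE)
    bsh <- .shift_mat(b, shift[1], shift[2], fill = 0)
    inc <- dom & riv
    e <- e + sum(((s0 - bsh)[inc])^2)
  }
  e
}

#' Potential-well energy
#'
#' `g * sum(d^2 * omega)` over the state's domain: a quadratic well (in the
#' river distance `d`) that penalizes density far from the river, modelling
#' attraction of the species to the water body.
#'
#' @inheritParams free_energy
#' @param dist A [distance_field()].
#' @param g Coupling constant (nonnegative).
#' @return Nonnegative scalar.
#' @export
potential_energy <- function(state, geom, dist, g) {
  dom <- .check_domain(state, geom)
  if (g < 0) stop("g must be nonnegative")
  stopifnot(inherits(dist, "distance_field"))
  g * sum((dist$d^2 * state)[dom])
}

#' Total Hamiltonian
#'
#' `free_energy + potential_energy`; its low-energy states realize the
#' equilibrium between spreading and attraction to the river.
#'
#' @inheritParams potential_energy
#' @param params A [model_params()].
#' @return Nonnegative scalar.
#' @export
total_energy <- function(state, geom, boundary, dist, params) {
  stopifnot(inherits(params, "model_params"))
  free_energy(state, geom, boundary) +
    potential_energy(state, geom, dist, params$g)
}

#' Energy increment of a single-site update
#'
#' Computes `H(state with cell <- new_value) - H(state)` from the cell's at
#' most four neighbour terms and its potential term only, in O(1); this is
#' the quantity driving each Metropolis step.
#'
#' @inheritParams total_energy
#' @param cell `(row, col)` grid coordinate (0-based) of the updated cell;
#'   must lie in the state's domain.
#' @param new_value Proposed density, in `[0, K]`.
#' @return Scalar energy difference (any sign).
#' @export
delta_energy <- function(state, cell, new_value, geom, boundary, dist, params) {
  stopifnot(inherits(params, "model_params"), length(cell) == 2)
  if (new_value < 0 || new_value > params$K)
    stop("new_value must lie in [0, K]")
  M <- geom$grid$n_rows; N <- geom$grid$n_cols
  r <- cell[1] + 1L; c <- cell[2] + 1L
  if (r < 1 || r > M || c < 1 || c > N || is.na(state[r, c]))
    stop("cell is not in the state's domain")
  b <- .boundary_matrix(geom, boundary)
  cur <- state[r, c]
  dh <- params$g * dist$d[r, c]^2 * (new_value - cur)
  for (shift in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    rr <- r + shift[1]; cc <- c + shift[2]
    if (rr < 1 || rr > M || cc < 1 || cc > N) next
    if (geom$river[rr, cc]) {
      v <- b[rr, cc]
      dh <- dh + (new_value - v)^2 - (cur - v)^2
    } else if (!is.na(state[rr, cc])) {
      v <- state[rr, cc]
      dh <- dh + (new_value - v)^2 - (cur - v)^2
    }
    # neighbours in other regions do not interact: the river decouples them
  }
  dh
}

#' Unnormalized log-density of the Gibbs measure
#'
#' `-H(state)/T`. The normalizing constant is never materialized: sampling
#' and comparison only ever use energy differences.
#'
#' @inheritParams total_energy
#' @return Scalar (nonpositive for valid states).
#' @export
log_unnorm_density <- function(state, geom, boundary, dist, params) {
  -total_energy(state, geom, boundary, dist, params) / params$T
}
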