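# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately use different algorithms from the package
# (label propagation instead of BFS, double loops instead of vectorized
# shifts) so they can catch implementation errors.

# label propagation flood fill: each non-river cell repeatedly takes the
# minimum provisional id among itself and its 4-neighbours
oracle_components <- function(mask) {
  M <- nrow(mask); N <- ncol(mask)
  id <- matrix(seq_len(M * N), M, N)
  id[mask] <- NA_integer_
  repeat {
    changed <- FALSE
    for (i in seq_len(M)) for (j in seq_len(N)) {
      if (is.na(id[i, j])) next
      for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- i + s[1]; c <- j + s[2]
        if (r >= 1 && r <= M && c >= 1 && c <= N && !is.na(id[r, c]) &&
            id[r, c] < id[i, j]) {
          id[i, j] <- id[r, c]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  id
}

# brute-force Hamiltonian: explicit double loop over cells and neighbours,
# interior cliques counted once via an unordered-pair set
oracle_total_energy <- function(state, geom, boundary, dist, g) {
  M <- nrow(state); N <- ncol(state)
  b <- if (is.matrix(boundary)) boundary else matrix(boundary, M, N)
  e <- 0
  for (i in seq_len(M)) for (j in seq_len(N)) {
    if (is.na(state[i, j])) next
    for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- i + s[1]; c <- j + s[2]
      if (r < 1 || r > M || c < 1 || c > N) next
      if (geom$river[r, c]) {
        e <- e + (state[i, j] - b[r, c])^2            # every incidence
      } else if (!is.na(state[r, c]) && (r > i || (r == i && c > j))) {
        e <- e + (state[i, j] - state[r, c])^2        # each pair once
      }
    }
    e <- e + g * dist$d[i, j]^2 * state[i, j]
  }
  e
}

# brute-force river distance: M = min column offset over river cells, A =
# min row offset among river cells at that column offset
oracle_distance <- function(geom) {
  M <- nrow(geom$river); N <- ncol(geom$river)
  rc <- which(geom$river, arr.ind = TRUE)
  d <- matrix(0, M, N)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    if (geom$river[i, j]) next
    coff <- abs(rc[, 2] - j)
    m <- min(coff)
    a <- min(abs(rc[coff == m, 1] - i))
    d[i, j] <- m + a
  }
  d
}

# straight vertical river in the given 1-based column
column_river_geom <- function(n_rows, n_cols, col) {
  mask <- matrix(FALSE, n_rows, n_cols)
  mask[, col] <- TRUE
  label_regions(mask, grid_spec(n_rows, n_cols))
}

# random state on the full off-river domain (or one region)
random_state <- function(geom, K, region = NULL) {
  s <- state_constant(geom, 0, region)
  dom <- !is.na(s)
  s[dom] <- stats::runif(sum(dom), 0, K)
  s
}

K_CASE <- compute_K(17, 15, 10)   # the case-study density cap
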