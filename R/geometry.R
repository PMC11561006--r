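#' Define the study-area lattice
#'
#' The study region is partitioned into a regular grid of square cells.
#' Cell coordinates are `(row, col)` with row 0 at the northern edge and
#' column 0 at the western edge, the convention used by the field survey
#' tables; matrix storage adds 1 to each index.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers). The Tacana
#'   case study uses 192 x 202.
#' @param cell_size_m Side length of a cell in meters (default 5).
#' @param utm_sw,utm_ne Optional `(easting, northing)` pairs for the
#'   south-west and north-east corners of the study rectangle (UTM meters),
#'   enabling [utm_to_grid()].
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(20, 21)
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_m = 5,
                      utm_sw = NULL, utm_ne = NULL) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1,
            n_rows >= 1, n_cols >= 1, n_rows == round(n_rows),
            n_cols == round(n_cols), cell_size_m > 0)
  if (xor(is.null(utm_sw), is.null(utm_ne)))
    stop("both or neither of utm_sw and utm_ne must be given")
  if (!is.null(utm_sw)) {
    stopifnot(length(utm_sw) == 2, length(utm_ne) == 2)
    if (utm_ne[1] <= utm_sw[1] || utm_ne[2] <= utm_sw[2])
      stop("utm_ne must lie north-east of utm_sw")
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size_m = cell_size_m,
                 utm_sw = utm_sw, utm_ne = utm_ne),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %g m per cell\n",
              x$n_rows, x$n_cols, x$cell_size_m))
  if (!is.null(x$utm_sw))
    cat(sprintf("  UTM anchor SW (%g, %g), NE (%g, %g)\n",
                x$utm_sw[1], x$utm_sw[2], x$utm_ne[1], x$utm_ne[2]))
  invisible(x)
}

# linear matrix index of neighbours, or 0 when off-grid
.nbr_idx <- function(idx, n_rows, n_cols, dr, dc) {
  r <- (idx - 1L) %% n_rows + dr
  c <- (idx - 1L) %/% n_rows + dc
  ok <- r >= 0L & r < n_rows & c >= 0L & c < n_cols
  ifelse(ok, c * n_rows + r + 1L, 0L)
}

#' Label the river and its off-river regions
#'
#' Splits the lattice into the river cells and the maximal 4-connected
#' components of the remaining cells ("regions"). Regions are numbered
#' deterministically: by decreasing size, ties broken by the smaller
#' row-major first cell, so "region 1" is stable across runs.
#'
#' @param river_mask Logical matrix of dimension `n_rows x n_cols`; `TRUE`
#'   marks a river cell.
#' @param grid A [grid_spec()].
#' @return An object of class `river_geometry` with elements `grid`,
#'   `river` (logical matrix), `label` (integer matrix, 0 for river cells,
#'   region id otherwise), `region_sizes`, and `n_regions`.
#' @seealso [validate_geometry()], [distance_field()]
#' @export
label_regions <- function(river_mask, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(river_mask) || !is.logical(river_mask))
    stop("river_mask must be a logical matrix")
  if (nrow(river_mask) != grid$n_rows || ncol(river_mask) != grid$n_cols)
    stop(sprintf("river_mask is %d x %d but the grid is %d x %d",
                 nrow(river_mask), ncol(river_mask),
                 grid$n_rows, grid$n_cols))
  M <- grid$n_rows; N <- grid$n_cols
  lab <- matrix(NA_integer_, M, N)
  lab[river_mask] <- 0L
  n_cells <- M * N

  # flood fill in row-major scan order so provisional ids order the
  # components by their first (row-major) cell
  prov <- 0L
  queue <- integer(n_cells)
  scan <- order(((seq_len(n_cells) - 1L) %% M), ((seq_len(n_cells) - 1L) %/% M))
  for (start in scan) {
    if (!is.na(lab[start])) next
    prov <- prov + 1L
    lab[start] <- prov
    queue[1L] <- start; head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      for (shift in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        nb <- .nbr_idx(cur, M, N, shift[1], shift[2])
        if (nb > 0L && is.na(lab[nb])) {
          lab[nb] <- prov
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
  }

  if (prov > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = prov)
    # renumber: decreasing size, ties by provisional id (= row-major first cell)
    new_id <- integer(prov)
    new_id[order(-sizes, seq_len(prov))] <- seq_len(prov)
    relab <- lab
    relab[lab > 0L] <- new_id[lab[lab > 0L]]
    lab <- relab
    sizes <- tabulate(lab[lab > 0L], nbins = prov)
  } else {
    sizes <- integer(0)
  }

  structure(list(grid = grid, river = river_mask, label = lab,
                 region_sizes = sizes, n_regions = prov),
            class = "river_geometry")
}

#' @export
print.river_geometry <- function(x, ...) {
  cat(sprintf("<river_geometry> %d x %d grid, %d river cells, %d region(s)\n",
              x$grid$n_rows, x$grid$n_cols, sum(x$river), x$n_regions))
  if (x$n_regions > 0)
    cat("  region sizes:", paste(x$region_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Distance of every cell to the river
#'
#' The river distance of a cell decomposes as `d = M + A`: `M` is the
#' minimal absolute column offset to any river cell, and `A` is the minimal
#' absolute row offset to a river cell in a column achieving that minimum.
#' Distances are in cell units; the coupling constant of the potential well
#' absorbs the physical scale. `d` is 0 exactly on river cells and at least
#' 1 elsewhere.
#'
#' @param geom A [label_regions()] result.
#' @return Object of class `distance_field`: list of matrices `d`,
#'   `M_horiz`, `A_vert`.
#' @export
distance_field <- function(geom) {
  stopifnot(inherits(geom, "river_geometry"))
  if (!any(geom$river)) stop("no river cells: the river distance is undefined")
  M <- geom$grid$n_rows; N <- geom$grid$n_cols
  rc <- which(geom$river, arr.ind = TRUE)
  river_cols <- sort(unique(rc[, 2]))         # 1-based matrix columns
  # per river column: min |row - river row| for every grid row
  vdist <- matrix(0, M, length(river_cols))
  for (k in seq_along(river_cols)) {
    rows_k <- rc[rc[, 2] == river_cols[k], 1]
    vdist[, k] <- apply(abs(outer(seq_len(M), rows_k, "-")), 1, min)
  }
  dM <- matrix(0, M, N); dA <- matrix(0, M, N)
  for (j in seq_len(N)) {
    off <- abs(river_cols - j)
    m_j <- min(off)
    at <- which(off == m_j)
    a_j <- if (length(at) == 1L) vdist[, at] else
      do.call(pmin, lapply(at, function(k) vdist[, k]))
    dM[, j] <- m_j
    dA[, j] <- a_j
  }
  dM[geom$river] <- 0
  dA[geom$river] <- 0
  structure(list(d = dM + dA, M_horiz = dM, A_vert = dA),
            class = "distance_field")
}

#' Convert UTM coordinates to grid coordinates
#'
#' Rows count down from the northern edge, columns count right from the
#' western edge: `row = round((northing_max - northing) / cell)` and
#' `col = round((easting - easting_min) / cell)`. This nearest-integer
#' convention reproduces the published parcel coordinates of the case study.
#'
#' @param easting,northing UTM coordinates in meters (vectorized).
#' @param grid A [grid_spec()] with UTM anchors.
#' @return A two-column integer matrix with columns `row`, `col`.
#' @examples
#' g <- tacana_preset()$grid
#' utm_to_grid(595008.5, 1668868.5, g)  # parcel 1: (133, 126)
#' @export
utm_to_grid <- function(easting, northing, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(grid$utm_sw)) stop("grid has no UTM anchor")
  stopifnot(length(easting) == length(northing))
  if (any(easting < grid$utm_sw[1] | easting > grid$utm_ne[1] |
          northing < grid$utm_sw[2] | northing > grid$utm_ne[2]))
    stop("point outside the anchored study rectangle")
  row <- round((grid$utm_ne[2] - northing) / grid$cell_size_m)
  col <- round((easting - grid$utm_sw[1]) / grid$cell_size_m)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Survey parcels
#'
#' A set of off-river survey cells together with the total number of
#' individuals recorded on them over a field year.
#'
#' @param cells Two-column matrix or data frame of `(row, col)` grid
#'   coordinates (0-based).
#' @param total_year_count Total individuals recorded on the parcels over
#'   the year (`NA` when unknown, e.g. for planted test scenarios).
#' @param n_trips Number of field trips in the year (default 10).
#' @return Object of class `parcel_set`.
#' @export
parcel_set <- function(cells, total_year_count = NA_integer_, n_trips = 10) {
  cells <- as.matrix(cells)
  stopifnot(ncol(cells) == 2, nrow(cells) >= 1, n_trips >= 1)
  storage.mode(cells) <- "integer"
  colnames(cells) <- c("row", "col")
  if (anyDuplicated(cells)) stop("parcel cells must be pairwise distinct")
  if (!is.na(total_year_count) && total_year_count < 0)
    stop("total_year_count must be nonnegative")
  structure(list(cells = cells,
                 total_year_count = total_year_count,
                 n_trips = as.integer(n_trips)),
            class = "parcel_set")
}

#' Check the internal consistency of a labelled geometry
#'
#' Verifies that every cell carries exactly one label, that each region is a
#' single maximal 4-connected component, and that no two cells of different
#' regions are 4-neighbours. Constructive output of [label_regions()] always
#' passes; the check is for hand-built or file-loaded labels.
#'
#' @param geom A `river_geometry` (possibly hand-modified).
#' @return List with `ok` (logical) and `failures`, a data frame naming each
#'   offending cell (0-based coordinates) and the rule it violates.
#' @export
validate_geometry <- function(geom) {
  stopifnot(inherits(geom, "river_geometry"))
  M <- geom$grid$n_rows; N <- geom$grid$n_cols
  lab <- geom$label
  fail <- list()
  bad <- function(idx, rule) {
    data.frame(row = (idx - 1L) %% M, col = (idx - 1L) %/% M, rule = rule)
  }

  un <- which(is.na(lab))
  if (length(un)) fail[[length(fail) + 1L]] <- bad(un, "unlabeled cell")
  riv_mismatch <- which((lab == 0L) != geom$river)
  if (length(riv_mismatch))
    fail[[length(fail) + 1L]] <- bad(riv_mismatch, "river/label mismatch")

  # cross-region adjacency
  for (shift in list(c(1L, 0L), c(0L, 1L))) {
    idx <- which(!is.na(lab) & lab > 0L)
    nb <- .nbr_idx(idx, M, N, shift[1], shift[2])
    keep <- nb > 0L & !is.na(lab[ifelse(nb > 0L, nb, 1L)]) &
      lab[ifelse(nb > 0L, nb, 1L)] > 0L
    idx <- idx[keep]; nb <- nb[keep]
    diffr <- idx[lab[idx] != lab[nb]]
    if (length(diffr))
      fail[[length(fail) + 1L]] <- bad(diffr, "adjacent cells in different regions")
  }

  # connectivity + size bookkeeping: re-label and compare component structure
  if (!anyNA(lab)) {
    ref <- label_regions(lab == 0L, geom$grid)
    for (i in seq_len(geom$n_regions)) {
      cells_i <- which(lab == i)
      if (length(cells_i) == 0L) next
      if (length(unique(ref$label[cells_i])) > 1L)
        fail[[length(fail) + 1L]] <- bad(cells_i[1L], sprintf("region %d is disconnected", i))
      if (!is.null(geom$region_sizes) && length(geom$region_sizes) >= i &&
          geom$region_sizes[i] != length(cells_i))
        fail[[length(fail) + 1L]] <-
          bad(cells_i[1L], sprintf("region %d size mismatch", i))
    }
  }

  failures <- if (length(fail)) do.call(rbind, fail) else
    data.frame(row = integer(0), col = integer(0), rule = character(0))
  list(ok = nrow(failures) == 0L, failures = failures)
}
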