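#' Simulated whole-year observation counts
#'
#' Draws, independently for every cell of the fitted surface, a Poisson
#' count with mean `trips * omega_hat`: a realization of the individuals
#' that could have been recorded on that cell over the whole field year.
#' River cells (and cells outside the fitted domain) stay `NA`.
#'
#' @param omega_hat Fitted density state matrix (values in `[0, K]`).
#' @param trips Number of field trips in the year (default 10).
#' @param seed Integer seed; the draw is reproducible.
#' @return Object of class `year_realization`: `counts` (integer matrix),
#'   `trips`, `seed`.
#' @export
year_counts <- function(omega_hat, trips = 10, seed = 1) {
  stopifnot(is.matrix(omega_hat), trips >= 1)
  dom <- !is.na(omega_hat)
  if (any(omega_hat[dom] < 0)) stop("negative density")
  set.seed(as.integer(seed))
  counts <- matrix(NA_integer_, nrow(omega_hat), ncol(omega_hat))
  counts[dom] <- stats::rpois(sum(dom), trips * omega_hat[dom])
  structure(list(counts = counts, trips = as.integer(trips),
                 seed = as.integer(seed)),
            class = "year_realization")
}

#' Simulated single-trip presences
#'
#' Draws, independently for every cell, a Bernoulli presence with success
#' probability `omega_hat` (valid because the density cap is below 1): a
#' realization of what one average field trip could have observed.
#'
#' @inheritParams year_counts
#' @return Object of class `trip_realization`: `presence` (0/1 integer
#'   matrix, `NA` off-domain), `seed`.
#' @export
trip_presence <- function(omega_hat, seed = 1) {
  stopifnot(is.matrix(omega_hat))
  dom <- !is.na(omega_hat)
  if (any(omega_hat[dom] < 0)) stop("negative density")
  if (any(omega_hat[dom] > 1))
    stop("density above 1: the Bernoulli presence reading requires omega <= 1")
  set.seed(as.integer(seed))
  presence <- matrix(NA_integer_, nrow(omega_hat), ncol(omega_hat))
  presence[dom] <- as.integer(stats::runif(sum(dom)) <= omega_hat[dom])
  structure(list(presence = presence, seed = as.integer(seed)),
            class = "trip_realization")
}

#' Rainbow bins of the density surface
#'
#' Assigns each fitted cell to one of 7 bins, constant on the half-open
#' intervals `((s/7) K, ((s+1)/7) K]` for `s = 0..6`; a density of exactly
#' 0 (outside every interval) falls in bin 0. Bins map to the rainbow
#' colors red, orange, yellow, green, cyan, blue, violet in order of
#' increasing density.
#'
#' @param omega_hat Fitted density state matrix.
#' @param K Density cap.
#' @return Object of class `heatmap_bins`: `bin` (integer matrix in 0..6,
#'   `NA` off-domain) and `bin_edges` (data frame with `bin`, `lower`,
#'   `upper`, `color`).
#' @export
heatmap_bins <- function(omega_hat, K) {
  stopifnot(is.matrix(omega_hat), K > 0)
  dom <- !is.na(omega_hat)
  v <- omega_hat[dom]
  if (any(v < 0) || any(v > K * (1 + 1e-12)))
    stop("density outside [0, K]")
  b <- pmin(pmax(ceiling(7 * v / K) - 1L, 0L), 6L)
  bin <- matrix(NA_integer_, nrow(omega_hat), ncol(omega_hat))
  bin[dom] <- as.integer(b)
  s <- 0:6
  structure(list(bin = bin,
                 bin_edges = data.frame(bin = s, lower = s * K / 7,
                                        upper = (s + 1) * K / 7,
                                        color = heat_palette())),
            class = "heatmap_bins")
}

#' Rainbow palette of the heat map
#'
#' Seven colors in ascending color energy (red through violet), with
#' intensity increasing along the scale.
#' @return Character vector of 7 colors.
#' @export
heat_palette <- function() {
  base <- c("red", "orange", "yellow", "green", "cyan", "blue", "violet")
  # deepen the tone as the bin index (density) grows
  mapply(function(col, f) grDevices::adjustcolor(col, red.f = f, green.f = f,
                                                 blue.f = f),
         base, seq(0.65, 1, length.out = 7), USE.NAMES = FALSE)
}

#' Render the density heat map
#'
#' Draws the binned density surface with the rainbow palette; river cells
#' are drawn black. With `file` given, writes a PNG instead of drawing on
#' the current device.
#'
#' @param omega_hat Fitted density state matrix.
#' @param geom A `river_geometry`.
#' @param K Density cap.
#' @param file Optional PNG path.
#' @param ... Passed to [graphics::image()].
#' @return The [heatmap_bins()] object, invisibly.
#' @export
render_heatmap <- function(omega_hat, geom, K, file = NULL, ...) {
  hb <- heatmap_bins(omega_hat, K)
  z <- hb$bin
  z[geom$river] <- 7L                      # river drawn black
  if (!is.null(file)) {
    grDevices::png(file, width = 1000,
                   height = round(1000 * nrow(z) / ncol(z)))
    on.exit(grDevices::dev.off())
  }
  # row 0 is the northern edge: flip so north is at the top of the plot
  graphics::image(t(z[nrow(z):1, , drop = FALSE]),
                  col = c(heat_palette(), "black"),
                  breaks = seq(-0.5, 7.5, by = 1),
                  axes = FALSE, asp = nrow(z) / ncol(z), ...)
  invisible(hb)
}

#' Render an observation realization as jittered dots
#'
#' Places `counts[i, j]` dots (or a single dot per presence) uniformly
#' jittered within each cell square over a light grid, with river cells
#' black: a picture of what the field year (or one trip) could have looked
#' like.
#'
#' @param realization A [year_counts()] or [trip_presence()] result.
#' @param geom A `river_geometry`.
#' @param file Optional PNG path.
#' @param seed Seed for the in-cell jitter (display only).
#' @return Invisibly, the number of dots drawn.
#' @export
plot_realization <- function(realization, geom, file = NULL, seed = 1) {
  z <- if (inherits(realization, "year_realization")) realization$counts
       else if (inherits(realization, "trip_realization")) realization$presence
       else stop("realization must be a year_realization or trip_realization")
  M <- nrow(z); N <- ncol(z)
  if (!is.null(file)) {
    grDevices::png(file, width = 1000, height = round(1000 * M / N))
    on.exit(grDevices::dev.off())
  }
  bg <- matrix(0L, M, N); bg[geom$river] <- 1L
  graphics::image(t(bg[M:1, , drop = FALSE]), col = c("white", "black"),
                  breaks = c(-0.5, 0.5, 1.5), axes = FALSE, asp = M / N)
  idx <- which(!is.na(z) & z > 0L)
  n_dots <- 0L
  if (length(idx)) {
    reps <- z[idx]
    rows <- rep((idx - 1L) %% M, reps)
    cols <- rep((idx - 1L) %/% M, reps)
    set.seed(as.integer(seed))
    # jitter within the unit cell square, in plot coordinates
    x <- (cols + stats::runif(length(cols))) / N
    y <- 1 - (rows + stats::runif(length(rows))) / M
    graphics::points(x, y, pch = 16, cex = 0.5, col = "darkgreen")
    n_dots <- length(x)
  }
  invisible(n_dots)
}
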