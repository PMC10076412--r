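#' Second-order spatial cumulants from a marked point pattern
#'
#' Estimates per-type densities, radially binned pair densities
#' \eqn{\hat k^{(2)}_{ij}(r)} and spatial covariances
#' \eqn{\hat u^{(2)}_{ij}(r) = \hat k^{(2)}_{ij}(r) - \hat u^{(1)}_i
#' \hat u^{(1)}_j} from a marked point pattern on a periodic rectangle.
#'
#' Each type's counts are rasterised onto a `grid_n x grid_n` periodic grid;
#' all ordered-pair raw cross-correlations are computed with the FFT (exact
#' on the raster, periodic wrap = minimum-image convention). For `i = j` the
#' `N_i` self-pairs are removed from the zero-lag before normalisation, so
#' pair densities count distinct ordered pairs per squared unit area. Raster
#' displacements are then radially averaged into bins of width `delta_h`.
#' The cross statistics (1,2) and (2,1) are symmetrised, making the estimator
#' exactly symmetric.
#'
#' @param pattern a [point_pattern()].
#' @param delta_h radial bin width; must be at least the raster pitch
#'   `Lx / grid_n`.
#' @param grid_n raster size per axis (>= 8). A non-square domain must be an
#'   integer multiple of square raster cells.
#' @param r_max largest binned distance (default: half the shorter domain
#'   side).
#' @return An object of class `pair_statistics` with fields:
#'   `densities` (per-type, exact `N_i / A`), `bin_edges`, `bin_mid`,
#'   `pair_density` and `covariance` (arrays `bins x type x type`),
#'   `annulus_count` and `annulus_measure` (raster cells and area per bin),
#'   plus the estimator settings.
#' @examples
#' pp <- generate_icc(icc_config("icc1"), seed = 1)
#' st <- pair_statistics(pp, grid_n = 64)
#' st$densities
#' @export
pair_statistics <- function(pattern, delta_h = NULL, grid_n = 256L,
                            r_max = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  grid_n <- as.integer(grid_n)
  if (grid_n < 8L) stop("`grid_n` must be >= 8", call. = FALSE)
  Lx <- pattern$domain[1]; Ly <- pattern$domain[2]
  h <- Lx / grid_n
  ny <- Ly / h
  if (abs(ny - round(ny)) > 1e-9) {
    stop("domain aspect does not fit square raster cells: Ly must be a ",
         "multiple of Lx/grid_n", call. = FALSE)
  }
  nx <- grid_n; ny <- as.integer(round(ny))
  if (is.null(delta_h)) delta_h <- h
  if (delta_h < h - 1e-12) {
    stop("`delta_h` must be at least the raster pitch Lx/grid_n = ", h,
         call. = FALSE)
  }
  if (is.null(r_max)) r_max <- min(Lx, Ly) / 2
  A <- Lx * Ly
  a_cell <- h * h
  S <- pattern$n_marks

  # raster counts and their FFTs per type
  ix <- pmin(floor(pattern$x / h), nx - 1)
  iy <- pmin(floor(pattern$y / h), ny - 1)
  cell <- 1 + ix + nx * iy
  Fm <- vector("list", S)
  N <- integer(S)
  for (i in seq_len(S)) {
    cnt <- tabulate(cell[pattern$mark == i], nbins = nx * ny)
    N[i] <- sum(pattern$mark == i)
    Fm[[i]] <- stats::fft(matrix(cnt, nrow = nx, ncol = ny))
  }

  # minimum-image radial distance of every raster displacement
  dx <- (0:(nx - 1)); dx <- pmin(dx, nx - dx) * h
  dy <- (0:(ny - 1)); dy <- pmin(dy, ny - dy) * h
  rdisp <- sqrt(outer(dx^2, dy^2, `+`))
  bin <- floor(rdisp / delta_h) + 1L
  keep <- rdisp <= r_max
  nbins <- as.integer(ceiling(r_max / delta_h))
  bin[!keep] <- NA_integer_
  bin[bin > nbins] <- NA_integer_
  binv <- as.vector(bin)
  ok <- !is.na(binv)
  annulus_count <- tabulate(binv[ok], nbins = nbins)

  raw_corr <- function(i, j) {
    # P[d] = sum_x n_i(x) n_j(x + d); these are integer pair counts, so
    # rounding removes FFT floating-point noise and makes the estimator
    # exact on the raster
    round(Re(stats::fft(Conj(Fm[[i]]) * Fm[[j]], inverse = TRUE)) / (nx * ny))
  }
  bin_sum <- function(P) {
    v <- as.vector(P)
    s <- rep(0, nbins)
    t <- tapply(v[ok], binv[ok], sum)
    s[as.integer(names(t))] <- t
    s
  }

  pair_density <- array(0, dim = c(nbins, S, S))
  for (i in seq_len(S)) {
    P <- raw_corr(i, i)
    P[1, 1] <- P[1, 1] - N[i]             # remove self-pairs at zero lag
    pair_density[, i, i] <- bin_sum(P) / (A * a_cell * annulus_count)
  }
  if (S >= 2L) {
    for (i in 1:(S - 1)) for (j in (i + 1):S) {
      P <- (raw_corr(i, j) + raw_corr(j, i)) / 2
      v <- bin_sum(P) / (A * a_cell * annulus_count)
      pair_density[, i, j] <- v
      pair_density[, j, i] <- v
    }
  }
  pair_density[!is.finite(pair_density)] <- 0   # empty annuli (none expected)

  densities <- N / A
  covariance <- pair_density -
    outer(rep(1, nbins), outer(densities, densities))

  structure(
    list(densities = densities,
         bin_edges = seq(0, nbins * delta_h, by = delta_h),
         bin_mid = (seq_len(nbins) - 0.5) * delta_h,
         pair_density = pair_density,
         covariance = covariance,
         annulus_count = annulus_count,
         annulus_measure = annulus_count * a_cell,
         delta_h = delta_h, grid_n = grid_n,
         domain = pattern$domain, time = pattern$time, n = N),
    class = "pair_statistics"
  )
}

#' @export
print.pair_statistics <- function(x, ...) {
  cat(sprintf(
    "pair statistics: %d radial bins of width %g, raster %d^2, t = %g\n",
    length(x$bin_mid), x$delta_h, x$grid_n, x$time))
  cat("  densities:", paste(signif(x$densities, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Serialise summary statistics
#'
#' Writes the radially binned pair densities and covariances as CSV
#' (`bin_left, bin_right, pair, pair_density, covariance`) with a JSON
#' sidecar (`<path>.json`) carrying densities and estimator metadata.
#'
#' @param stats a [pair_statistics()] object.
#' @param path CSV output path.
#' @return invisibly, `path`.
#' @export
write_statistics <- function(stats, path) {
  stopifnot(inherits(stats, "pair_statistics"))
  S <- length(stats$densities)
  nb <- length(stats$bin_mid)
  rows <- do.call(rbind, lapply(seq_len(S), function(i) {
    do.call(rbind, lapply(seq_len(S), function(j) {
      data.frame(bin_left = stats$bin_edges[seq_len(nb)],
                 bin_right = stats$bin_edges[seq_len(nb) + 1L],
                 pair = sprintf("%d%d", i, j),
                 pair_density = stats$pair_density[, i, j],
                 covariance = stats$covariance[, i, j])
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  meta <- list(densities = stats$densities, n = stats$n,
               delta_h = stats$delta_h, grid_n = stats$grid_n,
               domain = stats$domain, time = stats$time)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
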