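#' Initial cell configurations
#'
#' The comparison experiments start from one of three initial cell
#' configurations (ICCs) holding the same per-type cell counts but different
#' spatial structure:
#'
#' * `icc1`: both s1 (producers) and s2 (non-producers) uniformly random.
#' * `icc2`: s1 clustered, s2 uniformly random.
#' * `icc3`: both types clustered (independently).
#'
#' Clustered types are placed by a fixed-count Thomas-like construction:
#' `n_clusters` parent centres drawn uniformly on the domain, each cell
#' assigned to a parent uniformly at random, then offset by an isotropic
#' Gaussian of standard deviation `cluster_sd` and wrapped periodically.
#' The construction is fixed-count (not Poisson-count) so that all three
#' configurations hold exactly the same number of cells of each type.
#'
#' @param kind one of `"icc1"`, `"icc2"`, `"icc3"`.
#' @param n_cells length-2 integer vector: cells of type s1 and s2.
#' @param n_clusters parent clusters per clustered type.
#' @param cluster_sd within-cluster Gaussian scatter (model length units).
#' @param domain length-2 periodic domain `(Lx, Ly)`.
#' @return an object of class `icc_config`.
#' @examples
#' cfg <- icc_config("icc2", n_cells = c(200, 200))
#' pp <- generate_icc(cfg, seed = 1)
#' pp
#' @export
icc_config <- function(kind = c("icc1", "icc2", "icc3"),
                       n_cells = c(200L, 200L),
                       n_clusters = 8L, cluster_sd = 40,
                       domain = c(1000, 1000)) {
  kind <- match.arg(kind)
  stopifnot(length(n_cells) == 2L, all(n_cells >= 0),
            length(domain) == 2L, all(domain > 0))
  if (kind != "icc1" && (!is.numeric(cluster_sd) || cluster_sd <= 0)) {
    stop("`cluster_sd` must be positive for a clustered configuration",
         call. = FALSE)
  }
  if (kind != "icc1" && (!is.numeric(n_clusters) || n_clusters < 1)) {
    stop("`n_clusters` must be >= 1 for a clustered configuration",
         call. = FALSE)
  }
  structure(
    list(kind = kind, n_cells = as.integer(n_cells),
         n_clusters = as.integer(n_clusters),
         cluster_sd = as.numeric(cluster_sd), domain = as.numeric(domain)),
    class = "icc_config"
  )
}

place_uniform <- function(n, domain) {
  cbind(stats::runif(n, 0, domain[1]), stats::runif(n, 0, domain[2]))
}

place_clustered <- function(n, n_clusters, cluster_sd, domain) {
  centres <- place_uniform(n_clusters, domain)
  parent <- sample.int(n_clusters, n, replace = TRUE)
  xy <- centres[parent, , drop = FALSE] +
    matrix(stats::rnorm(2 * n, sd = cluster_sd), ncol = 2)
  cbind(wrap_coord(xy[, 1], domain[1]), wrap_coord(xy[, 2], domain[2]))
}

#' Generate an initial cell configuration
#'
#' @param config an [icc_config()].
#' @param seed integer seed; the result is deterministic given the seed.
#' @return a [point_pattern()] at time 0.
#' @export
generate_icc <- function(config, seed = 1L) {
  stopifnot(inherits(config, "icc_config"))
  set.seed(seed)
  clustered <- switch(config$kind,
                      icc1 = c(FALSE, FALSE),
                      icc2 = c(TRUE, FALSE),
                      icc3 = c(TRUE, TRUE))
  xy <- lapply(1:2, function(i) {
    n <- config$n_cells[i]
    if (n == 0L) return(matrix(numeric(0), ncol = 2))
    if (clustered[i]) {
      place_clustered(n, config$n_clusters, config$cluster_sd, config$domain)
    } else {
      place_uniform(n, config$domain)
    }
  })
  point_pattern(x = c(xy[[1]][, 1], xy[[2]][, 1]),
                y = c(xy[[1]][, 2], xy[[2]][, 2]),
                mark = rep(1:2, times = config$n_cells),
                domain = config$domain, time = 0)
}
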