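# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths (direct formulas, O(N^2) sums, simple
# generators) so that agreement is evidence, not tautology.

# O(N^2) pair-count histogram with minimum-image distances, computed on the
# raster-quantised positions so it reproduces the FFT estimator's discrete
# geometry exactly.
brute_pair_density <- function(pattern, mark_i, mark_j, delta_h, grid_n,
                               r_max) {
  h <- pattern$domain[1] / grid_n
  qx <- (floor(pattern$x / h) + 0.5) * h
  qy <- (floor(pattern$y / h) + 0.5) * h
  ii <- which(pattern$mark == mark_i)
  jj <- which(pattern$mark == mark_j)
  dx <- outer(qx[ii], qx[jj], "-")
  dx <- abs(dx - pattern$domain[1] * round(dx / pattern$domain[1]))
  dy <- outer(qy[ii], qy[jj], "-")
  dy <- abs(dy - pattern$domain[2] * round(dy / pattern$domain[2]))
  r <- sqrt(dx^2 + dy^2)
  if (mark_i == mark_j) {
    same <- outer(ii, jj, "==")
    r <- r[!same]          # drop self-pairs
  }
  nbins <- ceiling(r_max / delta_h)
  counts <- tabulate(pmin(floor(r / delta_h) + 1L, nbins + 1L),
                     nbins = nbins + 1L)[seq_len(nbins)]
  counts
}

# fixed-seed homogeneous Poisson pattern of a single mark
poisson_pattern <- function(lambda, domain = c(1000, 1000), seed = 1L) {
  set.seed(seed)
  n <- rpois(1, lambda * prod(domain))
  point_pattern(runif(n, 0, domain[1]), runif(n, 0, domain[2]),
                rep(1L, n), domain = domain)
}

# Poisson-count Thomas cluster process (parents Poisson(kappa*A), offspring
# Poisson(mu) per parent, isotropic Gaussian scatter, periodic wrap)
thomas_pattern <- function(kappa, mu, sigma_c, domain = c(1000, 1000),
                           seed = 1L) {
  set.seed(seed)
  np <- rpois(1, kappa * prod(domain))
  px <- runif(np, 0, domain[1]); py <- runif(np, 0, domain[2])
  noff <- rpois(np, mu)
  x <- rep(px, noff) + rnorm(sum(noff), sd = sigma_c)
  y <- rep(py, noff) + rnorm(sum(noff), sd = sigma_c)
  point_pattern(x %% domain[1], y %% domain[2], rep(1L, length(x)),
                domain = domain)
}

# parameters with every process switched off except those supplied
bare_params <- function(b1 = 0, b11 = 0, b12 = 0, c = 0, sigma_B = 25,
                        sigma_C = 100, m1 = 0, m2 = 0, sigma_M = 25,
                        delta1 = 0, delta2 = 0, ell = 1) {
  model_params(B1 = gaussian_kernel(b1, sigma_B),
               B11 = gaussian_kernel(b11, sigma_B),
               B12 = gaussian_kernel(b12, sigma_B),
               C = gaussian_kernel(c, sigma_C),
               M1 = if (m1 > 0) gaussian_kernel(m1, sigma_M) else NULL,
               M2 = if (m2 > 0) gaussian_kernel(m2, sigma_M) else NULL,
               delta1 = delta1, delta2 = delta2, ell = ell)
}

# mean per-type counts over a small ensemble of trajectories
ensemble_final_counts <- function(pattern0, params, t_end, n_reps,
                                  base_seed = 1L) {
  vapply(seq_len(n_reps), function(r) {
    tr <- simulate_stpp(pattern0, params, t_end = t_end,
                        record_times = c(pattern0$time, t_end),
                        seed = base_seed + r - 1L)
    sum(tr$counts[nrow(tr$counts), ])
  }, numeric(1))
}
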