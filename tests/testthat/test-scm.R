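# helper: a synthetic pair_statistics object with a prescribed covariance
# profile, bypassing the estimator
synthetic_stats <- function(cov_fun, densities = c(2e-4, 2e-4),
                            delta_h = 2, r_max = 400) {
  edges <- seq(0, r_max, by = delta_h)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(mid)
  cov <- array(0, dim = c(nb, 2, 2))
  v <- cov_fun(mid)
  for (i in 1:2) for (j in 1:2) cov[, i, j] <- v
  pd <- cov + outer(rep(1, nb), outer(densities, densities))
  structure(list(densities = densities, bin_edges = edges, bin_mid = mid,
                 pair_density = pd, covariance = cov,
                 annulus_count = rep(1L, nb),
                 annulus_measure = rep(delta_h, nb),
                 delta_h = delta_h, grid_n = NA_integer_,
                 domain = c(1000, 1000), time = 0, n = densities * 1e6),
            class = "pair_statistics")
}

test_that("binned covariance transforms match the Gaussian closed form", {
  sigma <- 25
  st <- synthetic_stats(function(r) kernel_eval(gaussian_kernel(1, sigma), r))
  k <- seq(0, 0.2, length.out = 41)
  sp <- covariance_spectrum(st$covariance[, 1, 1], st$bin_edges, k)
  expect_equal(sp, exp(-sigma^2 * k^2 / 2), tolerance = 2e-3)
  # zero covariance gives the zero spectrum
  expect_equal(covariance_spectrum(rep(0, 10), seq(0, 10), k), rep(0, 41))
})

test_that("initial states map measured cumulants into solver space", {
  params <- model_params()
  grid <- default_spectral_grid(params, n = 129)
  st0 <- synthetic_stats(function(r) 0)
  s <- scm_initial_state(st0, grid, params)
  expect_equal(s$q, c(2e-4, 2e-4))
  expect_equal(s$p, c(0, 0))
  expect_equal(s$g11, numeric(129))
  # Gaussian covariance profile: spectrum is the Gaussian closed form
  stg <- synthetic_stats(function(r) kernel_eval(gaussian_kernel(1, 30), r))
  sg <- scm_initial_state(stg, grid, params)
  expect_equal(sg$g11, exp(-30^2 * grid$k^2 / 2), tolerance = 2e-3)
  # round trip: reconstructing the initial solution returns the measured
  # densities exactly and the covariance within transform tolerance
  sol0 <- scm_solve(sg, params, grid, t_grid = 0)
  rec <- scm_reconstruct(sol0, r = stg$bin_mid[stg$bin_mid < 100])
  expect_identical(rec$u[1, ], stg$densities)
  truth <- kernel_eval(gaussian_kernel(1, 30),
                       stg$bin_mid[stg$bin_mid < 100])
  expect_lt(max(abs(rec$covariance[1, , 1] - truth)) / max(truth), 5e-3)
})

test_that("the right-hand side reduces correctly in limiting regimes", {
  params <- model_params(delta1 = 0, delta2 = 0)
  grid <- default_spectral_grid(params, n = 65)
  q0 <- 3e-4
  s <- scm_initial_state(grid = grid, params = params, q0 = c(q0, 0))
  d <- scm_rhs(s, params, grid)
  # producers alone, no covariance: growth from autocrine + facilitated
  # birth; everything else still
  expect_equal(d$q[1], 0.001 * q0 + 0.025 * 100 * q0^2)
  expect_equal(d$q[2], 0)
  expect_equal(d$p, c(0, 0))
  expect_equal(d$W11, 0)

  # death-only: every spectral covariance mode decays at delta_i + delta_j
  pd <- bare_params(delta1 = 0.03, delta2 = 0.07)
  sd0 <- scm_initial_state(grid = grid, params = pd, q0 = c(1e-4, 1e-4))
  sd0$g11 <- exp(-grid$k^2); sd0$g12 <- 1 + grid$k; sd0$g22 <- rep(2, 65)
  dd <- scm_rhs(sd0, pd, grid)
  expect_equal(dd$g11, -2 * 0.03 * sd0$g11)
  expect_equal(dd$g12, -(0.03 + 0.07) * sd0$g12)
  expect_equal(dd$g22, -2 * 0.07 * sd0$g22)

  # movement-only: densities and corrections are untouched
  pm <- bare_params(m1 = 0.1, m2 = 0.2)
  sm <- scm_initial_state(grid = grid, params = pm, q0 = c(1e-4, 2e-4))
  sm$g11 <- exp(-grid$k^2)
  dm <- scm_rhs(sm, pm, grid)
  expect_equal(dm$q, c(0, 0))
  expect_equal(dm$p, c(0, 0))
  # jumps redistribute covariance without creating mass at k = 0
  expect_equal(dm$g11[1], 0, tolerance = 1e-12)
})

test_that("integration matches analytic ODE oracles", {
  t_grid <- seq(0, 400, by = 50)
  # pure autocrine growth: q1 = q0 exp(b1 t), correction identically zero
  pa <- bare_params(b1 = 0.004)
  grid <- spectral_grid(0.4, 65)
  sa <- scm_initial_state(grid = grid, params = pa, q0 = c(2e-4, 1e-4))
  sola <- scm_solve(sa, pa, grid, t_grid)
  expect_equal(sola$q[, 1], 2e-4 * exp(0.004 * t_grid), tolerance = 1e-7)
  expect_equal(sola$p, matrix(0, length(t_grid), 2))

  # full mean-field growth: Bernoulli closed form
  params <- model_params()
  mf <- mfpm_solve(c(2e-4, 2e-4), params, t_grid)
  a <- 0.001; b <- 2.5; q0 <- 2e-4
  bern <- a * q0 * exp(a * t_grid) / (a + b * q0 * (1 - exp(a * t_grid)))
  expect_equal(mf[, "q1"], bern, tolerance = 1e-6, ignore_attr = TRUE)

  # death-only spectral decay: g~(t,k) = G(k) exp(-2 delta t)
  pd <- bare_params(delta1 = 0.01, delta2 = 0.01)
  sdec <- scm_initial_state(grid = grid, params = pd, q0 = c(1e-4, 1e-4))
  G <- exp(-400 * grid$k^2)
  sdec$g11 <- G
  sold <- scm_solve(sdec, pd, grid, seq(0, 100, by = 25))
  for (it in 1:5) {
    expect_equal(sold$g11[it, ], G * exp(-2 * 0.01 * (it - 1) * 25),
                 tolerance = 1e-6)
  }
})

test_that("mean-field equations honour their structural special cases", {
  t_grid <- seq(0, 100, by = 20)
  # no facilitation of s2: its density is frozen
  p0 <- bare_params(b1 = 0.002, b11 = 0.02, c = 100)
  mf <- mfpm_solve(c(2e-4, 3e-4), p0, t_grid)
  expect_equal(mf[, "q2"], rep(3e-4, 6), ignore_attr = TRUE)
  # a death rate equal to the growth rate at t = 0 freezes q1
  params <- model_params()
  q10 <- 2e-4
  d1 <- 0.001 + 2.5 * q10
  pf <- with_death_rates(params, d1, 0)
  mff <- mfpm_solve(c(q10, 1e-4), pf, t_grid)
  expect_lt(abs(mff[2, "q1"] - q10) / q10, 1e-3)
  # SCM density components equal MFPM when reconstructed in the mean-field
  # limit (the q-equations are shared)
  grid <- spectral_grid(0.4, 65)
  st <- scm_initial_state(grid = grid, params = params, q0 = c(2e-4, 2e-4))
  sol <- scm_solve(st, params, grid, t_grid)
  mfq <- mfpm_solve(c(2e-4, 2e-4), params, t_grid)
  rec <- scm_reconstruct(sol, mfpm_limit = TRUE)
  expect_equal(rec$u[, 1], unname(mfq[, "q1"]), tolerance = 1e-6)
})

test_that("the density correction scales as the square of eps", {
  # same measured structure, increasing interaction length-scale ell:
  # |u - q| must shrink as eps^2 = 1/ell^2 (up to the eps-dependence of the
  # initial spectrum, which vanishes as eps -> 0)
  st <- synthetic_stats(function(r) 5e-7 * exp(-r^2 / (2 * 40^2)))
  t_grid <- c(0, 100)
  gap <- vapply(c(1, 2, 10), function(ell) {
    params <- model_params(ell = ell)
    grid <- default_spectral_grid(params, n = 257)
    sol <- scm_solve(scm_initial_state(st, grid, params), params, grid,
                     t_grid)
    abs(sol$u[2, 1] - sol$q[2, 1])
  }, numeric(1))
  ratio21 <- gap[2] / gap[1]
  ratio31 <- gap[3] / gap[1]
  expect_lt(ratio21, 0.5)   # ~ (1/2)^2 = 0.25 with init-spectrum drift
  expect_gt(ratio21, 0.1)
  expect_lt(ratio31, 0.02)  # ~ (1/10)^2 = 0.01
  expect_gt(ratio31, 0.002)
})

test_that("solutions are robust to doubling the spectral resolution", {
  params <- model_params()
  st <- synthetic_stats(function(r) 5e-7 * exp(-r^2 / (2 * 40^2)))
  t_grid <- seq(0, 200, by = 50)
  u_by_n <- lapply(c(129, 257), function(n) {
    grid <- default_spectral_grid(params, n = n)
    scm_solve(scm_initial_state(st, grid, params), params, grid, t_grid)$u
  })
  expect_lt(max(abs(u_by_n[[2]] - u_by_n[[1]]) / u_by_n[[2]]), 0.005)
})

test_that("degenerate integration requests are handled", {
  params <- model_params()
  grid <- spectral_grid(0.4, 33)
  st <- scm_initial_state(grid = grid, params = params, q0 = c(1e-4, 1e-4))
  expect_error(scm_solve(st, params, grid, t_grid = c(5, 10)), "start")
  sol <- scm_solve(st, params, grid, t_grid = 0)
  expect_equal(sol$u[1, ], c(1e-4, 1e-4))
  expect_equal(nrow(mfpm_solve(c(1e-4, 2e-4), params, 0)), 1)
})
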