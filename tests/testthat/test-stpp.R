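test_that("per-cell rates follow the process table", {
  # two producers at a known distance: each one's facilitated-birth rate is
  # b11 * C(r), so its total rate is b1 + b11 C(r) + delta1
  params <- bare_params(b1 = 0.002, b11 = 0.03, c = 100, delta1 = 0.004)
  r_star <- 120
  pp <- point_pattern(c(500, 500 + r_star), c(500, 500), c(1L, 1L),
                      domain = c(1000, 1000))
  rc <- per_cell_rates(pp, params)
  Cr <- kernel_eval(params$C, r_star)
  expect_equal(rc$phi, rep(Cr, 2), tolerance = 1e-14)
  expect_equal(rc$rates, rep(0.002 + 0.03 * Cr + 0.004, 2))
  expect_equal(rc$total, sum(rc$rates))

  # periodic wrap: the same pair separated across the boundary
  pp2 <- point_pattern(c(10, 1000 - (r_star - 10)), c(500, 500), c(1L, 1L),
                       domain = c(1000, 1000))
  expect_equal(per_cell_rates(pp2, params)$phi, rc$phi)

  # a lone non-producer receives nothing and only carries death/movement
  params2 <- bare_params(b12 = 0.05, c = 100, delta2 = 0.007, m2 = 0.01)
  lone <- point_pattern(5, 5, 2L, domain = c(1000, 1000))
  rc2 <- per_cell_rates(lone, params2)
  expect_equal(rc2$phi, 0)
  expect_equal(rc2$rates, 0.007 + 0.01)

  # death rates are density independent: same for crowded and lone cells
  params3 <- bare_params(delta1 = 0.02)
  crowd <- generate_icc(icc_config("icc3", n_cells = c(50, 0)), seed = 1)
  expect_equal(per_cell_rates(crowd, params3)$rates, rep(0.02, 50))
})

test_that("simulation with all rates zero leaves the pattern unchanged", {
  pp <- generate_icc(icc_config("icc1", n_cells = c(30, 30)), seed = 1)
  tr <- simulate_stpp(pp, bare_params(), t_end = 100,
                      record_times = c(0, 50, 100), seed = 1)
  expect_equal(tr$n_events, 0)
  expect_true(all(tr$counts[, 1] == 30 & tr$counts[, 2] == 30))
  expect_equal(tr$final$x, pp$x)
})

test_that("trajectories are deterministic given the seed", {
  params <- model_params()
  pp <- generate_icc(icc_config("icc2", n_cells = c(80, 80)), seed = 1)
  a <- simulate_stpp(pp, params, t_end = 150, record_times = c(0, 75, 150),
                     seed = 11)
  b <- simulate_stpp(pp, params, t_end = 150, record_times = c(0, 75, 150),
                     seed = 11)
  expect_identical(a$counts, b$counts)
  expect_identical(a$final$x, b$final$x)
  c <- simulate_stpp(pp, params, t_end = 150, record_times = c(0, 75, 150),
                     seed = 12)
  expect_false(identical(a$final$x, c$final$x))
})

test_that("movement-only dynamics conserve per-type counts exactly", {
  params <- bare_params(m1 = 0.2, m2 = 0.2)
  pp <- generate_icc(icc_config("icc1", n_cells = c(60, 40)), seed = 2)
  tr <- simulate_stpp(pp, params, t_end = 60,
                      record_times = seq(0, 60, by = 10), seed = 3)
  expect_gt(tr$n_events, 0)
  expect_true(all(tr$counts[, 1] == 60L))
  expect_true(all(tr$counts[, 2] == 40L))
  # positions moved but remain on the domain
  expect_false(identical(sort(tr$final$x), sort(pp$x)))
  expect_true(all(tr$final$x >= 0 & tr$final$x < 1000))
})

test_that("incremental rate cache matches a from-scratch recomputation", {
  # movement + facilitation keeps the facilitation sums churning; with the
  # periodic refresh disabled, the incrementally maintained cache after
  # thousands of events must agree with per_cell_rates() on the final state
  params <- bare_params(b1 = 0.005, b11 = 0.05, b12 = 0.05, c = 100,
                        delta1 = 0.005, delta2 = 0.005, m1 = 0.3, m2 = 0.3)
  pp <- generate_icc(icc_config("icc2", n_cells = c(60, 60)), seed = 4)
  tr <- simulate_stpp(pp, params, t_end = 150, record_times = c(0, 150),
                      seed = 5, refresh_every = 1000000L)
  expect_gt(tr$n_events, 3000)
  fresh <- per_cell_rates(tr$final, params)
  expect_equal(tr$final_cache$phi, fresh$phi, tolerance = 1e-9)
  expect_equal(tr$final_cache$total, fresh$total, tolerance = 1e-9)
})

test_that("waiting times on a frozen-rate configuration are exponential", {
  # movement-only with c = 0: the global rate N * m never changes, so
  # inter-event gaps are iid Exponential(N m)
  params <- bare_params(m1 = 0.5, m2 = 0.5)
  pp <- generate_icc(icc_config("icc1", n_cells = c(100, 100)), seed = 6)
  tr <- simulate_stpp(pp, params, t_end = 30, record_times = c(0, 30),
                      seed = 7, store_event_times = TRUE)
  gaps <- diff(c(0, tr$event_times))
  expect_gt(length(gaps), 1500)
  ks <- stats::ks.test(gaps, "pexp", rate = 200 * 0.5)
  expect_gt(ks$p.value, 0.01)
})

test_that("pure death matches the exponential decay oracle", {
  params <- bare_params(delta1 = 0.01, delta2 = 0.01)
  pp <- generate_icc(icc_config("icc1", n_cells = c(100, 100)), seed = 8)
  finals <- ensemble_final_counts(pp, params, t_end = 50, n_reps = 60,
                                  base_seed = 100)
  expected <- 200 * exp(-0.01 * 50)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("death-only dynamics erase spatial covariance", {
  # thinning a cluster pattern uniformly shrinks its covariance towards 0
  cfg <- icc_config("icc3", n_cells = c(150, 150), n_clusters = 5,
                    cluster_sd = 20)
  pp <- generate_icc(cfg, seed = 9)
  params <- bare_params(delta1 = 0.02, delta2 = 0.02)
  short_cov <- function(pat) {
    st <- pair_statistics(pat, grid_n = 128, r_max = 100)
    mean(st$covariance[st$bin_mid < 30, 1, 1])
  }
  c0 <- short_cov(pp)
  cT <- mean(vapply(1:12, function(r) {
    tr <- simulate_stpp(pp, params, t_end = 100, seed = 200 + r)
    short_cov(tr$final)
  }, numeric(1)))
  expect_gt(c0, 0)
  expect_lt(cT, 0.3 * c0)
})

test_that("ensembles share the initial configuration and order statistics", {
  params <- bare_params(m1 = 0.05, m2 = 0.05)
  cfg <- icc_config("icc1", n_cells = c(40, 40))
  ens <- simulate_ensemble(cfg, params, t_end = 40,
                           record_times = c(0, 20, 40), n_reps = 4,
                           base_seed = 1, icc_seed = 3)
  # movement-only: every replicate keeps its counts, so the band is flat
  expect_true(all(ens$min == ens$max))
  expect_true(all(ens$min <= ens$mean & ens$mean <= ens$max))
  expect_identical(ens$pattern0, generate_icc(cfg, seed = 3))
  # one replicate reduces to plain simulation
  one <- simulate_ensemble(ens$pattern0, params, t_end = 40,
                           record_times = c(0, 40), n_reps = 1,
                           base_seed = 5)
  direct <- simulate_stpp(ens$pattern0, params, t_end = 40,
                          record_times = c(0, 40), seed = 5)
  expect_identical(one$trajectories[[1]]$counts, direct$counts)
})

test_that("the population cap aborts gracefully", {
  params <- bare_params(b1 = 0.5)
  pp <- generate_icc(icc_config("icc1", n_cells = c(50, 0)), seed = 1)
  expect_warning(
    tr <- simulate_stpp(pp, params, t_end = 100, record_times = c(0, 100),
                        seed = 1, cap = 120),
    "cap")
  expect_true(tr$aborted)
})
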