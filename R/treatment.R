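#' Mean-field-informed treatment doses
#'
#' Death rates that zero the mean-field density derivatives at the treatment
#' time, given the measured producer density \eqn{\hat u^{(1)}_{1,T}}:
#' \eqn{\delta_1 = b_1 + b_{11} c\, \hat u_1} and
#' \eqn{\delta_2 = b_{12} c\, \hat u_1}.
#'
#' @param u1_hat measured density of s1 (producers) at treatment time.
#' @param params a [model_params()] object.
#' @return named numeric vector `c(delta1, delta2)`.
#' @examples
#' mfpm_dose(2e-4, model_params())   # delta1 = 0.0015, delta2 = 0.001
#' @export
mfpm_dose <- function(u1_hat, params) {
  stopifnot(u1_hat >= 0, inherits(params, "scm_model"))
  c_int <- params$C$integral
  c(delta1 = params$B1$integral + params$B11$integral * c_int * u1_hat,
    delta2 = params$B12$integral * c_int * u1_hat)
}

#' Spatial-structure integrals from measured covariances
#'
#' Computes \eqn{\hat W_{11}} and \eqn{\hat W_{12}} — the spectral integrals
#' that feed the correction-density equations — from a measured covariance:
#' the binned covariances are transformed to \eqn{\hat{\tilde g}_{ij}(k)}
#' (the same scaling map as [scm_initial_state()]) and integrated against
#' the growth-factor kernel spectrum,
#' \eqn{\hat W_{1j} = 2\pi b_{1j} \int_0^\infty k\, \hat{\tilde g}_{1j}(k)
#' \tilde C(k)\, dk}.
#'
#' @param stats a [pair_statistics()] object measured at the treatment time.
#' @param params a [model_params()] object.
#' @param grid a [spectral_grid()].
#' @return named numeric vector `c(W11, W12)`.
#' @export
w_hat_from_stats <- function(stats, params, grid) {
  state <- scm_initial_state(stats, grid, params)
  sp <- scm_spectra(params, grid)
  c(W11 = w_integral(sp, state$g11, sp$b11),
    W12 = w_integral(sp, state$g12, sp$b12))
}

#' Spatially informed treatment doses
#'
#' Death rates that zero the corrected growth expressions
#' \eqn{H_{q_i} + \epsilon^2 H_{p_i}} at the treatment time, with the
#' correction densities set to zero upon measuring:
#' \eqn{\delta_1 = (b_1 \hat u_1 + b_{11} c\, \hat u_1^2 +
#' \epsilon^2 \hat W_{11}) / \hat u_1} and
#' \eqn{\delta_2 = (b_{12} c\, \hat u_1 \hat u_2 +
#' \epsilon^2 \hat W_{12}) / \hat u_2}; equivalently the mean-field dose
#' plus \eqn{\epsilon^2 \hat W / \hat u}. A noisy negative covariance can
#' yield a negative dose; it is floored at zero with a warning, since the
#' simulator's death rates cannot be negative.
#'
#' @param u1_hat,u2_hat measured densities at treatment time (`u1_hat > 0`;
#'   `u2_hat > 0` unless `W12 = 0`).
#' @param W11_hat,W12_hat measured spatial-structure integrals, see
#'   [w_hat_from_stats()].
#' @param params a [model_params()] object.
#' @return named numeric vector `c(delta1, delta2)`.
#' @export
scm_dose <- function(u1_hat, u2_hat, W11_hat, W12_hat, params) {
  stopifnot(inherits(params, "scm_model"), u1_hat > 0)
  if (u2_hat <= 0) {
    if (W12_hat != 0) {
      stop("SCM dose for s2 undefined: zero density with nonzero W12",
           call. = FALSE)
    }
    u2_hat <- 1  # dose reduces to b12 c u1 regardless
  }
  eps2 <- params$eps^2
  mf <- mfpm_dose(u1_hat, params)
  d <- c(delta1 = unname(mf["delta1"]) + eps2 * W11_hat / u1_hat,
         delta2 = unname(mf["delta2"]) + eps2 * W12_hat / u2_hat)
  if (any(d < 0)) {
    warning("negative derived dose floored at 0", call. = FALSE)
    d <- pmax(d, 0)
  }
  d
}

#' Apply per-replicate treatment doses and continue the simulation
#'
#' Runs an ensemble to the treatment time `T`, then, for each replicate,
#' measures the densities and spatial-structure integrals from that
#' replicate's own pattern at `T`, derives its individual doses (mean-field-
#' or spatially informed), and continues that replicate's stochastic
#' trajectory on `[T, t_end]` with the derived death rates switched on.
#' The matching deterministic solutions (mean-field and spatial-cumulant,
#' initialised from the shared initial pattern and restarted at `T` with the
#' ensemble-median doses) are returned for comparison.
#'
#' @param pattern0 shared initial [point_pattern()] or an [icc_config()].
#' @param params a [model_params()] object (death rates before `T` are taken
#'   from it, normally zero).
#' @param T_treat treatment time.
#' @param t_end final time (> `T_treat`).
#' @param method `"mfpm"` or `"scm"` dose derivation.
#' @param n_reps replicates.
#' @param base_seed first replicate's seed; replicate `r` uses
#'   `base_seed + r - 1` before and a derived seed after treatment.
#' @param record_times record grid over the whole run (must contain
#'   `T_treat`); defaults to 11 equally spaced times.
#' @param grid_n,delta_h estimator settings used at `T` (same defaults as
#'   [pair_statistics()]).
#' @param grid a [spectral_grid()]; defaults to [default_spectral_grid()].
#' @param icc_seed seed used to realise an `icc_config`.
#' @return An object of class `treated_ensemble`: `times`, per-replicate
#'   `densities` (time x type x rep), a `doses` data frame (one row per
#'   replicate: measured inputs and derived doses; replicates extinct in a
#'   dosed type at `T` are flagged and excluded from dose statistics),
#'   `method`, and the deterministic `mfpm` / `scm` density trajectories
#'   under the median doses.
#' @export
treat_and_continue <- function(pattern0, params, T_treat, t_end,
                               method = c("scm", "mfpm"),
                               n_reps = 30L, base_seed = 1L,
                               record_times = NULL,
                               grid_n = 256L, delta_h = NULL,
                               grid = NULL, icc_seed = 1L) {
  method <- match.arg(method)
  stopifnot(t_end > T_treat)
  if (inherits(pattern0, "icc_config")) {
    pattern0 <- generate_icc(pattern0, seed = icc_seed)
  }
  if (is.null(grid)) grid <- default_spectral_grid(params)
  if (is.null(record_times)) {
    record_times <- sort(unique(c(seq(pattern0$time, t_end, length.out = 11L),
                                  T_treat)))
  }
  if (!any(abs(record_times - T_treat) < 1e-9)) {
    record_times <- sort(c(record_times, T_treat))
  }
  pre_times <- record_times[record_times <= T_treat + 1e-9]
  post_times <- record_times[record_times >= T_treat - 1e-9]
  A <- prod(pattern0$domain)

  nrec <- length(record_times)
  dens <- array(NA_real_, dim = c(nrec, 2, n_reps))
  doses <- data.frame(replicate = seq_len(n_reps), u1 = NA_real_,
                      u2 = NA_real_, W11 = NA_real_, W12 = NA_real_,
                      delta1 = NA_real_, delta2 = NA_real_,
                      excluded = FALSE)
  for (r in seq_len(n_reps)) {
    seed_r <- base_seed + r - 1L
    pre <- simulate_stpp(pattern0, params, t_end = T_treat,
                         record_times = pre_times, seed = seed_r)
    patT <- pre$final
    u1 <- estimate_density(patT, 1L)
    u2 <- estimate_density(patT, 2L)
    doses$u1[r] <- u1; doses$u2[r] <- u2
    if (u1 <= 0) {
      doses$excluded[r] <- TRUE
      d <- c(delta1 = 0, delta2 = 0)
    } else {
      if (method == "scm") {
        st <- pair_statistics(patT, delta_h = delta_h, grid_n = grid_n)
        W <- w_hat_from_stats(st, params, grid)
        doses$W11[r] <- W["W11"]; doses$W12[r] <- W["W12"]
        d <- scm_dose(u1, u2, W["W11"], W["W12"], params)
      } else {
        d <- mfpm_dose(u1, params)
      }
    }
    doses$delta1[r] <- d[1]; doses$delta2[r] <- d[2]
    post <- simulate_stpp(patT, with_death_rates(params, d[1], d[2]),
                          t_end = t_end, record_times = post_times,
                          seed = seed_r + 100003L)
    dens[match(round(pre$times, 9), round(record_times, 9)), , r] <-
      pre$counts / A
    dens[match(round(post$times, 9), round(record_times, 9)), , r] <-
      post$counts / A
  }

  ok <- !doses$excluded
  med <- c(stats::median(doses$delta1[ok]), stats::median(doses$delta2[ok]))

  # deterministic comparison under the median doses, restarted at T
  st0 <- pair_statistics(pattern0, delta_h = delta_h, grid_n = grid_n)
  state0 <- scm_initial_state(st0, grid, params)
  scm_pre <- scm_solve(state0, params, grid, t_grid = pre_times)
  params_post <- with_death_rates(params, med[1], med[2])
  stateT <- unpack_state(
    c(scm_pre$q[nrow(scm_pre$q), ], scm_pre$p[nrow(scm_pre$p), ],
      scm_pre$g11[nrow(scm_pre$g11), ], scm_pre$g12[nrow(scm_pre$g12), ],
      scm_pre$g22[nrow(scm_pre$g22), ]),
    t = T_treat, M = length(grid$k))
  scm_post <- scm_solve(stateT, params_post, grid, t_grid = post_times)
  mf_pre <- mfpm_solve(st0$densities, params, pre_times)
  mf_post <- mfpm_solve(mf_pre[nrow(mf_pre), 2:3], params_post, post_times)

  structure(
    list(times = record_times, densities = dens, doses = doses,
         method = method, median_dose = med, T_treat = T_treat,
         scm = rbind(cbind(time = scm_pre$times, scm_pre$u)[-length(pre_times), , drop = FALSE],
                     cbind(time = scm_post$times, scm_post$u)),
         mfpm = rbind(mf_pre[-nrow(mf_pre), , drop = FALSE], mf_post)),
    class = "treated_ensemble"
  )
}

#' @export
print.treated_ensemble <- function(x, ...) {
  cat(sprintf(
    "treated ensemble (%s doses): %d replicates, treatment applied mid-run\n",
    x$method, dim(x$densities)[3]))
  cat(sprintf("  median doses: delta1 = %.4g, delta2 = %.4g\n",
              x$median_dose[1], x$median_dose[2]))
  invisible(x)
}

#' Fraction of replicates whose subpopulation keeps growing after treatment
#'
#' @param treated a [treat_and_continue()] result.
#' @param mark subpopulation (default 2, the non-producers).
#' @param T_treat treatment time; defaults to the one stored in the run.
#' @return fraction of (non-excluded) replicates whose density of `mark` at
#'   the final time exceeds its value at the treatment time.
#' @export
fraction_growing <- function(treated, mark = 2L, T_treat = NULL) {
  stopifnot(inherits(treated, "treated_ensemble"))
  times <- treated$times
  if (is.null(T_treat)) T_treat <- treated$T_treat
  iT <- which.min(abs(times - T_treat))
  iE <- length(times)
  ok <- !treated$doses$excluded
  growing <- treated$densities[iE, mark, ok] > treated$densities[iT, mark, ok]
  mean(growing)
}
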