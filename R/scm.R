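#' Hankel spectrum of a radially binned covariance
#'
#' Converts a radially binned covariance estimate (piecewise constant over
#' annuli) into transform space. Each bin `[r0, r1)` contributes exactly
#' \eqn{2\pi u_{bin} (r_1 J_1(\kappa r_1) - r_0 J_1(\kappa r_0))/\kappa}
#' (and \eqn{\pi (r_1^2 - r_0^2) u_{bin}} at \eqn{\kappa = 0}), so no radial
#' re-quadrature is involved.
#'
#' @param values per-bin covariance values.
#' @param edges bin edges (length `length(values) + 1`).
#' @param k frequencies at which to evaluate.
#' @return numeric vector of spectrum values.
#' @export
covariance_spectrum <- function(values, edges, k) {
  stopifnot(length(edges) == length(values) + 1L)
  r0 <- edges[-length(edges)]
  r1 <- edges[-1]
  vapply(k, function(kk) {
    if (kk == 0) {
      sum(values * pi * (r1^2 - r0^2))
    } else {
      sum(values * 2 * pi * (r1 * besselJ(kk * r1, 1) -
                             r0 * besselJ(kk * r0, 1)) / kk)
    }
  }, numeric(1))
}

#' Initial state of the spatial cumulant model
#'
#' Builds the solver state from summary statistics measured on an initial
#' point pattern: the mean-field densities `q` are set to the measured
#' densities, the correction densities `p` start at zero, and the spectral
#' covariances \eqn{\tilde g_{ij}(k)} are the Hankel transforms of the
#' measured covariances under the scaling map
#' \eqn{g_{ij}(s) = \hat u^{(2)}_{ij}(s/\epsilon)/\epsilon^2} (the identity
#' when `eps = 1`), which evaluates to the covariance transform at
#' frequency \eqn{\epsilon k}.
#'
#' @param stats a [pair_statistics()] object (two marks), or `NULL` to build
#'   a state from explicit densities with zero covariance via `q0`.
#' @param grid a [spectral_grid()].
#' @param params a [model_params()] object.
#' @param q0 explicit length-2 densities (used when `stats` is `NULL`).
#' @return an object of class `scm_state` with fields `t`, `q`, `p`,
#'   `g11`, `g12`, `g22` (spectra on `grid$k`).
#' @export
scm_initial_state <- function(stats = NULL, grid, params, q0 = NULL) {
  stopifnot(inherits(grid, "spectral_grid"), inherits(params, "scm_model"))
  M <- length(grid$k)
  if (is.null(stats)) {
    stopifnot(is.numeric(q0), length(q0) == 2L, all(q0 >= 0))
    return(structure(list(t = 0, q = as.numeric(q0), p = c(0, 0),
                          g11 = numeric(M), g12 = numeric(M),
                          g22 = numeric(M)),
                     class = "scm_state"))
  }
  stopifnot(inherits(stats, "pair_statistics"),
            length(stats$densities) == 2L)
  if (any(stats$densities < 0)) stop("negative measured density",
                                     call. = FALSE)
  ke <- params$eps * grid$k
  structure(
    list(t = stats$time, q = stats$densities, p = c(0, 0),
         g11 = covariance_spectrum(stats$covariance[, 1, 1], stats$bin_edges,
                                   ke),
         g12 = covariance_spectrum(stats$covariance[, 1, 2], stats$bin_edges,
                                   ke),
         g22 = covariance_spectrum(stats$covariance[, 2, 2], stats$bin_edges,
                                   ke)),
    class = "scm_state"
  )
}

# kernel spectra and scalars used by the right-hand side
scm_spectra <- function(params, grid) {
  list(
    b1 = params$B1$integral, b11 = params$B11$integral,
    b12 = params$B12$integral, c = params$C$integral,
    m1 = move_rate(params, 1L), m2 = move_rate(params, 2L),
    d1 = params$delta1, d2 = params$delta2,
    B1t = kernel_spectrum(params$B1, grid),
    B11t = kernel_spectrum(params$B11, grid),
    B12t = kernel_spectrum(params$B12, grid),
    Ct = kernel_spectrum(params$C, grid),
    M1t = if (is.null(params$M1)) numeric(length(grid$k))
          else kernel_spectrum(params$M1, grid),
    M2t = if (is.null(params$M2)) numeric(length(grid$k))
          else kernel_spectrum(params$M2, grid),
    k = grid$k, w = grid$w
  )
}

# W_{1j} = b_{1j} * Int u2_{1j}(x) C(x) d^2x, evaluated spectrally.
# In the unnormalised transform convention used throughout (a~(0) = total
# integral, under which the covariance rate equations are exact), Parseval
# gives Int f g d^2x = (1/2pi) Int k f~(k) g~(k) dk.
w_integral <- function(sp, g, b) {
  b * sum(sp$w * sp$k * g * sp$Ct) / (2 * pi)
}

#' Time derivative of the spatial cumulant state
#'
#' The closed rate equations of the two-type growth-factor model: mean-field
#' densities `q`, correction densities `p` (sourced by the spectral
#' W-integrals \eqn{W_{1j} = 2\pi b_{1j}\int_0^\infty k\,\tilde g_{1j}(k)
#' \tilde C(k)\,dk}), and the spectral covariances \eqn{\tilde g_{ij}(k)},
#' which are local in `k`. Movement enters the covariance equations as
#' \eqn{(\tilde M - m)\tilde g} terms and leaves `q` and `p` untouched.
#'
#' @param state an `scm_state` (see [scm_initial_state()]).
#' @param params a [model_params()] object.
#' @param grid the [spectral_grid()] on which the state's spectra live.
#' @param spectra optional precomputed kernel spectra (internal reuse).
#' @return a list with the time derivatives `q`, `p`, `g11`, `g12`, `g22`
#'   and the current W-integrals `W11`, `W12`.
#' @export
scm_rhs <- function(state, params, grid, spectra = NULL) {
  sp <- if (is.null(spectra)) scm_spectra(params, grid) else spectra
  q1 <- state$q[1]; q2 <- state$q[2]
  p1 <- state$p[1]; p2 <- state$p[2]
  g11 <- state$g11; g12 <- state$g12; g22 <- state$g22
  W11 <- w_integral(sp, g11, sp$b11)
  W12 <- w_integral(sp, g12, sp$b12)
  cpC <- sp$c + sp$Ct
  dq1 <- sp$b1 * q1 + sp$b11 * sp$c * q1^2 - sp$d1 * q1
  dq2 <- sp$b12 * sp$c * q1 * q2 - sp$d2 * q2
  dp1 <- sp$b1 * p1 + W11 + 2 * sp$b11 * sp$c * q1 * p1 - sp$d1 * p1
  dp2 <- W12 + sp$b12 * sp$c * (q1 * p2 + q2 * p1) - sp$d2 * p2
  dg11 <- 2 * sp$B1t * (q1 + g11) + 2 * sp$B11t * q1 * cpC * (q1 + g11) -
    2 * sp$d1 * g11 + (2 * sp$M1t - 2 * sp$m1) * g11
  dg12 <- sp$B1t * g12 + sp$B11t * q1 * g12 * cpC +
    sp$B12t * (sp$c * q1 * g12 + sp$Ct * q2 * (q1 + g11)) -
    (sp$d1 + sp$d2) * g12 +
    (sp$M1t - sp$m1 + sp$M2t - sp$m2) * g12
  dg22 <- 2 * sp$B12t * (sp$c * q1 * (q2 + g22) + sp$Ct * q2 * g12) -
    2 * sp$d2 * g22 + (2 * sp$M2t - 2 * sp$m2) * g22
  list(q = c(dq1, dq2), p = c(dp1, dp2),
       g11 = dg11, g12 = dg12, g22 = dg22, W11 = W11, W12 = W12)
}

pack_state <- function(state) {
  c(state$q, state$p, state$g11, state$g12, state$g22)
}

unpack_state <- function(y, t, M) {
  structure(list(t = t, q = y[1:2], p = y[3:4],
                 g11 = y[4 + seq_len(M)], g12 = y[4 + M + seq_len(M)],
                 g22 = y[4 + 2 * M + seq_len(M)]),
            class = "scm_state")
}

#' Integrate the spatial cumulant model
#'
#' Adaptive, stiff-capable integration (lsoda) of the coupled
#' `(4 + 3 * |grid|)`-dimensional system of mean-field densities, correction
#' densities and spectral covariances, with dense output at `t_grid`.
#' A diagnostic warning is issued if any mean-field density falls below
#' `-atol` (the equations preserve positivity from non-negative data, so
#' this indicates integration trouble).
#'
#' @inheritParams scm_rhs
#' @param state0 initial `scm_state` (its `t` must equal `t_grid[1]`).
#' @param t_grid increasing output times.
#' @param rtol,atol integration tolerances.
#' @return An object of class `scm_solution`: `times`, `q`, `p`, `u`
#'   (`q + eps^2 p`, time x type), spectra arrays `g11`, `g12`, `g22`
#'   (time x |grid|), the `grid`, `params` and `eps`.
#' @examples
#' params <- model_params()
#' grid <- default_spectral_grid(params, n = 65)
#' st0 <- scm_initial_state(grid = grid, params = params, q0 = c(2e-4, 2e-4))
#' sol <- scm_solve(st0, params, grid, t_grid = seq(0, 100, by = 25))
#' sol$u
#' @export
scm_solve <- function(state0, params, grid, t_grid,
                      rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(state0, "scm_state"), inherits(grid, "spectral_grid"),
            all(diff(t_grid) > 0))
  if (abs(t_grid[1] - state0$t) > 1e-9) {
    stop("t_grid must start at the state's time", call. = FALSE)
  }
  M <- length(grid$k)
  eps <- params$eps
  if (length(t_grid) == 1L) {      # degenerate request: the initial state
    q <- matrix(state0$q, nrow = 1)
    p <- matrix(state0$p, nrow = 1)
    return(structure(
      list(times = t_grid, q = q, p = p, u = q + eps^2 * p,
           g11 = matrix(state0$g11, nrow = 1),
           g12 = matrix(state0$g12, nrow = 1),
           g22 = matrix(state0$g22, nrow = 1),
           grid = grid, params = params, eps = eps),
      class = "scm_solution"))
  }
  sp <- scm_spectra(params, grid)
  deriv <- function(t, y, parms) {
    st <- unpack_state(y, t, M)
    d <- scm_rhs(st, params, grid, spectra = sp)
    list(c(d$q, d$p, d$g11, d$g12, d$g22))
  }
  out <- deSolve::ode(y = pack_state(state0), times = t_grid, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("SCM integration failed; time reached: ", max(out[, 1]),
         call. = FALSE)
  }
  y <- unname(out[, -1, drop = FALSE])
  q <- y[, 1:2, drop = FALSE]
  p <- y[, 3:4, drop = FALSE]
  if (any(q < -atol)) {
    warning("mean-field density dropped below -atol: diagnostic failure",
            call. = FALSE)
  }
  eps <- params$eps
  structure(
    list(times = out[, 1], q = q, p = p, u = q + eps^2 * p,
         g11 = y[, 4 + seq_len(M), drop = FALSE],
         g12 = y[, 4 + M + seq_len(M), drop = FALSE],
         g22 = y[, 4 + 2 * M + seq_len(M), drop = FALSE],
         grid = grid, params = params, eps = eps),
    class = "scm_solution"
  )
}

#' @export
print.scm_solution <- function(x, ...) {
  cat(sprintf("SCM solution: %d times in [%g, %g], %d spectral nodes\n",
              length(x$times), min(x$times), max(x$times),
              length(x$grid$k)))
  invisible(x)
}

#' Integrate the mean-field population model
#'
#' The density equations alone:
#' \eqn{dq_1/dt = b_1 q_1 + b_{11} c\, q_1^2 - \delta_1 q_1},
#' \eqn{dq_2/dt = b_{12} c\, q_1 q_2 - \delta_2 q_2}.
#'
#' @param q0 length-2 initial densities.
#' @param params a [model_params()] object.
#' @param t_grid increasing output times.
#' @param rtol,atol integration tolerances.
#' @return a matrix with columns `time`, `q1`, `q2`.
#' @export
mfpm_solve <- function(q0, params, t_grid, rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(q0) == 2L, all(diff(t_grid) > 0))
  b1 <- params$B1$integral; b11c <- params$B11$integral * params$C$integral
  b12c <- params$B12$integral * params$C$integral
  d1 <- params$delta1; d2 <- params$delta2
  if (length(t_grid) == 1L) {
    out <- matrix(c(t_grid, q0), nrow = 1,
                  dimnames = list(NULL, c("time", "q1", "q2")))
    return(out)
  }
  deriv <- function(t, y, parms) {
    list(c(b1 * y[1] + b11c * y[1]^2 - d1 * y[1],
           b12c * y[1] * y[2] - d2 * y[2]))
  }
  out <- deSolve::ode(y = as.numeric(q0), times = t_grid, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("MFPM integration failed; time reached: ", max(out[, 1]),
         call. = FALSE)
  }
  colnames(out) <- c("time", "q1", "q2")
  out
}

#' Reconstruct densities and real-space covariances from an SCM solution
#'
#' Densities are \eqn{u^{(1)}_i(t) = q_i(t) + \epsilon^2 p_i(t)} (the
#' mean-field limit `q` alone when `mfpm_limit = TRUE`); covariances are
#' \eqn{u^{(2)}_{ij}(t, r) = \epsilon^2 g_{ij}(t, \epsilon r)}, materialised
#' by inverse Hankel transform of the stored spectra at the requested radii.
#' Higher-order terms of the expansion are dropped.
#'
#' @param solution an [scm_solve()] result.
#' @param r optional radii at which to evaluate covariances.
#' @param mfpm_limit return the mean-field densities (the `eps -> 0` limit).
#' @return a list with `times`, `u` (time x type densities) and, when `r` is
#'   given, `covariance`: an array time x length(r) x 3 for the ordered
#'   pairs (1,1), (1,2), (2,2).
#' @export
scm_reconstruct <- function(solution, r = NULL, mfpm_limit = FALSE) {
  stopifnot(inherits(solution, "scm_solution"))
  eps <- solution$eps
  u <- if (mfpm_limit) solution$q else solution$u
  res <- list(times = solution$times, u = u)
  if (!is.null(r)) {
    nt <- length(solution$times)
    cov <- array(0, dim = c(nt, length(r), 3),
                 dimnames = list(NULL, NULL, c("11", "12", "22")))
    for (it in seq_len(nt)) {
      cov[it, , 1] <- eps^2 * inverse_spectrum(solution$g11[it, ],
                                               solution$grid, eps * r)
      cov[it, , 2] <- eps^2 * inverse_spectrum(solution$g12[it, ],
                                               solution$grid, eps * r)
      cov[it, , 3] <- eps^2 * inverse_spectrum(solution$g22[it, ],
                                               solution$grid, eps * r)
    }
    res$covariance <- cov
  }
  res
}
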