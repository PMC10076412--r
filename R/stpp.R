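#' Facilitation sums and per-cell event rates
#'
#' For every cell, computes the growth-factor facilitation sum
#' \eqn{\Phi(x) = \sum_{x_3 \in s_1,\, x_3 \ne x} C(x - x_3)} (the kernel-
#' weighted amount of growth factor received from producer cells, excluding
#' the cell itself) with minimum-image periodic distances, and the resulting
#' per-cell total event rates:
#'
#' * s1 cell: `b1 + b11 * Phi + delta1 + m1`
#' * s2 cell: `b12 * Phi + delta2 + m2`
#'
#' @param pattern a [point_pattern()].
#' @param params a [model_params()] object.
#' @return a list with `phi` (per-cell facilitation sums), `rates` (per-cell
#'   total event rates) and `total` (their sum, the global Gillespie rate).
#' @export
per_cell_rates <- function(pattern, params) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(params, "scm_model"))
  n <- length(pattern$x)
  phi <- phi_from_scratch(pattern$x, pattern$y, pattern$mark, n,
                          pattern$domain, params$C)
  rates <- cell_rates(pattern$mark[seq_len(n)], phi, params)
  list(phi = phi, rates = rates, total = sum(rates))
}

# kernel value from (x0, y0) to points (xs, ys) with minimum-image wrap
kernel_to_point <- function(kern, x0, y0, xs, ys, domain) {
  dx <- xs - x0
  dx <- dx - domain[1] * round(dx / domain[1])
  dy <- ys - y0
  dy <- dy - domain[2] * round(dy / domain[2])
  kernel_eval(kern, sqrt(dx * dx + dy * dy))
}

phi_from_scratch <- function(x, y, mark, n, domain, C) {
  phi <- numeric(n)
  if (n == 0L || C$integral == 0) return(phi)
  s1 <- which(mark[seq_len(n)] == 1L)
  for (i in seq_len(n)) {
    src <- setdiff(s1, i)
    if (length(src)) {
      phi[i] <- sum(kernel_to_point(C, x[i], y[i], x[src], y[src], domain))
    }
  }
  phi
}

cell_rates <- function(mark, phi, params) {
  m1 <- move_rate(params, 1L); m2 <- move_rate(params, 2L)
  base <- c(params$B1$integral + params$delta1 + m1, params$delta2 + m2)
  fac <- c(params$B11$integral, params$B12$integral)
  base[mark] + fac[mark] * phi
}

#' Exact Gillespie simulation of the growth-factor point process
#'
#' Simulates the marked spatio-temporal point process defined by the model's
#' processes — autocrine birth of s1, facilitated birth of s1 and s2, density-
#' independent death, and random jumps — with the exact stochastic simulation
#' algorithm: exponential waiting times at the global rate, event selection
#' proportional to per-cell rates, and incremental rate updates after each
#' event. Daughters are placed at the parent position plus an isotropic
#' Gaussian displacement whose per-axis standard deviation is the width of
#' the corresponding dispersal kernel; jumps displace a cell by a draw from
#' its movement kernel. All positions wrap periodically.
#'
#' @param pattern0 initial [point_pattern()].
#' @param params a [model_params()] object.
#' @param t_end final time (>= `pattern0$time`).
#' @param record_times times at which to record the state; defaults to
#'   `c(pattern0$time, t_end)`.
#' @param seed integer seed; the trajectory is deterministic given the seed.
#' @param store_snapshots keep a full pattern copy at every record time.
#' @param store_event_times keep the times of all executed events.
#' @param cap hard population cap; exceeding it aborts with a partial
#'   trajectory (flagged in the result).
#' @param refresh_every recompute the facilitation sums and total rate from
#'   scratch every this many events, bounding floating-point drift of the
#'   incremental cache.
#' @return An object of class `stpp_trajectory`: `times`, `counts`
#'   (time x type matrix), `densities`, optional `snapshots`, `final`
#'   (pattern at `t_end`), `n_events`, `seed`, `aborted`.
#' @examples
#' pp <- generate_icc(icc_config("icc1", n_cells = c(50, 50)), seed = 1)
#' tr <- simulate_stpp(pp, model_params(), t_end = 50,
#'                     record_times = c(0, 25, 50), seed = 1)
#' tr$counts
#' @export
simulate_stpp <- function(pattern0, params, t_end,
                          record_times = NULL, seed = 1L,
                          store_snapshots = FALSE, store_event_times = FALSE,
                          cap = 1e6, refresh_every = 5000L) {
  stopifnot(inherits(pattern0, "point_pattern"), inherits(params, "scm_model"),
            t_end >= pattern0$time)
  if (is.null(record_times)) record_times <- c(pattern0$time, t_end)
  record_times <- sort(unique(as.numeric(record_times)))
  if (any(record_times < pattern0$time - 1e-12) ||
      any(record_times > t_end + 1e-12)) {
    stop("record_times must lie in [pattern0$time, t_end]", call. = FALSE)
  }
  set.seed(seed)

  domain <- pattern0$domain
  A <- prod(domain)
  n <- length(pattern0$x)
  capn <- max(64L, 2L * n)
  x <- numeric(capn); y <- numeric(capn); mark <- integer(capn)
  x[seq_len(n)] <- pattern0$x
  y[seq_len(n)] <- pattern0$y
  mark[seq_len(n)] <- pattern0$mark

  Ck <- params$C
  use_phi <- Ck$integral > 0 &&
    (params$B11$integral > 0 || params$B12$integral > 0)
  phi <- numeric(capn)
  if (use_phi) {
    phi[seq_len(n)] <- phi_from_scratch(x, y, mark, n, domain, Ck)
  }
  rates <- numeric(capn)
  rates[seq_len(n)] <- cell_rates(mark[seq_len(n)], phi[seq_len(n)], params)
  R <- sum(rates[seq_len(n)])

  b1 <- params$B1$integral; b11 <- params$B11$integral
  b12 <- params$B12$integral
  m1 <- move_rate(params, 1L); m2 <- move_rate(params, 2L)
  sdB1 <- params$B1$width; sdB11 <- params$B11$width; sdB12 <- params$B12$width
  sdM <- c(if (is.null(params$M1)) 0 else params$M1$width,
           if (is.null(params$M2)) 0 else params$M2$width)

  grow <- function(min_cap) {
    newcap <- max(2L * capn, min_cap)
    length(x) <<- newcap; length(y) <<- newcap
    length(mark) <<- newcap; length(phi) <<- newcap; length(rates) <<- newcap
    x[(capn + 1L):newcap] <<- 0; y[(capn + 1L):newcap] <<- 0
    mark[(capn + 1L):newcap] <<- 0L
    phi[(capn + 1L):newcap] <<- 0; rates[(capn + 1L):newcap] <<- 0
    capn <<- newcap
  }

  t <- pattern0$time
  nrec <- length(record_times)
  counts <- matrix(0L, nrow = nrec, ncol = pattern0$n_marks)
  snapshots <- if (store_snapshots) vector("list", nrec) else NULL
  ev_times <- if (store_event_times) numeric(0) else NULL
  irec <- 1L
  n_events <- 0L
  aborted <- FALSE

  record_up_to <- function(tnow) {
    while (irec <= nrec && record_times[irec] <= tnow + 1e-12) {
      counts[irec, ] <<- tabulate(mark[seq_len(n)], nbins = pattern0$n_marks)
      if (store_snapshots) {
        snapshots[[irec]] <<- point_pattern(
          x[seq_len(n)], y[seq_len(n)], mark[seq_len(n)],
          domain = domain, time = record_times[irec],
          n_marks = pattern0$n_marks)
      }
      irec <<- irec + 1L
    }
  }

  refresh_rates <- function() {
    if (use_phi) {
      phi[seq_len(n)] <<- phi_from_scratch(x, y, mark, n, domain, Ck)
    }
    rates[seq_len(n)] <<- cell_rates(mark[seq_len(n)], phi[seq_len(n)], params)
    R <<- sum(rates[seq_len(n)])
  }

  while (TRUE) {
    if (n == 0L || R <= 0) { record_up_to(t_end); t <- t_end; break }
    dt <- stats::rexp(1L, rate = R)
    if (t + dt > t_end) { record_up_to(t_end); t <- t_end; break }
    record_up_to(t + dt)
    t <- t + dt
    n_events <- n_events + 1L
    if (store_event_times) ev_times <- c(ev_times, t)

    # select the cell, then the event within it
    u <- stats::runif(1L) * R
    i <- findInterval(u, cumsum(rates[seq_len(n)])) + 1L
    if (i > n) i <- n
    mi <- mark[i]
    if (mi == 1L) {
      comp <- c(birth = b1, fac = b11 * phi[i], death = params$delta1,
                jump = m1)
    } else {
      comp <- c(birth = 0, fac = b12 * phi[i], death = params$delta2,
                jump = m2)
    }
    if (sum(comp) <= 0) next   # numeric edge: zero-rate cell selected
    ev <- sample.int(4L, 1L, prob = comp)

    if (ev <= 2L) {                                   # birth
      sdD <- if (mi == 1L) (if (ev == 1L) sdB1 else sdB11) else sdB12
      nx <- wrap_coord(x[i] + stats::rnorm(1L, sd = sdD), domain[1])
      nyy <- wrap_coord(y[i] + stats::rnorm(1L, sd = sdD), domain[2])
      if (n + 1L > capn) grow(n + 1L)
      n <- n + 1L
      x[n] <- nx; y[n] <- nyy; mark[n] <- mi
      if (use_phi) {
        s1 <- which(mark[seq_len(n - 1L)] == 1L)
        phi[n] <- if (length(s1)) {
          sum(kernel_to_point(Ck, nx, nyy, x[s1], y[s1], domain))
        } else 0
        if (mi == 1L) {
          idx <- seq_len(n - 1L)
          phi[idx] <- phi[idx] + kernel_to_point(Ck, nx, nyy, x[idx], y[idx],
                                                 domain)
        }
      }
      if (n > cap) {
        warning("population cap exceeded; returning partial trajectory",
                call. = FALSE)
        aborted <- TRUE
        record_up_to(t_end)
        break
      }
    } else if (ev == 3L) {                            # death
      if (use_phi && mi == 1L) {
        idx <- seq_len(n)[-i]
        phi[idx] <- phi[idx] - kernel_to_point(Ck, x[i], y[i], x[idx], y[idx],
                                               domain)
      }
      x[i] <- x[n]; y[i] <- y[n]; mark[i] <- mark[n]; phi[i] <- phi[n]
      mark[n] <- 0L
      n <- n - 1L
    } else {                                          # jump
      nx <- wrap_coord(x[i] + stats::rnorm(1L, sd = sdM[mi]), domain[1])
      nyy <- wrap_coord(y[i] + stats::rnorm(1L, sd = sdM[mi]), domain[2])
      if (use_phi && mi == 1L && n > 1L) {
        idx <- seq_len(n)[-i]
        phi[idx] <- phi[idx] +
          kernel_to_point(Ck, nx, nyy, x[idx], y[idx], domain) -
          kernel_to_point(Ck, x[i], y[i], x[idx], y[idx], domain)
      }
      x[i] <- nx; y[i] <- nyy
      if (use_phi) {
        s1 <- which(mark[seq_len(n)] == 1L)
        s1 <- setdiff(s1, i)
        phi[i] <- if (length(s1)) {
          sum(kernel_to_point(Ck, nx, nyy, x[s1], y[s1], domain))
        } else 0
      }
    }

    if (n_events %% refresh_every == 0L) {
      refresh_rates()
    } else {
      rates[seq_len(n)] <- cell_rates(mark[seq_len(n)], phi[seq_len(n)],
                                      params)
      R <- sum(rates[seq_len(n)])
    }
  }

  final <- point_pattern(x[seq_len(n)], y[seq_len(n)], mark[seq_len(n)],
                         domain = domain, time = t,
                         n_marks = pattern0$n_marks)
  structure(
    list(times = record_times, counts = counts, densities = counts / A,
         snapshots = snapshots, final = final, n_events = n_events,
         event_times = ev_times, seed = seed, aborted = aborted,
         final_cache = list(phi = phi[seq_len(n)], rates = rates[seq_len(n)],
                            total = R)),
    class = "stpp_trajectory"
  )
}

#' @export
print.stpp_trajectory <- function(x, ...) {
  cat(sprintf("STPP trajectory: %d record times in [%g, %g], %d events\n",
              length(x$times), min(x$times), max(x$times), x$n_events))
  invisible(x)
}

#' Replicate ensemble of point-process trajectories
#'
#' Runs `n_reps` independent stochastic trajectories from a single shared
#' initial pattern (the same initial cell configuration for every replicate)
#' with seeds `base_seed, base_seed + 1, ...`, and summarises per-time,
#' per-type counts with min / max / mean / sd across replicates.
#'
#' @param pattern0 a shared initial [point_pattern()], or an [icc_config()]
#'   (realised once with `icc_seed`, or once per replicate when
#'   `redraw_icc = TRUE`).
#' @inheritParams simulate_stpp
#' @param n_reps number of replicates (>= 1).
#' @param base_seed seed of the first replicate.
#' @param redraw_icc draw a fresh initial configuration per replicate
#'   (only meaningful when `pattern0` is an `icc_config`).
#' @param icc_seed seed used to realise an `icc_config`.
#' @return An object of class `stpp_ensemble`: `times`, `trajectories`,
#'   `pattern0`, and summary arrays `min`, `max`, `mean`, `sd` of the
#'   densities (time x type).
#' @export
simulate_ensemble <- function(pattern0, params, t_end, record_times = NULL,
                              n_reps = 100L, base_seed = 1L,
                              store_snapshots = FALSE, redraw_icc = FALSE,
                              icc_seed = 1L, cap = 1e6) {
  stopifnot(n_reps >= 1L)
  cfg <- NULL
  if (inherits(pattern0, "icc_config")) {
    cfg <- pattern0
    pattern0 <- generate_icc(cfg, seed = icc_seed)
  }
  trajectories <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    p0 <- if (redraw_icc && !is.null(cfg)) {
      generate_icc(cfg, seed = icc_seed + r - 1L)
    } else pattern0
    trajectories[[r]] <- simulate_stpp(
      p0, params, t_end, record_times = record_times,
      seed = base_seed + r - 1L, store_snapshots = store_snapshots, cap = cap)
  }
  times <- trajectories[[1]]$times
  dens <- simplify2array(lapply(trajectories, `[[`, "densities"))
  # dens: time x type x rep
  structure(
    list(times = times, trajectories = trajectories, pattern0 = pattern0,
         min = apply(dens, c(1, 2), min),
         max = apply(dens, c(1, 2), max),
         mean = apply(dens, c(1, 2), mean),
         sd = apply(dens, c(1, 2), stats::sd)),
    class = "stpp_ensemble"
  )
}

#' @export
print.stpp_ensemble <- function(x, ...) {
  cat(sprintf("STPP ensemble: %d replicates, %d record times in [%g, %g]\n",
              length(x$trajectories), length(x$times), min(x$times),
              max(x$times)))
  invisible(x)
}
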