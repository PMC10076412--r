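#' Envelope capture criterion
#'
#' A deterministic curve "captures" the stochastic dynamics if it lies within
#' the minimum-to-maximum band of the replicate ensemble at every recorded
#' time. Reports, per statistic, whether it is captured and the fraction of
#' time points inside the band.
#'
#' @param det_series numeric vector (one statistic) or matrix (time x
#'   statistic) of deterministic values on the ensemble's time grid.
#' @param env_min,env_max matching vectors/matrices of per-time ensemble
#'   minima and maxima.
#' @param tol non-negative slack applied to the band edges (default 0:
#'   the strict criterion).
#' @return a data frame with one row per statistic: `statistic`, `captured`,
#'   `fraction_inside`.
#' @examples
#' envelope_capture(c(2, 2), env_min = c(1, 1), env_max = c(3, 3))
#' @export
envelope_capture <- function(det_series, env_min, env_max, tol = 0) {
  det_series <- as.matrix(det_series)
  env_min <- as.matrix(env_min)
  env_max <- as.matrix(env_max)
  if (!all(dim(det_series) == dim(env_min)) ||
      !all(dim(det_series) == dim(env_max))) {
    stop("time grids / shapes of the deterministic series and the envelope ",
         "do not match", call. = FALSE)
  }
  inside <- det_series >= env_min - tol & det_series <= env_max + tol
  nm <- colnames(det_series)
  if (is.null(nm)) nm <- paste0("stat", seq_len(ncol(det_series)))
  data.frame(statistic = nm,
             captured = apply(inside, 2, all),
             fraction_inside = apply(inside, 2, mean),
             row.names = NULL)
}

default_run_config <- function() {
  list(
    version = 1L,
    model = list(b1 = 0.001, b11 = 0.025, b12 = 0.050, sigma_B = 25,
                 c = 100, sigma_C = 100, m1 = 0, m2 = 0, sigma_M = 25,
                 delta1 = 0, delta2 = 0, ell = 1),
    icc = list(kind = "icc1", n_cells = c(200L, 200L), n_clusters = 8L,
               cluster_sd = 40, domain = c(1000, 1000), seed = 1L),
    simulation = list(t_end = 200, n_record = 9L, n_reps = 30L,
                      base_seed = 1L, cap = 1e6),
    estimator = list(grid_n = 256L, delta_h = NULL),
    solver = list(k_nodes = 257L, rtol = 1e-8, atol = 1e-10),
    treatment = list(enabled = FALSE, method = "scm", T = 200),
    output = list(dir = NULL, figures = FALSE)
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    key <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(base)) {
      stop("unknown config key: ", key, call. = FALSE)
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], as.list(user[[nm]]), key)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read and validate a run configuration
#'
#' Run configurations are YAML mappings with sections `model`, `icc`,
#' `simulation`, `estimator`, `solver`, `treatment` and `output`; every key
#' has a default and unknown keys are a hard error (listing the offending
#' key). See `default_run_config()` internals for the schema.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @param overrides optional named list merged over the file's values.
#' @return a validated config list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "run_config")
}

config_params <- function(cfg) {
  m <- cfg$model
  mk <- function(int, sd) if (int > 0) gaussian_kernel(int, sd) else NULL
  model_params(
    B1 = gaussian_kernel(m$b1, m$sigma_B),
    B11 = gaussian_kernel(m$b11, m$sigma_B),
    B12 = gaussian_kernel(m$b12, m$sigma_B),
    C = gaussian_kernel(m$c, m$sigma_C),
    M1 = mk(m$m1, m$sigma_M), M2 = mk(m$m2, m$sigma_M),
    delta1 = m$delta1, delta2 = m$delta2, ell = m$ell)
}

config_icc <- function(cfg) {
  icc_config(kind = cfg$icc$kind, n_cells = cfg$icc$n_cells,
             n_clusters = cfg$icc$n_clusters, cluster_sd = cfg$icc$cluster_sd,
             domain = cfg$icc$domain)
}

#' Run a full comparison experiment
#'
#' Executes the whole pipeline from a run configuration: generate the
#' initial cell configuration, simulate the replicate ensemble, estimate the
#' initial cumulants, solve the mean-field and spatial-cumulant equations
#' from the measured initial conditions, optionally derive and apply
#' treatment doses, and compare the deterministic densities against the
#' ensemble envelope. When an output directory is configured, all artifacts
#' (pattern CSV, trajectory CSVs, capture report JSON, run manifest, and
#' optional figures) are written there; results are fully reproducible from
#' the configuration and seeds.
#'
#' @param config a [read_run_config()] result (or `NULL` for defaults).
#' @return a list of class `experiment_result` with elements `config`,
#'   `pattern0`, `ensemble`, `mfpm`, `scm` (density trajectories), `capture`
#'   (capture report for MFPM and SCM densities) and, if enabled,
#'   `treatment`.
#' @export
run_experiment <- function(config = NULL) {
  cfg <- if (is.null(config)) read_run_config() else config
  stopifnot(inherits(cfg, "run_config"))
  params <- config_params(cfg)
  icc <- config_icc(cfg)
  pattern0 <- generate_icc(icc, seed = cfg$icc$seed)
  sim <- cfg$simulation
  record_times <- unique(seq(0, sim$t_end, length.out = sim$n_record))

  ens <- simulate_ensemble(pattern0, params, t_end = sim$t_end,
                           record_times = record_times,
                           n_reps = sim$n_reps, base_seed = sim$base_seed,
                           cap = sim$cap)

  st0 <- pair_statistics(pattern0, delta_h = cfg$estimator$delta_h,
                         grid_n = cfg$estimator$grid_n)
  grid <- default_spectral_grid(params, n = cfg$solver$k_nodes)
  state0 <- scm_initial_state(st0, grid, params)
  scm <- scm_solve(state0, params, grid, t_grid = record_times,
                   rtol = cfg$solver$rtol, atol = cfg$solver$atol)
  mf <- mfpm_solve(st0$densities, params, record_times,
                   rtol = cfg$solver$rtol, atol = cfg$solver$atol)

  det <- cbind(mfpm_u1 = mf[, "q1"], mfpm_u2 = mf[, "q2"],
               scm_u1 = scm$u[, 1], scm_u2 = scm$u[, 2])
  env_min <- cbind(ens$min, ens$min)
  env_max <- cbind(ens$max, ens$max)
  capture <- envelope_capture(det, env_min, env_max)

  result <- list(config = cfg, pattern0 = pattern0, ensemble = ens,
                 statistics0 = st0, mfpm = mf, scm = scm, capture = capture)

  if (isTRUE(cfg$treatment$enabled)) {
    result$treatment <- treat_and_continue(
      pattern0, params, T_treat = cfg$treatment$T,
      t_end = sim$t_end + (sim$t_end - cfg$treatment$T),
      method = cfg$treatment$method, n_reps = sim$n_reps,
      base_seed = sim$base_seed, grid_n = cfg$estimator$grid_n,
      delta_h = cfg$estimator$delta_h, grid = grid)
  }

  if (!is.null(cfg$output$dir)) {
    write_experiment(result, cfg$output$dir, figures = cfg$output$figures)
  }
  class(result) <- "experiment_result"
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("comparison experiment (", x$config$icc$kind, ")\n", sep = "")
  print(x$capture)
  invisible(x)
}

write_experiment <- function(result, dir, figures = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  write_pattern(result$pattern0, file.path(dir, "pattern0.csv"))
  write_statistics(result$statistics0, file.path(dir, "statistics0.csv"))
  ens <- result$ensemble
  traj <- data.frame(time = ens$times,
                     u1_min = ens$min[, 1], u1_max = ens$max[, 1],
                     u1_mean = ens$mean[, 1],
                     u2_min = ens$min[, 2], u2_max = ens$max[, 2],
                     u2_mean = ens$mean[, 2],
                     mfpm_u1 = result$mfpm[, "q1"],
                     mfpm_u2 = result$mfpm[, "q2"],
                     scm_u1 = result$scm$u[, 1],
                     scm_u2 = result$scm$u[, 2])
  utils::write.csv(traj, file.path(dir, "densities.csv"), row.names = FALSE)
  jsonlite::write_json(result$capture, file.path(dir, "capture.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(result$treatment)) {
    utils::write.csv(result$treatment$doses, file.path(dir, "doses.csv"),
                     row.names = FALSE)
  }
  if (isTRUE(figures)) {
    grDevices::png(file.path(dir, "densities.png"), width = 900, height = 600)
    plot_densities(result)
    grDevices::dev.off()
    grDevices::png(file.path(dir, "pattern0.png"), width = 600, height = 600)
    plot(result$pattern0)
    grDevices::dev.off()
  }
  invisible(dir)
}

#' Density-trajectory comparison plot
#'
#' Shaded min-to-max ensemble band per subpopulation, with the mean-field
#' (solid) and spatial-cumulant (triangles) densities overlaid.
#'
#' @param result an [run_experiment()] result.
#' @export
plot_densities <- function(result) {
  ens <- result$ensemble
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  cols <- c("red3", "blue3")
  for (i in 1:2) {
    ylim <- range(ens$min[, i], ens$max[, i], result$mfpm[, i + 1],
                  result$scm$u[, i])
    graphics::plot(NULL, xlim = range(ens$times), ylim = ylim,
                   xlab = "time", ylab = sprintf("density u%d", i),
                   main = sprintf("subpopulation s%d", i))
    graphics::polygon(c(ens$times, rev(ens$times)),
                      c(ens$min[, i], rev(ens$max[, i])),
                      col = grDevices::adjustcolor(cols[i], 0.25),
                      border = NA)
    graphics::lines(ens$times, result$mfpm[, i + 1], lwd = 2)
    graphics::points(result$scm$times, result$scm$u[, i], pch = 2,
                     col = "orange3", lwd = 2)
  }
  invisible(result)
}
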