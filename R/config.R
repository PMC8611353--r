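#' Read and validate a run configuration
#'
#' YAML run configuration for the command-line entry points.  Unknown keys
#' are rejected; defaults are filled in and the fully resolved configuration
#' is echoed into every run manifest.  Two solver profiles are provided:
#' `desk` (N = 400 particles, 20 000 iterations) for interactive work and
#' `paper` (N = 1000, 450 000 iterations, 50 000 burn-in) for full-scale
#' runs.
#'
#' @param path YAML file path, or a list already parsed.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  allowed <- c("mode", "dataset", "preset", "params", "solver", "inference",
               "priors", "output_dir", "seed", "profile", "sigma_o")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$mode) ||
      !cfg$mode %in% c("simulate", "fit", "predict", "validate"))
    stop("config needs mode: simulate | fit | predict | validate")
  profile <- if (is.null(cfg$profile)) "desk" else
    match.arg(cfg$profile, c("desk", "paper"))
  prof_defaults <- if (profile == "paper")
    list(N = 1000, n_iter = 450000, burn_in = 50000) else
    list(N = 400, n_iter = 20000, burn_in = 2000)
  solver_defaults <- list(N = prof_defaults$N, R0 = NULL, rtol = 1e-8,
                          atol = 1e-12, method = "dp45", fixed_dt = 1e-3)
  cfg$solver <- modifyList(solver_defaults,
                           if (is.null(cfg$solver)) list() else cfg$solver)
  inf_defaults <- list(n_iter = prof_defaults$n_iter,
                       burn_in = prof_defaults$burn_in,
                       target_acceptance = 0.234, pilot_length = 2000,
                       s = NULL)
  cfg$inference <- modifyList(inf_defaults,
                              if (is.null(cfg$inference)) list() else
                                cfg$inference)
  if (cfg$inference$burn_in >= cfg$inference$n_iter)
    stop("burn_in must be smaller than n_iter")
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (is.null(cfg$output_dir)) cfg$output_dir <- "ebtgrowth-run"
  cfg$profile <- profile
  structure(cfg, class = "run_config")
}

.cfg_forward_config <- function(cfg, preset_obj = NULL) {
  ctrl <- solver_control(rtol = cfg$solver$rtol, atol = cfg$solver$atol,
                         method = cfg$solver$method,
                         fixed_dt = cfg$solver$fixed_dt)
  fc <- forward_config(N = cfg$solver$N, R0 = cfg$solver$R0, control = ctrl)
  if (!is.null(preset_obj)) {
    fc$c <- preset_obj$profile_c
    fc$q <- preset_obj$profile_q
  }
  fc
}

.cfg_params <- function(cfg, preset_obj) {
  if (!is.null(cfg$params))
    return(model_params(cfg$params$alpha, cfg$params$sigma_k,
                        cfg$params$sigma_o, cfg$params$sigma_i))
  if (is.null(preset_obj))
    stop("config needs either params or a preset label")
  med <- preset_obj$priors$medians
  sigma_o <- if (is.null(cfg$sigma_o)) 0.05 else cfg$sigma_o
  model_params(med[["alpha"]], med[["sigma_k"]], sigma_o, med[["sigma_i"]])
}

.cfg_priors <- function(cfg, preset_obj) {
  if (!is.null(cfg$priors))
    return(prior_spec(unlist(cfg$priors$medians),
                      if (is.null(cfg$priors$sdlog))
                        c(alpha = 1, sigma_k = 1, sigma_o = 5, sigma_i = 1)
                      else unlist(cfg$priors$sdlog)))
  if (is.null(preset_obj)) stop("config needs either priors or a preset label")
  preset_obj$priors
}

.write_manifest <- function(cfg, out_dir, extra = list()) {
  man <- c(list(config = unclass(cfg),
                package_version = as.character(utils::packageVersion("ebtgrowth")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(man)
}

#' Run a forward simulation from a configuration
#'
#' Writes the simulated growth-curve CSV (`dataset.csv`), the full particle
#' trajectory (`trajectory.csv`), and a run manifest into the output
#' directory.
#'
#' @param config a `run_config` (or path to one).
#' @return The simulated [growth_dataset()], invisibly.
#' @export
cmd_simulate <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  ps <- if (!is.null(cfg$preset)) preset(cfg$preset) else NULL
  params <- .cfg_params(cfg, ps)
  fc <- .cfg_forward_config(cfg, ps)
  times <- if (!is.null(ps)) ps$schedule_days else seq(0, 38, by = 2)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(params, times, fc, seed = cfg$seed,
                         cell_line = if (!is.null(ps)) ps$label else NA)
  write_growth_csv(ds, file.path(cfg$output_dir, "dataset.csv"))
  # trajectory at the measurement grid for the noiseless forward curve
  prof <- initial_profile(initial_profile_spec(params$sigma_i, fc$c, fc$q))
  R0 <- if (is.null(fc$R0))
    default_R0(params$sigma_i, params$sigma_k, max(ds$radii)) else fc$R0
  st <- init_masses(prof, fc$N, R0)
  traj <- evolve(st, params, sort(unique(c(0, times))), fc$control)
  write.csv(as.data.frame(traj), file.path(cfg$output_dir, "trajectory.csv"),
            row.names = FALSE)
  .write_manifest(cfg, cfg$output_dir,
                  list(mode = "simulate", params = unclass(params), R0 = R0))
  invisible(ds)
}

#' Fit the model to a growth dataset from a configuration
#'
#' Reads the dataset (CSV path in `dataset`, or simulates from the preset
#' when none is given), runs the tuned Metropolis--Hastings chain, and
#' writes the chain CSV, MAP report, 95\% predictive band and manifest.
#'
#' @param config a `run_config` (or path to one).
#' @return The fitted `ebt_chain`, invisibly.
#' @export
cmd_fit <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  ps <- if (!is.null(cfg$preset)) preset(cfg$preset) else NULL
  data <- if (!is.null(cfg$dataset)) read_growth_csv(cfg$dataset) else {
    if (is.null(ps)) stop("fit needs a dataset path or a preset to simulate from")
    simulate_preset_dataset(cfg$preset,
                            sigma_o = if (is.null(cfg$sigma_o)) 0.05 else
                              cfg$sigma_o,
                            seed = cfg$seed)
  }
  priors <- .cfg_priors(cfg, ps)
  fc <- .cfg_forward_config(cfg, ps)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  chain <- run_chain(data, priors, fc,
                     n_iter = cfg$inference$n_iter,
                     burn_in = cfg$inference$burn_in,
                     seed = cfg$seed, s = cfg$inference$s,
                     pilot_length = cfg$inference$pilot_length,
                     checkpoint_file = file.path(cfg$output_dir,
                                                 "checkpoint.rds"))
  write_chain_csv(chain, file.path(cfg$output_dir, "chain.csv"))
  map <- map_estimate(chain)
  band <- predictive_band(chain, seed = cfg$seed)
  write.csv(band, file.path(cfg$output_dir, "predictive_band.csv"),
            row.names = FALSE)
  .write_manifest(cfg, cfg$output_dir,
                  list(mode = "fit", s = chain$s,
                       acceptance = mean(chain$accepted),
                       map = unclass(map),
                       map_log_posterior = attr(map, "log_posterior"),
                       R0 = chain$config$R0))
  invisible(chain)
}

#' Run the validation suite from a configuration
#'
#' Executes the analytic-oracle and convergence checks (homogeneous
#' logistic match; grid-refinement order when at least three particle
#' counts are given) and writes a JSON report.  Fails with an error if any
#' check misses its tolerance, so shell callers exit nonzero.
#'
#' @param config a `run_config` (or path to one); `solver$N` may be a
#'   vector of particle counts for the convergence section.
#' @return The report list, invisibly.
#' @export
cmd_validate <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  hom <- homogeneous_oracle_error(N = 1000)
  report$homogeneous_max_rel_error <- as.numeric(hom)
  report$homogeneous_pass <- as.numeric(hom) < 1e-3
  N_list <- cfg$solver$N
  if (length(N_list) >= 3) {
    params <- model_params(1, 0.06, 0.05, 0.264)
    prof <- initial_profile(initial_profile_spec(0.264))
    conv <- convergence_report(params, prof, N_list = sort(N_list), T = 10)
    report$convergence <- list(errors = conv$error,
                               order = attr(conv, "order"),
                               fit_residual = attr(conv, "fit_residual"))
    report$convergence_pass <- all(diff(conv$error) < 0) &&
      abs(attr(conv, "order") - 1) < 0.5
  }
  jsonlite::write_json(report, file.path(cfg$output_dir, "validation.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ok <- report$homogeneous_pass &&
    (is.null(report$convergence_pass) || report$convergence_pass)
  if (!ok) stop("validation checks failed; see validation.json")
  invisible(report)
}
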