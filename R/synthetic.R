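#' Cell-line preset
#'
#' Returns the constants of one of the three classical spheroid cell lines
#' (murine leukaemia L-5178Y, Chinese hamster lung V-79, mouse melanoma
#' B-16) together with the matching lognormal prior specification: the
#' proliferation-rate prior median derives from the line's doubling time,
#' the kernel-radius median spans roughly six cell diameters (0.06 mm for
#' L-5178Y and V-79, 0.09 mm for B-16), and the initial-radius median equals
#' the first measured colony radius.  The observation-noise prior is centred
#' at 0.1 with log-sd 5, at which scale the centre is practically
#' immaterial.
#'
#' @param cell_line one of `"L-5178Y"`, `"V-79"`, `"B-16"`.
#' @return A list of class `cell_line_preset` with fields `label`,
#'   `doubling_time_h`, `cell_diameter_um`, `initial_radius_mm`,
#'   `schedule_days`, `profile_c`, `profile_q`, `map_estimate`
#'   (a [model_params()]), and `priors` (a [prior_spec()]).
#' @examples
#' preset("V-79")$initial_radius_mm  # 0.403
#' @export
preset <- function(cell_line) {
  db <- .load_presets()
  if (!cell_line %in% names(db))
    stop("unknown cell line '", cell_line, "'; available: ",
         paste(names(db), collapse = ", "))
  p <- db[[cell_line]]
  sched <- seq(p$schedule_days$from, p$schedule_days$to, by = p$schedule_days$by)
  priors <- prior_spec(c(alpha = p$prior_alpha, sigma_k = p$prior_sigma_k,
                         sigma_o = 0.1, sigma_i = p$initial_radius_mm))
  structure(list(label = cell_line,
                 doubling_time_h = p$doubling_time_h,
                 cell_diameter_um = p$cell_diameter_um,
                 initial_radius_mm = p$initial_radius_mm,
                 schedule_days = sched,
                 profile_c = p$profile_c,
                 profile_q = p$profile_q,
                 map_estimate = model_params(p$map_estimate$alpha,
                                             p$map_estimate$sigma_k,
                                             p$map_estimate$sigma_o,
                                             p$map_estimate$sigma_i),
                 priors = priors),
            class = "cell_line_preset")
}

#' Available cell-line presets
#' @return Character vector of labels.
#' @export
preset_names <- function() names(.load_presets())

.load_presets <- function() {
  path <- system.file("extdata", "cell_lines.yaml", package = "ebtgrowth")
  yaml::read_yaml(path)$cell_lines
}

#' Simulate a synthetic growth-curve dataset
#'
#' Solves the forward model from the mollified-ball initial profile,
#' extracts quantile radii at the measurement times, and multiplies each by
#' i.i.d. lognormal noise: `r_obs_i = r(t_i) * Z_i` with
#' `log Z_i ~ N(0, sigma_o^2)`.  The seed and generating parameters are
#' recorded in the dataset's provenance, and the noise draws use their own
#' seeded stream so data generation is reproducible independently of any
#' later inference.
#'
#' @param params a [model_params()]; `params$sigma_o` sets the noise level
#'   (0 is allowed and yields noiseless observations).
#' @param times measurement times, days; defaults to every 2 days over
#'   0--38.
#' @param config a [forward_config()].
#' @param seed integer seed for the noise stream.
#' @param cell_line optional label stored in the dataset.
#' @return A [growth_dataset()].
#' @export
simulate_dataset <- function(params, times = seq(0, 38, by = 2),
                             config = forward_config(), seed = 1,
                             cell_line = NA_character_) {
  stopifnot(inherits(params, "model_params") || is.list(params))
  sigma_o <- params$sigma_o
  solver_params <- model_params(params$alpha, params$sigma_k,
                                max(sigma_o, 1e-12), params$sigma_i)
  r <- forward_radii(solver_params, times, config)
  set.seed(seed)
  z <- if (sigma_o > 0) exp(rnorm(length(times), 0, sigma_o)) else
    rep(1, length(times))
  growth_dataset(times, r * z, cell_line = cell_line,
                 provenance = list(type = "synthetic", seed = seed,
                                   params = unclass(params),
                                   N = config$N, R0 = config$R0))
}

#' Simulate a dataset from a cell-line preset
#'
#' Convenience wrapper: takes the generating parameters from the preset's
#' prior medians (or any supplied `params`), the measurement schedule from
#' the preset, and the preset's initial-profile shape constants.
#'
#' @param cell_line preset label.
#' @param sigma_o observation-noise standard deviation (log scale).
#' @param params optional [model_params()] overriding the preset medians.
#' @param config a [forward_config()]; the preset's profile constants are
#'   filled in.
#' @param seed noise seed.
#' @return A [growth_dataset()].
#' @export
simulate_preset_dataset <- function(cell_line, sigma_o = 0.05, params = NULL,
                                    config = forward_config(), seed = 1) {
  ps <- preset(cell_line)
  if (is.null(params)) {
    med <- ps$priors$medians
    params <- model_params(med[["alpha"]], med[["sigma_k"]], sigma_o,
                           med[["sigma_i"]])
  }
  config$c <- ps$profile_c
  config$q <- ps$profile_q
  simulate_dataset(params, times = ps$schedule_days, config = config,
                   seed = seed, cell_line = cell_line)
}
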