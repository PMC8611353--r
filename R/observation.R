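#' Growth-curve dataset
#'
#' Measurement times (days) and observed colony radii (mm) with provenance
#' metadata.
#'
#' @param times strictly increasing, nonnegative measurement times, days.
#' @param radii positive observed radii, mm.
#' @param cell_line optional label.
#' @param provenance free-form provenance record (synthetic seed, file path).
#' @param sd_mm optional per-time standard deviations carried as metadata;
#'   not used in the likelihood, which assumes homogeneous-in-time
#'   multiplicative error.
#' @return An object of class `growth_dataset`.
#' @export
growth_dataset <- function(times, radii, cell_line = NA_character_,
                           provenance = NULL, sd_mm = NULL) {
  times <- as.numeric(times); radii <- as.numeric(radii)
  if (length(times) != length(radii) || length(times) < 1)
    stop("times and radii must have equal positive length")
  if (any(times < 0) || any(diff(times) <= 0))
    stop("times must be nonnegative and strictly increasing")
  if (any(radii <= 0) || any(!is.finite(radii)))
    stop("radii must be positive and finite")
  structure(list(times = times, radii = radii, l = length(times),
                 cell_line = cell_line, provenance = provenance,
                 sd_mm = sd_mm),
            class = "growth_dataset")
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat(sprintf("Growth dataset (%s): %d measurements, t in [%g, %g] d, radius in [%g, %g] mm\n",
              ifelse(is.na(x$cell_line), "unlabelled", x$cell_line), x$l,
              min(x$times), max(x$times), min(x$radii), max(x$radii)))
  invisible(x)
}

#' Read a growth-curve CSV
#'
#' Accepts a `time_days` column plus either `radius_mm` or `diameter_mm`;
#' diameters are halved on ingest since the observation model works in
#' radii.  An optional `sd_mm` column is carried as metadata.
#'
#' @param path CSV path.
#' @param cell_line optional label override.
#' @return A [growth_dataset()].
#' @export
read_growth_csv <- function(path, cell_line = NA_character_) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"time_days" %in% names(df))
    stop("growth CSV needs a time_days column")
  if ("radius_mm" %in% names(df)) {
    r <- df$radius_mm
  } else if ("diameter_mm" %in% names(df)) {
    r <- df$diameter_mm / 2
  } else stop("growth CSV needs a radius_mm or diameter_mm column")
  if (is.na(cell_line) && "cell_line" %in% names(df))
    cell_line <- df$cell_line[1]
  growth_dataset(df$time_days, r, cell_line = cell_line,
                 provenance = list(path = path),
                 sd_mm = if ("sd_mm" %in% names(df)) df$sd_mm else NULL)
}

#' Write a growth-curve CSV
#'
#' @param data a [growth_dataset()].
#' @param path output path.
#' @param as_diameter write a `diameter_mm` column (default) or `radius_mm`.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(data, path, as_diameter = TRUE) {
  stopifnot(inherits(data, "growth_dataset"))
  df <- data.frame(time_days = data$times)
  if (as_diameter) df$diameter_mm <- 2 * data$radii else
    df$radius_mm <- data$radii
  if (!is.null(data$sd_mm)) df$sd_mm <- data$sd_mm
  if (!is.na(data$cell_line)) df$cell_line <- data$cell_line
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Quantile radius of a particle state
#'
#' The colony radius is the smallest radius enclosing a fraction `quantile`
#' of the total mass: `r = inf{s : sum_{x_i <= s} m_i > quantile * M}`.
#' Without smoothing this is the smallest particle location at which the
#' cumulative mass strictly exceeds the threshold.  With `smoothing_eps > 0`
#' the discrete measure is convolved with the Laplace density
#' `rho_eps(x) = exp(-|x|/eps)/(2 eps)` and the smoothed CDF crossing is
#' root-found to 1e-10; the regularized and plain radii differ only at the
#' particle-grid scale, so smoothing is off by default.
#'
#' With `interpolate = TRUE` the cumulative mass is interpolated linearly
#' between particle locations before the crossing is found, which makes the
#' radius a continuous function of the masses (and hence the likelihood
#' smooth in the parameters) at the cost of leaving the atom-location
#' convention; the two differ by at most one grid cell.
#'
#' @param state a [particle_state()].
#' @param quantile mass fraction in (0, 1); default 0.95.
#' @param smoothing_eps Laplace smoothing width, mm, or `NULL` (default).
#' @param interpolate interpolate the cumulative mass linearly between
#'   particle locations instead of returning an atom location.
#' @return Radius, mm.
#' @examples
#' s <- particle_state(c(0, 1, 0, 0), R0 = 2)
#' quantile_radius(s)  # 1: the single atom holds all mass
#' @export
quantile_radius <- function(state, quantile = 0.95, smoothing_eps = NULL,
                            interpolate = FALSE) {
  stopifnot(inherits(state, "particle_state"), quantile > 0, quantile < 1)
  total <- sum(state$masses)
  if (total <= 0) stop("zero total mass: colony radius undefined")
  if (is.null(smoothing_eps)) {
    cum <- cumsum(state$masses)
    i <- which(cum > quantile * total)[1]
    if (is.na(i)) i <- state$N
    if (!interpolate) return(state$locations[i])
    x0 <- if (i == 1) 0 else state$locations[i - 1]
    c0 <- if (i == 1) 0 else cum[i - 1]
    frac <- (quantile * total - c0) / (cum[i] - c0)
    return(x0 + frac * (state$locations[i] - x0))
  }
  eps <- smoothing_eps
  stopifnot(eps > 0)
  # Laplace CDF: 0.5*exp(z/eps) for z<0, 1-0.5*exp(-z/eps) for z>=0
  Fcdf <- function(s) {
    z <- (s - state$locations) / eps
    w <- ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
    sum(state$masses * w) / total
  }
  lo <- 0
  hi <- state$R0 + 50 * eps
  uniroot(function(s) Fcdf(s) - quantile, c(lo, hi), tol = 1e-10)$root
}

#' Colony-radius trajectory
#'
#' Quantile radii at every output time of an [evolve()] trajectory.
#'
#' @param traj an `ebt_trajectory`.
#' @param quantile mass fraction; default 0.95.
#' @param smoothing_eps optional Laplace smoothing width, mm.
#' @param interpolate see [quantile_radius()].
#' @return Numeric vector, one radius per trajectory time.
#' @export
radius_trajectory <- function(traj, quantile = 0.95, smoothing_eps = NULL,
                              interpolate = FALSE) {
  stopifnot(inherits(traj, "ebt_trajectory"))
  vapply(seq_along(traj$times), function(i)
    quantile_radius(state_at(traj, i), quantile, smoothing_eps, interpolate),
    numeric(1))
}

#' Log-likelihood of observed radii
#'
#' Multiplicative lognormal measurement error: `log r_obs_i` is Gaussian
#' around `log r_model_i` with standard deviation `sigma_o`, so
#' \deqn{\log \ell = \sum_i \log \phi(\log r_o^i; \log r(t_i), \sigma_o^2).}
#' Invariant under common rescaling of observed and model radii.
#'
#' @param data a [growth_dataset()] (or a vector of observed radii).
#' @param model_radii model radii at the observation times, mm.
#' @param sigma_o log-scale error standard deviation.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(data, model_radii, sigma_o) {
  obs <- if (inherits(data, "growth_dataset")) data$radii else as.numeric(data)
  if (length(model_radii) != length(obs))
    stop("model_radii must match the number of observations")
  if (any(model_radii <= 0) || any(obs <= 0))
    stop("radii must be positive")
  if (sigma_o <= 0) stop("sigma_o must be positive")
  sum(dnorm(log(obs), mean = log(model_radii), sd = sigma_o, log = TRUE))
}
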