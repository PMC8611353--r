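#' Radial density profile
#'
#' A continuum radial mass density `p(R)` on `[0, Inf)` used for initial
#' conditions and oracle comparisons.  `cumulative`, when supplied, must be
#' the closed-form antiderivative `M(r) = int_0^r p(s) ds`; cell integrals of
#' the EBT initialization then evaluate exactly instead of by quadrature.
#'
#' @param density function of a vector of radii returning nonnegative values,
#'   1/mm mass density.
#' @param support upper bound of the support, mm.
#' @param cumulative optional function, `M(r) = int_0^r p`.
#' @return An object of class `radial_profile`.
#' @export
radial_profile <- function(density, support, cumulative = NULL) {
  stopifnot(is.function(density), is.numeric(support), support >= 0)
  structure(list(density = density, support = support,
                 cumulative = cumulative),
            class = "radial_profile")
}

#' Initial-profile specification
#'
#' The initial colony is a mollified ball: in radial form
#' \deqn{p(r,0) = 4\pi r^2 (1 - (r/\tilde\sigma)^q)\,1_{[0,\tilde\sigma]}(r),}
#' with `sigma_tilde = c * sigma_i`.  The inflation `c` and exponent `q` are
#' chosen so that the 95\% mass-quantile radius of the profile is close to
#' the nominal initial radius `sigma_i` (defaults `c = 1.065`, `q = 13`).
#'
#' @param sigma_i target initial colony radius, mm.
#' @param c inflation factor (>= 1), dimensionless.
#' @param q mollification exponent (> 0), dimensionless.
#' @return An object of class `initial_profile_spec`.
#' @export
initial_profile_spec <- function(sigma_i, c = 1.065, q = 13) {
  stopifnot(sigma_i > 0, c >= 1, q > 0)
  structure(list(sigma_i = sigma_i, c = c, q = q),
            class = "initial_profile_spec")
}

#' Build the mollified-ball initial profile
#'
#' @param spec an [initial_profile_spec()].
#' @return A [radial_profile()] with closed-form cumulative mass
#'   `M(r) = 4 pi (r^3/3 - r^(q+3)/((q+3) sigma_tilde^q))` on the support.
#' @examples
#' prof <- initial_profile(initial_profile_spec(0.264))
#' profile_total_mass(prof)
#' @export
initial_profile <- function(spec) {
  stopifnot(inherits(spec, "initial_profile_spec"))
  st <- spec$c * spec$sigma_i
  q <- spec$q
  dens <- function(r) {
    v <- 4 * pi * r^2 * (1 - (r / st)^q)
    v[r < 0 | r > st] <- 0
    pmax(v, 0)
  }
  cum <- function(r) {
    r <- pmin(pmax(r, 0), st)
    4 * pi * (r^3 / 3 - r^(q + 3) / ((q + 3) * st^q))
  }
  radial_profile(dens, support = st, cumulative = cum)
}

#' Total mass of a radial profile
#'
#' @param profile a [radial_profile()].
#' @param upper integration bound; defaults to the profile support.
#' @return `int_0^upper p(r) dr`.
#' @export
profile_total_mass <- function(profile, upper = profile$support) {
  if (!is.null(profile$cumulative)) return(profile$cumulative(upper))
  integrate(profile$density, 0, upper, rel.tol = 1e-10,
            subdivisions = 500L)$value
}

#' Mass-quantile radius of a continuum profile
#'
#' Smallest radius enclosing a given fraction of the total profile mass.
#'
#' @param profile a [radial_profile()].
#' @param quantile mass fraction in (0, 1); default 0.95.
#' @return Radius, mm.
#' @export
profile_quantile_radius <- function(profile, quantile = 0.95) {
  stopifnot(quantile > 0, quantile < 1)
  total <- profile_total_mass(profile)
  if (total <= 0) stop("profile has zero total mass; radius undefined")
  M <- if (!is.null(profile$cumulative)) profile$cumulative else
    function(r) vapply(r, function(u)
      integrate(profile$density, 0, u, rel.tol = 1e-10,
                subdivisions = 500L)$value, numeric(1))
  uniroot(function(r) M(r) - quantile * total, c(0, profile$support),
          tol = 1e-12)$root
}
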