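#' Model parameters
#'
#' Container for the four inferred quantities of the non-local proliferation
#' model.  Units are fixed package-wide: days for time, millimetres for
#' length.
#'
#' @param alpha proliferation rate, 1/day.
#' @param sigma_k kernel (interaction) radius, mm.
#' @param sigma_o standard deviation of the log-radius measurement error,
#'   dimensionless.
#' @param sigma_i initial colony radius, mm.
#' @return An object of class `model_params`.
#' @examples
#' model_params(alpha = 1.04, sigma_k = 0.06, sigma_o = 0.05, sigma_i = 0.403)
#' @export
model_params <- function(alpha, sigma_k, sigma_o, sigma_i) {
  p <- c(alpha = alpha, sigma_k = sigma_k, sigma_o = sigma_o,
         sigma_i = sigma_i)
  if (!all(is.finite(p)) || any(p <= 0))
    stop("all model parameters must be finite and strictly positive")
  structure(as.list(p), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Non-local proliferation model parameters (days, mm):\n")
  cat(sprintf("  alpha   = %g 1/day\n  sigma_k = %g mm\n  sigma_o = %g\n  sigma_i = %g mm\n",
              x$alpha, x$sigma_k, x$sigma_o, x$sigma_i))
  invisible(x)
}

#' Convert a log-parameter vector to `model_params`
#'
#' The sampler works with `theta_log = log(c(alpha, sigma_k, sigma_o,
#' sigma_i))`; this is the inverse map.
#'
#' @param theta_log numeric vector of length 4 (log alpha, log sigma_k,
#'   log sigma_o, log sigma_i).
#' @return A `model_params` object.
#' @export
params_from_log <- function(theta_log) {
  stopifnot(length(theta_log) == 4, all(is.finite(theta_log)))
  p <- exp(theta_log)
  model_params(p[[1]], p[[2]], p[[3]], p[[4]])
}

#' Ball-indicator proliferation kernel
#'
#' The 3D kernel is the normalized characteristic function of a ball of
#' radius `sigma_k`: `K(d) = 3/(4 pi sigma_k^3)` for `d <= sigma_k` and 0
#' beyond, so it integrates to 1 over 3D space.
#'
#' @param distance nonnegative distance(s), mm.
#' @param sigma_k kernel radius, mm (positive scalar).
#' @return Kernel density values, 1/mm^3.
#' @examples
#' kernel_K(0.5, 1)      # 3/(4*pi)
#' kernel_K(2, 1)        # 0
#' @export
kernel_K <- function(distance, sigma_k) {
  if (!is.numeric(sigma_k) || length(sigma_k) != 1 || !is.finite(sigma_k) ||
      sigma_k <= 0)
    stop("sigma_k must be a positive scalar")
  if (any(distance < 0)) stop("distance must be nonnegative")
  ifelse(distance <= sigma_k, 3 / (4 * pi * sigma_k^3), 0)
}

#' Radial interaction kernel
#'
#' The interaction kernel of the radially reduced model,
#' \deqn{L(R,r) = \frac{3\alpha}{16\pi\sigma_k^3}\,
#'   \frac{\min\{(R+r)^2,\sigma_k^2\} - \min\{(R-r)^2,\sigma_k^2\}}{R\,r},}
#' symmetric in (R, r), nonnegative, and zero for `|R - r| >= sigma_k`.
#' Evaluation is by exact case analysis: when `(R+r)^2 <= sigma_k^2` the
#' numerator is identically `4 R r`, so `L = 3 alpha/(4 pi sigma_k^3)`
#' without forming the cancellation-prone difference -- this also yields the
#' analytic limit at the coordinate singularity `R*r = 0` (the value
#' `3 alpha/(4 pi sigma_k^3)` inside the kernel support, 0 outside); the
#' division by `R*r` only occurs in the regime `|R-r| < sigma_k < R+r`,
#' where it is well conditioned.
#'
#' @param R,r radial coordinates, mm (vectors, recycled).
#' @param alpha proliferation rate, 1/day.
#' @param sigma_k kernel radius, mm.
#' @return Kernel values, 1/(day mm mass-unit).
#' @examples
#' interaction_L(1, 1, alpha = 1, sigma_k = 0.06)
#' @export
interaction_L <- function(R, r, alpha, sigma_k) {
  if (alpha <= 0 || sigma_k <= 0) stop("alpha and sigma_k must be positive")
  if (any(R < 0) || any(r < 0)) stop("radial coordinates must be nonnegative")
  n <- max(length(R), length(r))
  R <- rep_len(R, n); r <- rep_len(r, n)
  s2 <- sigma_k^2
  pref <- 3 * alpha / (16 * pi * sigma_k^3)
  out <- numeric(n)
  inner <- (R + r)^2 <= s2            # both minima at the squares
  out[inner] <- 4 * pref
  mid <- !inner & (R - r)^2 < s2      # only the first minimum clamped
  out[mid] <- pref * (s2 - (R[mid] - r[mid])^2) / (R[mid] * r[mid])
  out                                 # |R - r| >= sigma_k: zero
}

#' Dense interaction matrix on the particle grid
#'
#' Reference (O(N^2)) construction of `L(x_i, x_j)` on the EBT grid
#' `x_i = i R0/N`.  The solver itself uses an equivalent banded construction
#' in compiled code; this dense form is exported for inspection and testing.
#'
#' @param N particle count.
#' @param R0 truncation radius, mm.
#' @param alpha proliferation rate, 1/day.
#' @param sigma_k kernel radius, mm.
#' @return An `N x N` symmetric matrix.
#' @export
interaction_matrix <- function(N, R0, alpha, sigma_k) {
  x <- seq_len(N) * R0 / N
  outer(x, x, interaction_L, alpha = alpha, sigma_k = sigma_k)
}
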