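# shared fixtures: small parameter sets and profiles used across test files

v79_params <- function(sigma_o = 0.05)
  model_params(alpha = 1.04, sigma_k = 0.06, sigma_o = sigma_o,
               sigma_i = 0.403)

small_profile <- function(sigma_i = 0.264, c = 1.065, q = 13)
  initial_profile(initial_profile_spec(sigma_i, c, q))

# brute-force flat norm via pracma's LP (shifted variables phi = psi + 1 so
# the implicit nonnegativity constraint encodes |psi| <= 1)
flat_norm_lp <- function(mu, nu) {
  x <- c(mu$locations, nu$locations)
  d <- c(mu$masses, -nu$masses)
  o <- order(x); x <- x[o]; d <- d[o]
  grp <- cumsum(c(TRUE, diff(x) > 1e-14))
  x <- as.numeric(tapply(x, grp, `[`, 1))
  d <- as.numeric(tapply(d, grp, sum))
  n <- length(x)
  if (n == 1) return(min(abs(d[1]), abs(d[1])))  # single atom: |d| (<=1 bound)
  gaps <- diff(x)
  D <- diff(diag(n))
  A <- rbind(D, -D, diag(n))
  b <- c(gaps, gaps, rep(2, n))
  lp <- pracma::linprog(cc = -d, A = A, b = b, maxiter = 2000)
  -lp$fval - sum(d)
}
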