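#' One random-walk Metropolis--Hastings step
#'
#' Proposes `theta_tilde = theta + Z`, `Z ~ N(0, s^2 I)` (isotropic Gaussian
#' in log-parameter space), and accepts with probability
#' `min(1, exp(lp(theta_tilde) - lp(theta)))`; on rejection the current draw
#' is repeated.  Uses the current R RNG stream.
#'
#' @param theta current draw (numeric vector).
#' @param lp log-posterior value at `theta`.
#' @param logpost log-posterior function.
#' @param s proposal standard deviation per coordinate.
#' @return List with `theta`, `lp`, `accepted`.
#' @export
metropolis_step <- function(theta, lp, logpost, s) {
  stopifnot(s > 0)
  prop <- theta + rnorm(length(theta), 0, s)
  lp_prop <- logpost(prop)
  u <- runif(1)  # always drawn, keeping the RNG stream aligned
  if (is.finite(lp_prop) && log(u) <= lp_prop - lp) {
    list(theta = prop, lp = lp_prop, accepted = TRUE)
  } else {
    list(theta = theta, lp = lp, accepted = FALSE)
  }
}

.mh_loop <- function(logpost, theta0, s, n_iter) {
  d <- length(theta0)
  draws <- matrix(NA_real_, n_iter, d)
  lps <- numeric(n_iter)
  acc <- logical(n_iter)
  theta <- theta0
  lp <- logpost(theta)
  if (!is.finite(lp)) stop("log posterior is not finite at the initial point")
  for (i in seq_len(n_iter)) {
    prop <- theta + rnorm(d, 0, s)
    lp_prop <- logpost(prop)
    u <- runif(1)
    if (is.finite(lp_prop) && log(u) <= lp_prop - lp) {
      theta <- prop; lp <- lp_prop; acc[i] <- TRUE
    }
    draws[i, ] <- theta
    lps[i] <- lp
  }
  list(draws = draws, log_posterior = lps, accepted = acc)
}

#' Run a random-walk Metropolis--Hastings chain on a generic target
#'
#' Low-level sampler used both for the model posterior and for analytic toy
#' targets in tests.
#'
#' @param logpost log-density function of a numeric vector.
#' @param theta0 starting point.
#' @param s proposal standard deviation.
#' @param n_iter number of iterations.
#' @param seed optional integer seed (set before sampling).
#' @return List with `draws` (n_iter x d), `log_posterior`, `accepted`.
#' @export
run_mh <- function(logpost, theta0, s, n_iter, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .mh_loop(logpost, theta0, s, n_iter)
}

#' Tune the proposal step size
#'
#' Robbins--Monro stochastic approximation on `log s` during a pilot phase:
#' after every batch the log step size moves by `gain * (batch acceptance -
#' target)` with a decaying gain, then the tuned value is frozen and checked
#' on a confirmation run.  The target acceptance 0.234 is the classical
#' optimum for random-walk proposals in moderate dimension.
#'
#' @param logpost log-posterior function.
#' @param theta0 starting point.
#' @param s0 initial step size.
#' @param target target acceptance rate.
#' @param pilot_length iterations per adaptation round (>= 500).
#' @param batch batch length between updates.
#' @param max_rounds maximum adaptation rounds before giving up.
#' @param band acceptable acceptance band for the frozen confirmation run.
#' @param seed optional integer seed.
#' @return Tuned `s`, with the realized confirmation acceptance rate and the
#'   final pilot state in attributes `"acceptance"` and `"theta"`.
#' @export
tune_step_size <- function(logpost, theta0, s0 = 0.5, target = 0.234,
                           pilot_length = 2000, batch = 100, max_rounds = 5,
                           band = c(0.15, 0.35), seed = NULL) {
  stopifnot(pilot_length >= 500, s0 > 0)
  if (!is.null(seed)) set.seed(seed)
  s <- s0
  theta <- theta0
  for (round in seq_len(max_rounds)) {
    nbatch <- ceiling(pilot_length / batch)
    for (b in seq_len(nbatch)) {
      res <- .mh_loop(logpost, theta, s, batch)
      theta <- res$draws[batch, ]
      # gain restarts each round: early rounds also pull the chain toward
      # the typical set, so late rounds must stay able to correct s
      gain <- 2 / (1 + b)^0.6
      s <- exp(log(s) + gain * (mean(res$accepted) - target))
    }
    conf <- .mh_loop(logpost, theta, s, max(500, pilot_length %/% 2))
    rate <- mean(conf$accepted)
    theta <- conf$draws[nrow(conf$draws), ]
    if (rate >= band[1] && rate <= band[2]) {
      attr(s, "acceptance") <- rate
      attr(s, "theta") <- theta
      return(s)
    }
  }
  stop(sprintf("step-size tuning failed: confirmation acceptance %.3f outside [%g, %g] after %d rounds (s = %g)",
               rate, band[1], band[2], max_rounds, s))
}

#' Run the posterior sampling chain for a growth dataset
#'
#' Ties the pieces together: builds the log-posterior closure, tunes the
#' proposal step (unless `s` is given), and runs the production chain.  The
#' full chain is stored with a burn-in marker; nothing is discarded.  A
#' single `seed` fans out into separate tuning and sampling streams so runs
#' are reproducible end to end.
#'
#' @param data a [growth_dataset()].
#' @param priors a [prior_spec()].
#' @param config a [forward_config()]; desk-scale inference default is
#'   `forward_config(N = 400)`.
#' @param n_iter production iterations.
#' @param burn_in burn-in length (< n_iter), marked but kept.
#' @param seed integer seed.
#' @param s proposal sd; `NULL` (default) tunes it first.
#' @param theta0 starting log-parameter vector; defaults to the prior
#'   medians.
#' @param pilot_length pilot iterations per tuning round.
#' @param checkpoint_file optional RDS path written every `checkpoint_every`
#'   iterations, from which [resume_chain()] can continue an interrupted
#'   run.
#' @param checkpoint_every checkpoint interval, iterations.
#' @return An object of class `ebt_chain`.
#' @export
run_chain <- function(data, priors, config = forward_config(N = 400),
                      n_iter = 20000, burn_in = 2000, seed = 1, s = NULL,
                      theta0 = NULL, pilot_length = 2000,
                      checkpoint_file = NULL, checkpoint_every = 5000) {
  stopifnot(inherits(data, "growth_dataset"), n_iter > burn_in, burn_in >= 0)
  logpost <- make_log_posterior(data, priors, config)
  config <- attr(logpost, "config")
  if (is.null(theta0)) theta0 <- log(priors$medians)
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, 2)
  if (is.null(s)) {
    s <- tune_step_size(logpost, theta0, seed = seeds[1],
                        pilot_length = pilot_length)
    theta0 <- attr(s, "theta")
    pilot_acc <- attr(s, "acceptance")
    s <- as.numeric(s)
  } else pilot_acc <- NA_real_
  set.seed(seeds[2])
  if (is.null(checkpoint_file)) {
    res <- .mh_loop(logpost, theta0, s, n_iter)
  } else {
    res <- NULL
    theta <- theta0
    done <- 0
    while (done < n_iter) {
      k <- min(checkpoint_every, n_iter - done)
      part <- .mh_loop(logpost, theta, s, k)
      res <- if (is.null(res)) part else
        list(draws = rbind(res$draws, part$draws),
             log_posterior = c(res$log_posterior, part$log_posterior),
             accepted = c(res$accepted, part$accepted))
      theta <- part$draws[k, ]
      done <- done + k
      saveRDS(list(res = res, theta = theta, rng = .Random.seed, s = s,
                   n_iter = n_iter, burn_in = burn_in, seed = seed,
                   priors = priors, config = config, data = data,
                   pilot_acc = pilot_acc, done = done),
              checkpoint_file)
    }
  }
  colnames(res$draws) <- c("alpha", "sigma_k", "sigma_o", "sigma_i")
  structure(list(draws = res$draws, log_posterior = res$log_posterior,
                 accepted = res$accepted, s = s, seed = seed,
                 burn_in = burn_in, priors = priors, config = config,
                 data = data, pilot_acceptance = pilot_acc),
            class = "ebt_chain")
}

#' Resume an interrupted chain from a checkpoint
#'
#' @param checkpoint_file RDS checkpoint written by [run_chain()].
#' @return A completed `ebt_chain`.
#' @export
resume_chain <- function(checkpoint_file) {
  ck <- readRDS(checkpoint_file)
  if (ck$done >= ck$n_iter) {
    res <- ck$res
  } else {
    logpost <- make_log_posterior(ck$data, ck$priors, ck$config)
    assign(".Random.seed", ck$rng, envir = globalenv())
    res <- ck$res
    theta <- ck$theta
    done <- ck$done
    while (done < ck$n_iter) {
      k <- min(5000, ck$n_iter - done)
      part <- .mh_loop(logpost, theta, ck$s, k)
      res <- list(draws = rbind(res$draws, part$draws),
                  log_posterior = c(res$log_posterior, part$log_posterior),
                  accepted = c(res$accepted, part$accepted))
      theta <- part$draws[k, ]
      done <- done + k
    }
  }
  colnames(res$draws) <- c("alpha", "sigma_k", "sigma_o", "sigma_i")
  structure(list(draws = res$draws, log_posterior = res$log_posterior,
                 accepted = res$accepted, s = ck$s, seed = ck$seed,
                 burn_in = ck$burn_in, priors = ck$priors, config = ck$config,
                 data = ck$data, pilot_acceptance = ck$pilot_acc),
            class = "ebt_chain")
}

#' @export
print.ebt_chain <- function(x, ...) {
  n <- length(x$log_posterior)
  cat(sprintf("Metropolis-Hastings chain: %d iterations (burn-in %d), s = %.4g, acceptance = %.3f\n",
              n, x$burn_in, x$s, mean(x$accepted)))
  post <- exp(x$draws[(x$burn_in + 1):n, , drop = FALSE])
  print(t(apply(post, 2, quantile, c(0.025, 0.5, 0.975))))
  invisible(x)
}

#' Post-burn-in draws of a chain
#'
#' @param chain an `ebt_chain`.
#' @param natural return natural-scale parameters (`exp`) instead of logs.
#' @return Matrix of draws.
#' @export
chain_draws <- function(chain, natural = FALSE) {
  stopifnot(inherits(chain, "ebt_chain"))
  d <- chain$draws[(chain$burn_in + 1):nrow(chain$draws), , drop = FALSE]
  if (natural) exp(d) else d
}

#' MAP estimate from a chain
#'
#' The post-burn-in draw with the largest stored log posterior, optionally
#' polished by Nelder--Mead on the log posterior (polishing can only
#' increase the posterior value; if the local search fails to improve, the
#' chain draw is kept).
#'
#' @param chain an `ebt_chain`.
#' @param polish run a local derivative-free optimization from the best
#'   draw.
#' @param logpost log-posterior function, required when `polish = TRUE`.
#' @return A [model_params()] with attributes `log_posterior` and
#'   `theta_log`.
#' @export
map_estimate <- function(chain, polish = FALSE, logpost = NULL) {
  stopifnot(inherits(chain, "ebt_chain"))
  idx <- (chain$burn_in + 1):nrow(chain$draws)
  if (length(idx) < 1) stop("no post-burn-in draws")
  best <- idx[which.max(chain$log_posterior[idx])]
  theta <- chain$draws[best, ]
  lp <- chain$log_posterior[best]
  if (polish) {
    if (is.null(logpost))
      logpost <- make_log_posterior(chain$data, chain$priors, chain$config)
    opt <- optim(theta, function(x) -logpost(x), method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-8))
    if (-opt$value >= lp) { theta <- opt$par; lp <- -opt$value }
  }
  out <- params_from_log(theta)
  attr(out, "log_posterior") <- lp
  attr(out, "theta_log") <- theta
  out
}

#' Chain diagnostics
#'
#' Normalized autocorrelation per log-parameter, trace summaries, and the
#' realized acceptance rate, computed on the post-burn-in segment.
#'
#' @param chain an `ebt_chain`.
#' @param lag_max maximum autocorrelation lag.
#' @return List with `autocorrelation` (matrix, lags x parameters),
#'   `summary` (per-parameter posterior quantiles on the natural scale),
#'   `acceptance`.
#' @export
diagnostics <- function(chain, lag_max = 50) {
  d <- chain_draws(chain)
  if (nrow(d) < 100) stop("need at least 100 post-burn-in draws")
  ac <- apply(d, 2, function(v)
    as.numeric(acf(v, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf))
  rownames(ac) <- 0:lag_max
  nat <- exp(d)
  summ <- t(apply(nat, 2, function(v)
    c(mean = mean(v), sd = sd(v),
      quantile(v, c(0.025, 0.5, 0.975)))))
  list(autocorrelation = ac, summary = summ,
       acceptance = mean(chain$accepted[(chain$burn_in + 1):length(chain$accepted)]))
}

#' Posterior-predictive credible band for diameters
#'
#' Pushes a thinned posterior sub-sample through the forward solver and
#' returns pointwise quantiles of the predicted diameter (2 x radius) over
#' time, plus the curve at the posterior mean of the log-parameters.
#'
#' @param chain an `ebt_chain`.
#' @param times prediction times, days; defaults to the chain's data times.
#' @param n_draws number of posterior draws pushed through the solver.
#' @param level credible level (default 0.95).
#' @param seed thinning seed.
#' @return Data frame with `time`, `lower`, `upper`, `mean_curve` (mm,
#'   diameters).
#' @export
predictive_band <- function(chain, times = NULL, n_draws = 100, level = 0.95,
                            seed = 1) {
  stopifnot(inherits(chain, "ebt_chain"))
  if (is.null(times)) times <- chain$data$times
  d <- chain_draws(chain)
  set.seed(seed)
  pick <- sample(nrow(d), min(n_draws, nrow(d)))
  curves <- vapply(pick, function(i) {
    2 * forward_radii(params_from_log(d[i, ]), times, chain$config)
  }, numeric(length(times)))
  curves <- matrix(curves, nrow = length(times))
  a <- (1 - level) / 2
  mean_curve <- 2 * forward_radii(params_from_log(colMeans(d)), times,
                                  chain$config)
  data.frame(time = times,
             lower = apply(curves, 1, quantile, a),
             upper = apply(curves, 1, quantile, 1 - a),
             mean_curve = mean_curve)
}

#' Total-variation distance between smoothed chain marginals
#'
#' Kernel-density smooths the post-burn-in marginal of each log-parameter in
#' both chains on a common grid (shared bandwidth) and returns
#' `0.5 * int |f - g|` per parameter.  Note that between independently run
#' chains this distance includes the chains' own Monte-Carlo error; for
#' comparing posteriors across solver resolutions use
#' [posterior_stability_report()], which shares one sample across the
#' resolutions.
#'
#' @param chain_a,chain_b `ebt_chain` objects over the same parameters.
#' @param n_grid density grid size.
#' @return Named vector of per-parameter TV distances with the mean in
#'   attribute `"mean"`.
#' @export
marginal_tv <- function(chain_a, chain_b, n_grid = 512) {
  da <- chain_draws(chain_a); db <- chain_draws(chain_b)
  stopifnot(ncol(da) == ncol(db))
  out <- vapply(seq_len(ncol(da)), function(j) {
    xa <- da[, j]; xb <- db[, j]
    bw <- mean(c(stats::bw.nrd0(xa), stats::bw.nrd0(xb)))
    lo <- min(xa, xb) - 3 * bw; hi <- max(xa, xb) + 3 * bw
    fa <- density(xa, bw = bw, from = lo, to = hi, n = n_grid)
    fb <- density(xb, bw = bw, from = lo, to = hi, n = n_grid)
    dx <- fa$x[2] - fa$x[1]
    ya <- fa$y / sum(fa$y * dx); yb <- fb$y / sum(fb$y * dx)
    0.5 * sum(abs(ya - yb)) * dx
  }, numeric(1))
  names(out) <- colnames(da)
  attr(out, "mean") <- mean(out)
  out
}

#' Export a chain to CSV
#'
#' One row per iteration: the four log-parameters, the four natural
#' parameters, the log posterior, and the acceptance flag.
#'
#' @param chain an `ebt_chain`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chain_csv <- function(chain, path) {
  d <- chain$draws
  df <- data.frame(iteration = seq_len(nrow(d)))
  for (j in colnames(d)) df[[paste0("log_", j)]] <- d[, j]
  for (j in colnames(d)) df[[j]] <- exp(d[, j])
  df$log_posterior <- chain$log_posterior
  df$accepted <- as.integer(chain$accepted)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
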