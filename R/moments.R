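#' Analytic forward moments of the accumulation model
#'
#' The accumulator given the click trains is Gaussian at every time with
#' mean and variance available in closed form: the mean is the
#' exponentially discounted sum of adapted click magnitudes (right minus
#' left) and the variance accrues the initial variance, the memory
#' diffusion, and one per-click noise term per click (both sides entering
#' with positive sign).  The \code{lam -> 0} limit is handled by series
#' expansion.
#'
#' @param trial a \code{dc_trial}.
#' @param theta a \code{\link{model_params}} object.
#' @param times evaluation times in seconds (default: 1 ms grid over the
#'   trial).
#' @param mu0 mean of the initial condition (default 0).
#' @return An object of class \code{dc_gaussian_trace}: list with
#'   \code{times}, \code{mu}, \code{var}.
#' @export
forward_moments <- function(trial, theta, times = NULL, mu0 = 0) {
  stopifnot(inherits(theta, "dc_params"))
  if (is.null(times))
    times <- unique(c(seq(0, trial$duration, by = 0.001), trial$duration))
  ac <- adapt_clicks(trial, theta$phi, theta$tau_phi)
  lam <- theta$lam
  mu <- rep(mu0 * exp(lam * times), length.out = length(times))
  var <- theta$sigma_i2 * exp(2 * lam * times) +
    theta$sigma_a2 * times * exprel(2 * lam * times)
  if (length(ac$times) > 0) {
    # lag[t, i] = t - s_i, masked to clicks with s_i <= t
    lag <- outer(times, ac$times, "-")
    inc <- lag >= 0
    e1 <- exp(lam * lag) * inc
    cw <- if (theta$var_convention == "C2") ac$magnitudes^2 else
      ac$magnitudes
    mu <- mu + as.numeric(e1 %*% (ac$sides * ac$magnitudes))
    var <- var + theta$sigma_s2 * as.numeric((e1^2) %*% cw)
  }
  structure(list(times = times, mu = mu, var = pmax(var, 0)),
            class = "dc_gaussian_trace")
}

# Final-time (t = duration) moments for a set of trials, via the compiled
# sufficient-statistics kernel.  Returns a data.frame(mu, var).
final_moments <- function(trials, theta) {
  dat <- flatten_clicks(trials)
  stats_final_moments(dat, theta)
}

# Concatenate click trains across trials once; reused across likelihood
# evaluations during fitting.
flatten_clicks <- function(trials) {
  mcs <- lapply(trials, merged_clicks)
  nclicks <- vapply(mcs, function(m) length(m$times), 1L)
  list(times = unlist(lapply(mcs, `[[`, "times")),
       sides = unlist(lapply(mcs, `[[`, "sides")),
       starts = c(0L, cumsum(nclicks))[seq_along(nclicks)],
       nclicks = nclicks,
       t_end = vapply(trials, function(x) x$duration, 1),
       choice = vapply(trials, function(x) as.integer(x$choice), 1L))
}

stats_final_moments <- function(dat, theta) {
  s <- trial_stats_cpp(dat$times, dat$sides, dat$starts, dat$nclicks,
                       dat$t_end, theta$lam, theta$phi, theta$tau_phi)
  lam <- theta$lam
  tN <- dat$t_end
  vclick <- if (theta$var_convention == "C2") s[, 3] else s[, 2]
  var <- theta$sigma_i2 * exp(2 * lam * tN) +
    theta$sigma_a2 * tN * exprel(2 * lam * tN) +
    theta$sigma_s2 * vclick
  data.frame(mu = s[, 1], var = pmax(var, 0))
}

# P(a_N > B) for given final moments; degenerate variance becomes a step.
tail_above <- function(mu, var, B) {
  sd <- sqrt(var)
  ifelse(sd > 0, stats::pnorm((mu - B) / sd), as.numeric(mu > B))
}

#' Probability of a rightward choice
#'
#' Gaussian tail probability of the final accumulator value above the
#' decision boundary, mixed with the lapse rate:
#' \code{P(right) = (1 - lapse) * P(a_N > B) + lapse/2}.
#'
#' @param trial a \code{dc_trial} (or \code{dc_trials} list, vectorized).
#' @param theta a \code{\link{model_params}} object.
#' @return Probability (vector) of a rightward choice.
#' @export
choice_prob <- function(trial, theta) {
  trials <- if (inherits(trial, "dc_trial")) list(trial) else trial
  fm <- final_moments(trials, theta)
  p <- tail_above(fm$mu, fm$var, theta$B)
  (1 - theta$lapse) * p + theta$lapse / 2
}

#' Negative log-likelihood of observed choices
#'
#' Sum over trials of \code{-log P(y_i | theta)} plus half-Gaussian prior
#' penalties on the initial and memory noise variances.  Probabilities are
#' floored at 1e-10 before taking logs.
#'
#' @param trials a \code{dc_trials} list; every trial must have a choice
#'   (+1 right, -1 left).
#' @param theta a \code{\link{model_params}} object.
#' @param prior_sd named numeric: half-Gaussian prior SDs for
#'   \code{sigma_i2} and \code{sigma_a2} (default 30 each; \code{Inf}
#'   disables a prior).
#' @return Scalar negative log-likelihood (plus prior penalty).
#' @export
negative_log_likelihood <- function(trials, theta,
                                    prior_sd = c(sigma_i2 = 30,
                                                 sigma_a2 = 30)) {
  dat <- flatten_clicks(trials)
  if (anyNA(dat$choice)) stop("every trial must have a defined choice")
  nll_from_data(dat, theta, prior_sd)
}

nll_from_data <- function(dat, theta, prior_sd) {
  nll <- nll_cpp(dat$times, dat$sides, dat$starts, dat$nclicks,
                 dat$t_end, dat$choice, theta$sigma_i2, theta$sigma_a2,
                 theta$sigma_s2, theta$lam, theta$phi, theta$tau_phi,
                 theta$B, theta$lapse,
                 as.integer(theta$var_convention == "C2"))
  if (is.finite(prior_sd[["sigma_i2"]]))
    nll <- nll + theta$sigma_i2^2 / (2 * prior_sd[["sigma_i2"]]^2)
  if (is.finite(prior_sd[["sigma_a2"]]))
    nll <- nll + theta$sigma_a2^2 / (2 * prior_sd[["sigma_a2"]]^2)
  nll
}

#' Fit the accumulation model by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) minimization of
#' \code{\link{negative_log_likelihood}} with optional multi-start, and
#' parameter standard errors from the inverse numeric Hessian at the
#' optimum.
#'
#' @param trials a \code{dc_trials} list with choices.
#' @param theta0 starting \code{\link{model_params}} (also fixes the
#'   per-click variance convention).
#' @param lower,upper named bound vectors over
#'   \code{sigma_i2, sigma_a2, sigma_s2, lam, phi, tau_phi, B, lapse}.
#' @param n_starts number of optimizer starts (the first from
#'   \code{theta0}, the rest drawn uniformly within bounds).
#' @param seed RNG seed controlling the restart draws.
#' @param prior_sd see \code{\link{negative_log_likelihood}}.
#' @return An object of class \code{dc_fit}: list with \code{theta_hat},
#'   \code{nll}, \code{se} (NA where the Hessian is not positive
#'   definite), \code{hessian}, \code{convergence} (0 = converged),
#'   \code{starts} (per-start NLLs).
#' @export
fit_parameters <- function(trials, theta0 = model_params(
                             sigma_i2 = 0.5, sigma_a2 = 0.5,
                             sigma_s2 = 0.5, lam = -1, phi = 0.8,
                             tau_phi = 0.1, B = 0, lapse = 0.02),
                           lower = c(sigma_i2 = 1e-6, sigma_a2 = 1e-6,
                                     sigma_s2 = 1e-6, lam = -40,
                                     phi = 0.02, tau_phi = 0.02,
                                     B = -5, lapse = 1e-4),
                           upper = c(sigma_i2 = 25, sigma_a2 = 50,
                                     sigma_s2 = 25, lam = 5, phi = 2,
                                     tau_phi = 1.5, B = 5,
                                     lapse = 0.999),
                           n_starts = 3, seed = NULL,
                           prior_sd = c(sigma_i2 = 30, sigma_a2 = 30)) {
  dat <- flatten_clicks(trials)
  if (anyNA(dat$choice)) stop("every trial must have a defined choice")
  conv <- theta0$var_convention
  # cache the click-train statistics: they depend only on
  # (lam, phi, tau_phi), so finite-difference perturbations of the
  # other five parameters reuse them
  cache <- list(key = NULL, s = NULL)
  obj <- function(v) {
    th <- tryCatch(vec_to_params(v, conv), error = function(e) NULL)
    if (is.null(th)) return(1e12)
    key <- c(th$lam, th$phi, th$tau_phi)
    if (is.null(cache$key) || !identical(cache$key, key)) {
      cache <<- list(key = key,
                     s = trial_stats_cpp(dat$times, dat$sides,
                                         dat$starts, dat$nclicks,
                                         dat$t_end, th$lam, th$phi,
                                         th$tau_phi))
    }
    s <- cache$s
    vclick <- if (conv == "C2") s[, 3] else s[, 2]
    var <- th$sigma_i2 * exp(2 * th$lam * dat$t_end) +
      th$sigma_a2 * dat$t_end * exprel(2 * th$lam * dat$t_end) +
      th$sigma_s2 * vclick
    p_right <- (1 - th$lapse) * tail_above(s[, 1], pmax(var, 0), th$B) +
      th$lapse / 2
    p <- ifelse(dat$choice == 1L, p_right, 1 - p_right)
    val <- -sum(log(pmax(p, 1e-10)))
    if (is.finite(prior_sd[["sigma_i2"]]))
      val <- val + th$sigma_i2^2 / (2 * prior_sd[["sigma_i2"]]^2)
    if (is.finite(prior_sd[["sigma_a2"]]))
      val <- val + th$sigma_a2^2 / (2 * prior_sd[["sigma_a2"]]^2)
    if (!is.finite(val)) 1e12 else val
  }
  lower <- lower[param_names]; upper <- upper[param_names]
  starts <- list(params_to_vec(theta0))
  if (n_starts > 1) {
    extra <- with_seed(derive_seed(seed, "fit_starts"), {
      lapply(seq_len(n_starts - 1), function(i) {
        v <- stats::runif(8, lower, pmin(upper, c(5, 5, 5, 2, 1.5, 0.5,
                                                  1, 0.2)))
        stats::setNames(v, param_names)
      })
    })
    starts <- c(starts, extra)
  }
  best <- NULL
  start_nlls <- numeric(0)
  for (s in starts) {
    res <- tryCatch(
      stats::optim(pmin(pmax(s, lower), upper), obj,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e9,
                                  pgtol = 1e-2)),
      error = function(e) NULL)
    if (is.null(res)) next
    start_nlls <- c(start_nlls, res$value)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed")
  H <- tryCatch(stats::optimHess(best$par, obj), error = function(e) NULL)
  se <- rep(NA_real_, 8)
  if (!is.null(H)) {
    # parameters pinned at a bound have no interior curvature; standard
    # errors come from the Hessian restricted to the free parameters
    tol <- 1e-6
    free <- which(best$par > lower + tol & best$par < upper - tol)
    cov <- tryCatch(solve(H[free, free, drop = FALSE]),
                    error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      se[free] <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  names(se) <- param_names
  structure(list(theta_hat = vec_to_params(best$par, conv),
                 nll = best$value, se = se, hessian = H,
                 convergence = best$convergence,
                 starts = start_nlls),
            class = "dc_fit")
}

#' @export
print.dc_fit <- function(x, ...) {
  cat("Accumulation-model fit (NLL =", round(x$nll, 2), ")\n")
  tab <- cbind(estimate = params_to_vec(x$theta_hat), se = x$se)
  print(round(tab, 4))
  invisible(x)
}
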