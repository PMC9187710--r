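#' Simulate the accumulation SDE on one trial
#'
#' Draws one accumulator path and the resulting choice.  The path is
#' sampled at the grid points of a regular time grid with an exact
#' exponential integrator: between grid points the accumulator is a linear
#' (Ornstein-Uhlenbeck) process whose transition is known in closed form,
#' and each click enters at its exact time with its adapted magnitude and
#' per-click noise.  The sampled values therefore follow the model's exact
#' finite-dimensional distributions at the grid points for any \code{dt}.
#'
#' @param trial a \code{dc_trial}.
#' @param theta a \code{\link{model_params}}.
#' @param dt grid step in seconds (default 1 ms).
#' @param a0 optional fixed initial value (default: drawn from
#'   \code{N(0, sigma_i2)}).
#' @return List with \code{times}, \code{a} (path at grid points, starting
#'   at t = 0), \code{a_N} (final value), \code{choice} (+1/-1),
#'   \code{lapsed} (logical), \code{hit}.
#' @export
simulate_agent <- function(trial, theta, dt = 0.001, a0 = NULL) {
  stopifnot(inherits(theta, "dc_params"))
  if (dt > 0.001 + 1e-12) stop("dt must be <= 1 ms")
  dur <- trial$duration
  n_full <- floor(dur / dt + 1e-9)
  times <- c(seq(0, n_full * dt, by = dt),
             if (n_full * dt < dur - 1e-12) dur)
  nstep <- length(times) - 1
  if (is.null(a0)) a0 <- stats::rnorm(1, 0, sqrt(theta$sigma_i2))

  ac <- adapt_clicks(trial, theta$phi, theta$tau_phi)
  lam <- theta$lam
  # noisy click contributions, assigned to the first grid point >= click time
  input <- numeric(nstep)
  if (length(ac$times) > 0) {
    eps <- click_noise(ac$magnitudes, theta)
    amp <- ac$sides * (ac$magnitudes + eps)
    idx <- pmin(pmax(ceiling((ac$times - 1e-12) / dt), 1L), nstep)
    # clicks in the irregular final interval map to the last step
    contrib <- amp * exp(lam * (times[idx + 1] - ac$times))
    input <- as.numeric(tapply(contrib, factor(idx, levels = seq_len(nstep)),
                               sum, default = 0))
  }
  step_len <- diff(times)
  mem_sd <- sqrt(theta$sigma_a2 * step_len * exprel(2 * lam * step_len))
  input <- input + stats::rnorm(nstep, 0, mem_sd)

  if (nstep == 0) {
    a <- a0
  } else if (length(unique(round(step_len, 12))) == 1) {
    a <- c(a0, as.numeric(stats::filter(input, exp(lam * dt),
                                        method = "recursive", init = a0)))
  } else {
    # regular part via the linear recursion, final partial step by hand
    a_reg <- as.numeric(stats::filter(input[-nstep], exp(lam * dt),
                                      method = "recursive", init = a0))
    a <- c(a0, a_reg,
           a_reg[length(a_reg)] * exp(lam * step_len[nstep]) + input[nstep])
  }
  a_N <- a[length(a)]
  lapsed <- stats::runif(1) < theta$lapse
  choice <- if (lapsed) sample(c(-1L, 1L), 1) else
    if (a_N > theta$B) 1L else -1L
  hit <- (choice == 1L) == (trial$final_state == 1L)
  list(times = times, a = a, a_N = a_N, choice = choice,
       lapsed = lapsed, hit = hit)
}

# Per-click additive noise under the configured variance convention:
# "C"  -> epsilon ~ N(0, sigma_s2 * C)        (variance proportional to C)
# "C2" -> epsilon = C*(eta - 1), eta ~ N(1, sigma_s2)  (variance prop. C^2)
click_noise <- function(magnitudes, theta) {
  n <- length(magnitudes)
  if (theta$var_convention == "C2")
    magnitudes * stats::rnorm(n, 0, sqrt(theta$sigma_s2))
  else
    stats::rnorm(n, 0, sqrt(theta$sigma_s2 * magnitudes))
}

#' Simulate an ensemble of accumulator paths on one trial
#'
#' Event-driven exact sampler used as the Monte-Carlo oracle for the
#' analytic forward moments and the posterior: the process is advanced
#' click-to-click with the closed-form Ornstein-Uhlenbeck transition and
#' recorded at the requested times.
#'
#' @param trial a \code{dc_trial}.
#' @param theta a \code{\link{model_params}}.
#' @param n number of paths.
#' @param times recording times (ascending, within [0, duration]).
#' @return List with \code{at} (an \code{n x length(times)} matrix of path
#'   values; a click at exactly a recording time is included),
#'   \code{a_N} (values at trial end), and \code{choice} (+1/-1 per path,
#'   lapse included).
#' @export
simulate_ensemble <- function(trial, theta, n, times = numeric(0)) {
  stopifnot(inherits(theta, "dc_params"))
  ac <- adapt_clicks(trial, theta$phi, theta$tau_phi)
  lam <- theta$lam
  ev_t <- c(ac$times, times, trial$duration)
  # type 1 = click, 2 = record, 3 = end; clicks first at exact ties
  ev_type <- c(rep(1L, length(ac$times)), rep(2L, length(times)), 3L)
  ev_aux <- c(seq_along(ac$times), seq_along(times), 0L)
  o <- order(ev_t, ev_type)
  a <- stats::rnorm(n, 0, sqrt(theta$sigma_i2))
  at <- matrix(NA_real_, n, length(times))
  t_cur <- 0
  for (k in o) {
    dtk <- ev_t[k] - t_cur
    if (dtk > 0) {
      sd <- sqrt(theta$sigma_a2 * dtk * exprel(2 * lam * dtk))
      a <- a * exp(lam * dtk) + stats::rnorm(n, 0, sd)
      t_cur <- ev_t[k]
    }
    if (ev_type[k] == 1L) {
      i <- ev_aux[k]
      Cm <- ac$magnitudes[i]
      sd_c <- if (theta$var_convention == "C2")
        Cm * sqrt(theta$sigma_s2) else sqrt(theta$sigma_s2 * Cm)
      a <- a + ac$sides[i] * (Cm + stats::rnorm(n, 0, sd_c))
    } else if (ev_type[k] == 2L) {
      at[, ev_aux[k]] <- a
    }
  }
  lapsed <- stats::runif(n) < theta$lapse
  choice <- ifelse(a > theta$B, 1L, -1L)
  choice[lapsed] <- sample(c(-1L, 1L), sum(lapsed), replace = TRUE)
  list(at = at, a_N = a, choice = choice)
}

#' Attach model-driven choices to a trial set
#'
#' Simulates one accumulator path per trial and stores the resulting
#' choice and outcome on each trial.
#'
#' @param trials a \code{dc_trials} list.
#' @param theta a \code{\link{model_params}}.
#' @param dt simulation grid step (s).
#' @param seed optional RNG seed.
#' @param keep_paths if TRUE, the latent paths are attached as the
#'   \code{"paths"} attribute (list of \code{times}/\code{a} per trial).
#' @return The trials with \code{choice} and \code{hit} filled in.
#' @export
simulate_choices <- function(trials, theta, dt = 0.001, seed = NULL,
                             keep_paths = FALSE) {
  with_seed(seed, {
    paths <- vector("list", length(trials))
    for (i in seq_along(trials)) {
      sim <- simulate_agent(trials[[i]], theta, dt = dt)
      trials[[i]]$choice <- sim$choice
      trials[[i]]$hit <- sim$hit
      if (keep_paths) paths[[i]] <- list(times = sim$times, a = sim$a)
    }
    if (keep_paths) attr(trials, "paths") <- paths
    trials
  })
}
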