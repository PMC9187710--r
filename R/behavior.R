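#' Ideal-observer log-odds for the dynamic clicks task
#'
#' Exact discrete-time Bayesian filter on the two-state telegraph process:
#' at each step the belief is propagated through the hazard-rate Markov
#' transition and updated with the click likelihood, which reduces to
#' \code{kappa * (nR - nL)} with \code{kappa = log(rate_high/rate_low)}
#' because the total click rate is state-independent.  In continuous time
#' this filter is \code{da/dt = kappa*(dR - dL) - 2h*sinh(a)}, the
#' nonlinear discounting update optimal for this task family.
#'
#' @param trial a \code{dc_trial}.
#' @param task a \code{\link{task_params}}.
#' @param dt filter step in seconds (default 1 ms).
#' @return Class \code{dc_ideal}: list with \code{times} (bin right edges),
#'   \code{logodds} (of state 1, "go right", after each bin),
#'   \code{final} (log-odds at trial end) and the click weight
#'   \code{kappa}.
#' @export
ideal_observer_logodds <- function(trial, task = task_params(),
                                   dt = 0.001) {
  if (task$rate_low <= 0) stop("rate_low must be > 0 (kappa is infinite)")
  kappa <- log(task$rate_high / task$rate_low)
  nbin <- max(1L, ceiling(trial$duration / dt - 1e-9))
  edges <- c(seq(0, by = dt, length.out = nbin), trial$duration)
  nr <- tabulate(pmin(findInterval(trial$right_clicks, edges,
                                   left.open = TRUE) + 1L, nbin), nbin)
  nl <- tabulate(pmin(findInterval(trial$left_clicks, edges,
                                   left.open = TRUE) + 1L, nbin), nbin)
  # clicks at exactly t = 0 land in the first bin
  nr[1] <- nr[1] + sum(trial$right_clicks == 0)
  nl[1] <- nl[1] + sum(trial$left_clicks == 0)
  lo <- ideal_filter_cpp(nr, nl, dt, task$hazard_rate, kappa, 0)
  structure(list(times = edges[-1], logodds = as.numeric(lo),
                 final = lo[nbin], kappa = kappa),
            class = "dc_ideal")
}

#' Psychometric curve with model overlay
#'
#' Bins trials by a per-trial predictor (canonically the final
#' ideal-observer log-odds), and reports in each bin the empirical
#' probability of a rightward choice with Wilson 95\% binomial intervals,
#' together with the model-predicted curve obtained by averaging
#' \code{\link{choice_prob}} over the same bins in place of the observed
#' choices.
#'
#' @param trials a \code{dc_trials} list with choices.
#' @param theta a \code{\link{model_params}} for the overlay (NULL skips
#'   it).
#' @param predictor numeric per-trial predictor; default computes final
#'   ideal-observer log-odds under \code{task}.
#' @param task task parameters used when \code{predictor} is NULL.
#' @param n_bins number of quantile bins (default 10).
#' @return data.frame with bin centers (mean predictor), \code{n},
#'   \code{p_right}, \code{lower}, \code{upper}, and \code{model} (NA if
#'   no overlay).
#' @export
psychometric <- function(trials, theta = NULL, predictor = NULL,
                         task = task_params(), n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  choice <- vapply(trials, function(x) as.integer(x$choice), 1L)
  if (anyNA(choice)) stop("every trial must have a choice")
  if (is.null(predictor))
    predictor <- vapply(trials, function(tr)
      ideal_observer_logodds(tr, task)$final, 1)
  qs <- stats::quantile(predictor, probs = seq(0, 1, length.out = n_bins + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  bin <- cut(predictor, unique(qs), labels = FALSE)
  pmod <- if (!is.null(theta)) choice_prob(trials, theta) else
    rep(NA_real_, length(trials))
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- which(bin == b)
    k <- sum(choice[i] == 1L)
    ci <- wilson_ci(k, length(i))
    data.frame(predictor = mean(predictor[i]), n = length(i),
               p_right = k / length(i), lower = ci[1], upper = ci[2],
               model = mean(pmod[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Final-state chronometric curve
#'
#' Accuracy as a function of the final-state duration (time from the last
#' hidden-state change, or stimulus onset when there was none, to the go
#' cue), grouped by the number of state changes (0, 1, more than 1), with
#' Wilson 95\% binomial intervals.
#'
#' @param trials a \code{dc_trials} list with choices and outcomes.
#' @param breaks bin edges over final-state duration in seconds.
#' @return data.frame with \code{group} ("0", "1", ">1"), bin
#'   \code{duration} (bin center), \code{n}, \code{accuracy},
#'   \code{lower}, \code{upper}.  Empty (group, bin) cells are omitted.
#' @export
chronometric <- function(trials, breaks = seq(0, 2, by = 0.25)) {
  hit <- vapply(trials, function(x) as.logical(x$hit), NA)
  if (anyNA(hit)) stop("every trial must have an outcome")
  fsd <- vapply(trials, final_state_duration, 1)
  k <- vapply(trials, function(x) length(x$state_changes), 1L)
  group <- ifelse(k == 0, "0", ifelse(k == 1, "1", ">1"))
  bin <- cut(fsd, breaks, labels = FALSE, include.lowest = TRUE)
  rows <- list()
  for (g in c("0", "1", ">1")) for (b in sort(unique(bin[!is.na(bin)]))) {
    i <- which(group == g & !is.na(bin) & bin == b)
    if (length(i) == 0) next
    succ <- sum(hit[i])
    ci <- wilson_ci(succ, length(i))
    rows[[length(rows) + 1]] <- data.frame(
      group = g, duration = (breaks[b] + breaks[b + 1]) / 2,
      n = length(i), accuracy = succ / length(i),
      lower = ci[1], upper = ci[2])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Psychophysical reverse correlation kernel
#'
#' Each trial's click trains are smoothed with a causal Gaussian
#' (SD \code{kernel_sd}) and differenced (right minus left); the expected
#' click difference rate given the generative hidden state,
#' \code{+/-(rate_high - rate_low)}, is subtracted to give the excess click
#' rate.  Excess rates are aligned to trial end over a common window,
#' averaged conditional on choice, and each choice-conditioned kernel is
#' normalized to integrate to one over the window (its units become the
#' effective weight of each moment's clicks on choice).
#'
#' @param trials a \code{dc_trials} list with choices; trials shorter than
#'   the window are skipped.
#' @param task a \code{\link{task_params}} (for the expected rates).
#' @param kernel_sd causal Gaussian SD in seconds (default 0.005).
#' @param window analysis window before trial end in seconds (default 0.5,
#'   the shortest trial).
#' @param dt evaluation step (default 1 ms).
#' @return data.frame with \code{time_to_end} (negative values = before
#'   trial end), and per choice the mean excess rate (\code{excess_right},
#'   \code{excess_left}), its SD across trials, and the normalized kernels
#'   (\code{kernel_right}, \code{kernel_left}).
#' @export
reverse_correlation <- function(trials, task = task_params(),
                                kernel_sd = 0.005, window = 0.5,
                                dt = 0.001) {
  choice <- vapply(trials, function(x) as.integer(x$choice), 1L)
  if (anyNA(choice)) stop("every trial must have a choice")
  keep <- vapply(trials, function(x) x$duration >= window, NA)
  trials <- trials[keep]; choice <- choice[keep]
  tau <- seq(-window, 0, by = dt)  # time relative to trial end
  klen <- ceiling(4 * kernel_sd / dt) * dt
  exp_diff <- task$rate_high - task$rate_low
  excess <- vapply(trials, function(tr) {
    tt <- tr$duration + tau
    d <- smoothed_click_diff(tr, tt, kernel_sd, klen)
    st <- state_at(tr, tt)
    d - ifelse(st == 1L, exp_diff, -exp_diff)
  }, numeric(length(tau)))
  out <- data.frame(time_to_end = tau)
  for (side in c("right", "left")) {
    cc <- if (side == "right") 1L else -1L
    m <- rowMeans(excess[, choice == cc, drop = FALSE])
    s <- apply(excess[, choice == cc, drop = FALSE], 1, stats::sd)
    norm <- sum(m) * dt
    out[[paste0("excess_", side)]] <- m
    out[[paste0("excess_sd_", side)]] <- s
    out[[paste0("kernel_", side)]] <-
      if (abs(norm) > 0) m / norm else m
  }
  out
}

# Causally smoothed click difference rate d(t) evaluated at times tt:
# sum over clicks of a causal Gaussian bump (unit mass) at each click.
smoothed_click_diff <- function(trial, tt, sd, klen) {
  kval <- function(lag) {
    v <- exp(-lag^2 / (2 * sd^2))
    v[lag < 0 | lag > klen] <- 0
    v
  }
  # normalizing constant of the truncated causal kernel
  z <- sd * sqrt(2 * pi) * (stats::pnorm(klen / sd) - 0.5)
  f <- function(clicks) {
    if (length(clicks) == 0) return(numeric(length(tt)))
    rowSums(kval(outer(tt, clicks, "-"))) / z
  }
  f(trial$right_clicks) - f(trial$left_clicks)
}

# Generative hidden state at the requested times.
state_at <- function(trial, tt) {
  flips <- findInterval(tt, trial$state_changes)
  ifelse(flips %% 2 == 0, trial$initial_state,
         3L - trial$initial_state)
}
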