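#' Synthetic neuron specification
#'
#' A synthetic unit fires as an inhomogeneous Poisson process with rate
#' \code{max(0, baseline + m(t - lag) * f(a(t - lag)))}: a separable code
#' in which a bounded sigmoidal evidence tuning curve
#' \code{f(a) = sign * (logistic(slope * (a - midpoint)) - 1/2)} (range
#' [-1/2, 1/2], sign +1 for right-preferring units) is multiplied by a
#' temporal gain \code{m(t) = gain * min(1, t / rise_time)} that rises and
#' then plateaus, and drives the cell with a fixed response lag.  Untuned
#' units (\code{preferred = "none"}) fire at baseline only.
#'
#' @param baseline baseline rate, spikes/s (>= 0).
#' @param gain maximum temporal gain, spikes/s.
#' @param slope,midpoint sigmoid tuning parameters (a-units).
#' @param preferred "right", "left", or "none".
#' @param lag response lag in seconds (default 0.1).
#' @param rise_time time for the gain to reach its plateau (default 0.5 s,
#'   the earliest possible go cue).
#' @return An object of class \code{dc_neuron}.
#' @export
neuron_spec <- function(baseline = 20, gain = 20, slope = 1,
                        midpoint = 0, preferred = c("right", "left",
                                                    "none"),
                        lag = 0.1, rise_time = 0.5) {
  preferred <- match.arg(preferred)
  if (baseline < 0) stop("baseline must be >= 0")
  structure(list(baseline = baseline, gain = gain, slope = slope,
                 midpoint = midpoint, preferred = preferred, lag = lag,
                 rise_time = rise_time),
            class = "dc_neuron")
}

#' Evidence tuning curve of a synthetic unit
#' @param spec a \code{\link{neuron_spec}}.
#' @param a accumulator values.
#' @return f(a), bounded in [-1/2, 1/2]; 0 for untuned units.
#' @export
neuron_tuning <- function(spec, a) {
  if (spec$preferred == "none") return(rep(0, length(a)))
  sgn <- if (spec$preferred == "right") 1 else -1
  sgn * (stats::plogis(spec$slope * (a - spec$midpoint)) - 0.5)
}

#' Temporal gain of a synthetic unit
#' @param spec a \code{\link{neuron_spec}}.
#' @param t times in seconds (stimulus-aligned).
#' @return m(t) in spikes/s; 0 outside [0, Inf).
#' @export
neuron_gain <- function(spec, t) {
  ifelse(t < 0, 0, spec$gain * pmin(1, t / spec$rise_time))
}

# Piecewise-constant (1 ms) firing rate of a unit over [t_min, t_max],
# given the trial's latent path (times/a at 1 ms).
unit_rate_grid <- function(trial, path, spec, t_min, t_max, dt = 0.001) {
  grid <- seq(t_min, t_max, by = dt)
  tt <- grid[-length(grid)]  # left bin edges
  rate <- rep(spec$baseline, length(tt))
  if (spec$preferred != "none") {
    tl <- tt - spec$lag
    ok <- tl >= 0 & tl <= trial$duration
    if (any(ok)) {
      ai <- pmin(pmax(round(tl[ok] / dt) + 1L, 1L), length(path$a))
      rate[ok] <- rate[ok] +
        neuron_gain(spec, tl[ok]) * neuron_tuning(spec, path$a[ai])
    }
  }
  list(edges = grid, rate = pmax(rate, 0))
}

#' Generate a spike train for one unit on one trial
#'
#' Exact thinning sampler for the inhomogeneous Poisson process with the
#' unit's piecewise-constant (1 ms) rate.
#'
#' @param trial a \code{dc_trial}.
#' @param path the trial's latent path as returned by
#'   \code{\link{simulate_agent}} (fields \code{times}, \code{a} at 1 ms).
#' @param spec a \code{\link{neuron_spec}}.
#' @param t_min,t_max spike window relative to stimulus onset (defaults:
#'   -1 s to movement + 0.2 s).
#' @return Ascending spike times in seconds.
#' @export
generate_spikes <- function(trial, path, spec, t_min = -1,
                            t_max = NULL) {
  if (is.null(t_max)) t_max <- trial$movement + 0.2
  rg <- unit_rate_grid(trial, path, spec, t_min, t_max)
  rmax <- max(rg$rate)
  if (rmax <= 0) return(numeric(0))
  n <- stats::rpois(1, rmax * (t_max - t_min))
  if (n == 0) return(numeric(0))
  cand <- sort(stats::runif(n, t_min, t_max))
  idx <- pmin(findInterval(cand, rg$edges), length(rg$rate))
  keep <- stats::runif(n) < rg$rate[idx] / rmax
  cand[keep]
}

default_population <- function(n_units, seed = NULL) {
  with_seed(seed, {
    n_tuned <- round(0.6 * n_units)
    pref <- rep("none", n_units)
    if (n_tuned > 0)
      pref[seq_len(n_tuned)] <- rep(c("right", "left"),
                                    length.out = n_tuned)
    lapply(seq_len(n_units), function(i)
      neuron_spec(baseline = stats::runif(1, 10, 25),
                  gain = stats::runif(1, 15, 30),
                  slope = stats::runif(1, 0.6, 1.2),
                  midpoint = stats::rnorm(1, 0, 0.3),
                  preferred = pref[i]))
  })
}

#' Generate a complete synthetic dataset
#'
#' Task trials, model-driven choices with their latent accumulator paths,
#' and spike trains for a population of synthetic units (by default 60%
#' accumulator-tuned, split evenly between right- and left-preferring, and
#' 40% untuned).  Deterministic given \code{seed}.
#'
#' @param n_trials,n_units dataset size (defaults 5000 trials, 20 units).
#' @param task a \code{\link{task_params}}.
#' @param theta a \code{\link{model_params}} driving the agent.
#' @param specs optional list of \code{\link{neuron_spec}}s (default: the
#'   population above).
#' @param seed master RNG seed; per-stage streams are derived from it.
#' @return A list with \code{trials} (choices filled in), \code{spikes}
#'   (long data.frame: \code{unit_id}, \code{trial_id},
#'   \code{spike_time}), \code{units} (per-unit spec table),
#'   \code{specs}, \code{paths} (ground-truth latent paths), and
#'   \code{theta}/\code{task}.
#' @export
generate_dataset <- function(n_trials = 5000, n_units = 20,
                             task = task_params(),
                             theta = model_params(), specs = NULL,
                             seed = 1) {
  trials <- generate_trials(n_trials, task,
                            seed = derive_seed(seed, "trials"))
  trials <- simulate_choices(trials, theta, keep_paths = TRUE,
                             seed = derive_seed(seed, "agent"))
  paths <- attr(trials, "paths")
  if (is.null(specs)) specs <- default_population(
    n_units, seed = derive_seed(seed, "population"))
  spk <- with_seed(derive_seed(seed, "spikes"), {
    rows <- vector("list", length(specs) * max(n_trials, 1))
    k <- 0
    for (u in seq_along(specs)) for (i in seq_len(n_trials)) {
      st <- generate_spikes(trials[[i]], paths[[i]], specs[[u]])
      k <- k + 1
      rows[[k]] <- if (length(st)) data.frame(unit_id = u, trial_id = i,
                                              spike_time = st) else NULL
    }
    do.call(rbind, rows)
  })
  if (is.null(spk))
    spk <- data.frame(unit_id = integer(0), trial_id = integer(0),
                      spike_time = numeric(0))
  units <- data.frame(
    unit_id = seq_along(specs),
    baseline = vapply(specs, `[[`, 1, "baseline"),
    gain = vapply(specs, `[[`, 1, "gain"),
    slope = vapply(specs, `[[`, 1, "slope"),
    midpoint = vapply(specs, `[[`, 1, "midpoint"),
    preferred = vapply(specs, `[[`, "", "preferred"),
    lag = vapply(specs, `[[`, 1, "lag"))
  list(trials = trials, spikes = spk, units = units, specs = specs,
       paths = paths, theta = theta, task = task)
}
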