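#' Generate a single trial of the dynamic clicks task
#'
#' The hidden state starts in state 1 or 2 with equal probability and
#' switches at exponential inter-event waits with the task hazard rate
#' (an exact simulation of the telegraph process); the telegraph stops at
#' the go cue, so no state change ever falls after \code{duration}.  Within
#' each state epoch the left and right click trains are independent Poisson
#' processes at the state-appropriate rates, drawn as a Poisson count with
#' uniform placement (exact for a homogeneous process).
#'
#' @param task a \code{\link{task_params}} object.
#' @param trial_id identifier stored on the trial.
#' @return An object of class \code{dc_trial}: a list with fields
#'   \code{trial_id}, \code{duration}, \code{left_clicks},
#'   \code{right_clicks}, \code{state_changes}, \code{initial_state},
#'   \code{final_state}, \code{movement} (time the animal leaves the center
#'   port), and \code{choice}/\code{hit} (NA until an agent responds).
#' @export
generate_trial <- function(task = task_params(), trial_id = 1L) {
  stopifnot(inherits(task, "dc_task"))
  duration <- stats::runif(1, task$duration_min, task$duration_max)
  changes <- numeric(0)
  t <- 0
  if (task$hazard_rate > 0) {
    repeat {
      t <- t + stats::rexp(1, task$hazard_rate)
      if (t >= duration) break
      changes <- c(changes, t)
    }
  }
  initial_state <- sample(c(1L, 2L), 1)
  final_state <- if (length(changes) %% 2 == 0) initial_state else
    (3L - initial_state)

  # per-epoch click draws
  edges <- c(0, changes, duration)
  states <- initial_state
  if (length(changes) > 0)
    states <- c(states, ifelse(seq_along(changes) %% 2 == 1,
                               3L - initial_state, initial_state))
  left <- right <- numeric(0)
  for (k in seq_along(states)) {
    len <- edges[k + 1] - edges[k]
    r_right <- if (states[k] == 1L) task$rate_high else task$rate_low
    r_left <- if (states[k] == 1L) task$rate_low else task$rate_high
    nr <- stats::rpois(1, r_right * len)
    nl <- stats::rpois(1, r_left * len)
    right <- c(right, edges[k] + sort(stats::runif(nr, 0, len)))
    left <- c(left, edges[k] + sort(stats::runif(nl, 0, len)))
  }

  structure(list(trial_id = trial_id, duration = duration,
                 left_clicks = left, right_clicks = right,
                 state_changes = changes, initial_state = initial_state,
                 final_state = final_state,
                 movement = duration + stats::runif(1, 0.2, 0.4),
                 choice = NA_integer_, hit = NA),
            class = "dc_trial")
}

#' Generate a set of trials
#'
#' @param n number of trials.
#' @param task a \code{\link{task_params}} object.
#' @param seed optional RNG seed (restores the RNG state afterwards).
#' @return A list of \code{dc_trial} objects with class \code{dc_trials}.
#' @export
generate_trials <- function(n, task = task_params(), seed = NULL) {
  with_seed(seed, {
    structure(lapply(seq_len(n), function(i) generate_trial(task, i)),
              class = "dc_trials")
  })
}

#' Summarize trials as a data frame
#'
#' One row per trial with scalar fields and event counts; the per-trial
#' event-time vectors stay on the \code{dc_trial} objects.
#'
#' @param trials a \code{dc_trials} list.
#' @return A data.frame with columns \code{trial_id}, \code{duration},
#'   \code{n_left}, \code{n_right}, \code{n_changes},
#'   \code{final_state_duration}, \code{initial_state}, \code{final_state},
#'   \code{movement}, \code{choice}, \code{hit}.
#' @export
trials_summary <- function(trials) {
  data.frame(
    trial_id = vapply(trials, function(x) as.integer(x$trial_id), 1L),
    duration = vapply(trials, function(x) x$duration, 1),
    n_left = vapply(trials, function(x) length(x$left_clicks), 1L),
    n_right = vapply(trials, function(x) length(x$right_clicks), 1L),
    n_changes = vapply(trials, function(x) length(x$state_changes), 1L),
    final_state_duration = vapply(trials, final_state_duration, 1),
    initial_state = vapply(trials, function(x) x$initial_state, 1L),
    final_state = vapply(trials, function(x) x$final_state, 1L),
    movement = vapply(trials, function(x) x$movement, 1),
    choice = vapply(trials, function(x) as.integer(x$choice), 1L),
    hit = vapply(trials, function(x) as.logical(x$hit), NA)
  )
}

# Final-state duration: time from the last hidden-state change (or stimulus
# onset when there were none) to the go cue.
final_state_duration <- function(trial) {
  last <- if (length(trial$state_changes)) max(trial$state_changes) else 0
  trial$duration - last
}

#' State-change count statistics for a trial set
#'
#' @param trials a \code{dc_trials} list.
#' @return A list with the fraction of trials having zero, exactly one, and
#'   more than one state change, and the mean number of changes per trial.
#' @export
state_change_stats <- function(trials) {
  k <- vapply(trials, function(x) length(x$state_changes), 1L)
  list(frac_zero = mean(k == 0), frac_one = mean(k == 1),
       frac_multi = mean(k > 1), mean_changes = mean(k))
}
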