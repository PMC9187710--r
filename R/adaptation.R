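# Merge a trial's left and right click trains into one ascending train.
# Exact ties are ordered left before right (stable), matching the
# discretized-update convention used throughout.
merged_clicks <- function(trial) {
  times <- c(trial$left_clicks, trial$right_clicks)
  sides <- c(rep(-1, length(trial$left_clicks)),
             rep(1, length(trial$right_clicks)))
  o <- order(times, sides)
  list(times = times[o], sides = sides[o])
}

#' Adapted click magnitudes
#'
#' Runs the sensory adaptation dynamics over a trial's merged click train.
#' The adaptation state C starts at 1; each click's effective magnitude is C
#' evaluated immediately before the click, after which C jumps
#' multiplicatively to \code{phi * C} and relaxes exponentially back toward 1
#' with time constant \code{tau_phi}.  With \code{phi = 1} every magnitude
#' is exactly 1.
#'
#' @param trial a \code{dc_trial}.
#' @param phi adaptation strength (> 0).
#' @param tau_phi recovery time constant in seconds (> 0).
#' @return A list with ascending \code{times}, per-click \code{sides}
#'   (+1 right, -1 left) and \code{magnitudes} (the adapted C values).
#' @export
adapt_clicks <- function(trial, phi, tau_phi) {
  if (phi <= 0 || tau_phi <= 0) stop("phi and tau_phi must be > 0")
  mc <- merged_clicks(trial)
  if (is.unsorted(mc$times)) stop("click times must be ascending")
  mag <- adapt_clicks_cpp(mc$times, phi, tau_phi)
  list(times = mc$times, sides = mc$sides, magnitudes = as.numeric(mag))
}
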