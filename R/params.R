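#' Task parameters for the dynamic clicks environment
#'
#' The environment is a two-state telegraph process: a hidden state switches
#' stochastically with hazard rate \code{hazard_rate}, and each state assigns
#' the high Poisson click rate to one speaker and the low rate to the other.
#' In state 1 ("go right") the right speaker plays at \code{rate_high}; in
#' state 2 ("go left") the rates are swapped.  Stimulus durations are drawn
#' uniformly between \code{duration_min} and \code{duration_max}.
#'
#' @param hazard_rate switch rate of the hidden state, events/s (default 1).
#' @param rate_high click rate on the favored side, clicks/s (default 38).
#' @param rate_low click rate on the disfavored side, clicks/s (default 2).
#' @param duration_min,duration_max stimulus duration bounds in seconds
#'   (defaults 0.5 and 2).
#' @return An object of class \code{dc_task} (a named list).
#' @export
task_params <- function(hazard_rate = 1, rate_high = 38, rate_low = 2,
                        duration_min = 0.5, duration_max = 2) {
  if (hazard_rate < 0) stop("hazard_rate must be >= 0")
  if (!(rate_high > rate_low && rate_low >= 0))
    stop("need rate_high > rate_low >= 0")
  if (!(duration_min > 0 && duration_min <= duration_max))
    stop("need 0 < duration_min <= duration_max")
  structure(list(hazard_rate = hazard_rate, rate_high = rate_high,
                 rate_low = rate_low, duration_min = duration_min,
                 duration_max = duration_max),
            class = "dc_task")
}

#' Accumulation-model parameters
#'
#' The eight parameters of the leaky accumulation model with sensory
#' adaptation: initial variance \code{sigma_i2}, memory (per-second diffusion)
#' variance \code{sigma_a2}, per-click noise variance \code{sigma_s2},
#' discounting rate \code{lam} (negative = leaky), adaptation strength
#' \code{phi} (\code{phi < 1} depresses successive clicks, \code{phi > 1}
#' facilitates), adaptation recovery time constant \code{tau_phi}, decision
#' boundary \code{B} (side bias), and lapse rate \code{lapse}.
#'
#' @param sigma_i2 initial variance of the accumulator (a^2-units).
#' @param sigma_a2 memory-noise variance accrued per second.
#' @param sigma_s2 per-click noise variance per unit adapted magnitude.
#' @param lam evidence discounting rate, 1/s; \code{lam < 0} leaks.
#' @param phi adaptation strength (unitless, > 0).
#' @param tau_phi adaptation recovery time constant, s.
#' @param B decision boundary: the choice is right iff the final accumulator
#'   value exceeds \code{B}.
#' @param lapse probability in [0, 1] of a stimulus-independent random choice.
#' @param var_convention how per-click noise variance scales with the adapted
#'   click magnitude C: \code{"C"} (variance proportional to C, the default)
#'   or \code{"C2"} (proportional to C^2, i.e. multiplicative unit-mean
#'   Gaussian noise on the magnitude).  The simulator and the analytic
#'   moments always use the same convention.
#' @return An object of class \code{dc_params}.
#' @export
model_params <- function(sigma_i2 = 0.2, sigma_a2 = 1, sigma_s2 = 0.5,
                         lam = -3, phi = 0.5, tau_phi = 0.2, B = 0,
                         lapse = 0.05, var_convention = c("C", "C2")) {
  var_convention <- match.arg(var_convention)
  if (sigma_i2 < 0 || sigma_a2 < 0 || sigma_s2 < 0)
    stop("variances must be >= 0")
  if (tau_phi <= 0) stop("tau_phi must be > 0")
  if (phi <= 0) stop("phi must be > 0")
  if (lapse < 0 || lapse > 1) stop("lapse must lie in [0, 1]")
  structure(list(sigma_i2 = sigma_i2, sigma_a2 = sigma_a2,
                 sigma_s2 = sigma_s2, lam = lam, phi = phi,
                 tau_phi = tau_phi, B = B, lapse = lapse,
                 var_convention = var_convention),
            class = "dc_params")
}

#' @export
print.dc_params <- function(x, ...) {
  cat("Accumulation-model parameters:\n")
  v <- unlist(x[c("sigma_i2", "sigma_a2", "sigma_s2", "lam", "phi",
                  "tau_phi", "B", "lapse")])
  print(round(v, 4))
  cat("per-click variance convention:", x$var_convention, "\n")
  invisible(x)
}

param_names <- c("sigma_i2", "sigma_a2", "sigma_s2", "lam", "phi",
                 "tau_phi", "B", "lapse")

#' Convert model parameters to/from a named numeric vector
#'
#' @param theta a \code{\link{model_params}} object.
#' @return \code{params_to_vec}: named numeric vector in the order
#'   \code{sigma_i2, sigma_a2, sigma_s2, lam, phi, tau_phi, B, lapse};
#'   \code{vec_to_params}: a \code{dc_params} built from such a vector.
#' @export
params_to_vec <- function(theta)
  stats::setNames(as.numeric(theta[param_names]), param_names)

#' @rdname params_to_vec
#' @param v numeric vector of length 8 (order as above).
#' @param var_convention per-click variance convention (see
#'   \code{\link{model_params}}).
#' @export
vec_to_params <- function(v, var_convention = "C") {
  stopifnot(length(v) == 8)
  v <- unname(v)
  model_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8],
               var_convention = var_convention)
}
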