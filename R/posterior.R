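#' Backward (choice-constrained) mixture distribution
#'
#' The backward distribution places a unit of probability mass at each point
#' of a grid of final accumulator values on the choice side of the boundary
#' (half-step offsets \code{B + (j - 1/2) * da}) and evolves each mass with
#' the model dynamics run in reversed time: the deterministic affine
#' accumulation map over \code{(t, t_N]} is inverted while the adapted click
#' magnitudes (a property of the stimulus, not of the latent path) are taken
#' from the forward adaptation dynamics.  Component j at time t is Gaussian
#' with mean \code{(x_j - S(t)) * exp(-lam*(t_N - t))}, where \code{S(t)} is
#' the discounted signed sum of adapted clicks in \code{(t, t_N]}, and a
#' component-independent variance collecting the memory and click noise of
#' \code{(t, t_N]} mapped back through the inverse flow.  At \code{t = t_N}
#' every component is a point mass at its grid value.
#'
#' @param trial a \code{dc_trial}.
#' @param theta a \code{\link{model_params}}.
#' @param choice +1 (right) or -1 (left).
#' @param da component grid spacing (a-units).
#' @param a_max outer truncation of the component grid, measured from B
#'   (default: 12 times the maximum forward SD over the trial).
#' @param times evaluation times (default 1 ms grid).
#' @return Class \code{dc_backward}: list with \code{times}, component
#'   final values \code{x}, \code{means} (J x T), \code{var} (length T,
#'   shared across components), equal \code{weights}, and \code{choice}.
#' @export
backward_mixture <- function(trial, theta, choice, da = 0.1,
                             a_max = NULL, times = NULL) {
  if (is.null(times))
    times <- unique(c(seq(0, trial$duration, by = 0.001), trial$duration))
  comp <- post_mixture(trial, theta, choice, times, da, a_max)
  structure(list(times = times, x = comp$x, means = comp$m_b,
                 var = comp$v_b, weights = rep(1 / length(comp$x),
                                               length(comp$x)),
                 choice = choice),
            class = "dc_backward")
}

# Core computation shared by the posterior functions.  Returns forward
# moments, backward component means/variance, normalized log mixture
# weights of the posterior, and the per-component posterior means/variance.
post_mixture <- function(trial, theta, choice, times, da = 0.1,
                         a_max = NULL) {
  stopifnot(choice %in% c(-1, 1))
  if (da <= 0) stop("da must be > 0")
  tN <- trial$duration
  fwd <- forward_moments(trial, theta, times = times)
  mu_f <- fwd$mu
  v_f <- fwd$var
  if (is.null(a_max)) a_max <- 12 * max(sqrt(v_f), 0.5)
  if (a_max <= 0) stop("a_max must exceed 0")
  J <- max(2L, ceiling(a_max / da))
  x <- theta$B + choice * (seq_len(J) - 0.5) * da

  ac <- adapt_clicks(trial, theta$phi, theta$tau_phi)
  lam <- theta$lam
  rem <- tN - times
  # suffix sums over clicks strictly after t
  S <- numeric(length(times))
  Vc <- numeric(length(times))
  if (length(ac$times) > 0) {
    w_drift <- ac$sides * exp(lam * (tN - ac$times)) * ac$magnitudes
    cw <- if (theta$var_convention == "C2") ac$magnitudes^2 else
      ac$magnitudes
    w_var <- exp(2 * lam * (tN - ac$times)) * cw
    after <- outer(ac$times, times, ">")  # clicks x times
    S <- as.numeric(crossprod(after, w_drift))
    Vc <- as.numeric(crossprod(after, w_var))
  }
  v_fwdnoise <- theta$sigma_a2 * rem * exprel(2 * lam * rem) +
    theta$sigma_s2 * Vc
  v_b <- pmax(v_fwdnoise * exp(-2 * lam * rem), 0)
  m_b <- outer(x, S, "-") * rep(exp(-lam * rem), each = J)

  v_sum <- pmax(v_f + v_b, 1e-18)
  logz <- stats::dnorm(m_b, mean = rep(mu_f, each = J),
                       sd = rep(sqrt(v_sum), each = J), log = TRUE)
  logw <- apply(logz, 2, function(col) col - logsumexp(col))
  if (J == 1) logw <- matrix(logw, nrow = 1)
  m_p <- (rep(mu_f * v_b, each = J) + m_b * rep(v_f, each = J)) /
    rep(v_sum, each = J)
  v_p <- v_f * v_b / v_sum
  list(times = times, mu_f = mu_f, v_f = v_f, x = x, m_b = m_b,
       v_b = v_b, logw = logw, m_p = m_p, v_p = v_p)
}

#' Posterior distribution of the accumulator given stimulus and choice
#'
#' Normalized product of the forward Gaussian and the backward mixture,
#' evaluated as probability mass on a regular accumulator grid at each
#' time.  The product of the forward Gaussian with each equal-variance
#' backward component is itself Gaussian, so each time slice is an exact
#' Gaussian mixture; bin masses are computed from Gaussian CDF differences
#' and the mixture weights are normalized per slice in log space.  The
#' lapse process is not part of the conditioning (the posterior assumes a
#' non-lapse choice).
#'
#' @inheritParams backward_mixture
#' @param da_eval evaluation bin width over accumulator values (default
#'   0.1).
#' @param dt_eval time resolution in seconds (default 1 ms).
#' @return Class \code{dc_posterior}: list with bin centers \code{a},
#'   \code{times}, and \code{mass} (length(a) x length(times); each column
#'   sums to 1).
#' @export
posterior_grid <- function(trial, theta, choice, da_eval = 0.1,
                           dt_eval = 0.001, da = 0.1, a_max = NULL) {
  times <- unique(c(seq(0, trial$duration, by = dt_eval), trial$duration))
  comp <- post_mixture(trial, theta, choice, times, da, a_max)
  sd_p <- sqrt(comp$v_p)
  pad <- 8 * max(sd_p, da_eval)
  lo <- min(comp$m_p) - pad
  hi <- max(comp$m_p) + pad
  edges <- seq(lo, hi + da_eval, by = da_eval)
  centers <- edges[-length(edges)] + da_eval / 2
  mass <- mixture_bin_mass(comp, edges)
  structure(list(a = centers, times = times, mass = mass,
                 choice = choice, B = theta$B),
            class = "dc_posterior")
}

# Bin masses of the per-slice posterior mixture on the given ascending
# edges (may include +/-Inf).  Returns (length(edges)-1) x T.
# Each backward component stands for a grid cell of width da, so its
# posterior image is convolved with the affine image of that cell
# (uniform smear, variance = spacing^2 / 12); this keeps bin masses
# stable under grid refinement, including at trial end where the
# component variance vanishes and the mixture degenerates to a comb.
mixture_bin_mass <- function(comp, edges) {
  J <- length(comp$x)
  Tn <- length(comp$times)
  nb <- length(edges) - 1
  mass <- matrix(0, nb, Tn)
  for (t in seq_len(Tn)) {
    w <- exp(comp$logw[, t])
    # drop components with negligible posterior weight (renormalized
    # below; truncation error bounded by J * 1e-12)
    keep <- w > 1e-9
    if (!any(keep)) keep <- rep(TRUE, J)
    w <- w[keep]
    mp <- comp$m_p[keep, t]
    spacing <- if (J > 1) abs(comp$m_p[2, t] - comp$m_p[1, t]) else 0
    P <- comp_cdf(outer(edges, mp, "-"),
                  sqrt(comp$v_p[t]), spacing / 2)
    if (is.null(P)) {
      idx <- findInterval(mp, edges,
                          rightmost.closed = TRUE)
      ok <- idx >= 1 & idx <= nb
      mass[, t] <- as.numeric(tapply(w[ok],
                                     factor(idx[ok], levels = seq_len(nb)),
                                     sum, default = 0))
    } else {
      cell <- P[-1, , drop = FALSE] - P[-(nb + 1), , drop = FALSE]
      mass[, t] <- as.numeric(cell %*% w)
    }
    s <- sum(mass[, t])
    if (s <= 0) stop("posterior slice lost all mass (grid too narrow)")
    mass[, t] <- mass[, t] / s
  }
  mass
}

# CDF (evaluated at edge - mean offsets `d`) of a Gaussian with sd `s`
# convolved with a uniform cell of half-width `h`, the affine image of a
# backward grid cell.  Reduces to the plain Gaussian CDF when h = 0, to
# the uniform-cell overlap when s = 0 (so no mass leaks past the cell,
# preserving the hard choice constraint at trial end), and to NULL when
# both vanish (point-mass fallback).
comp_cdf <- function(d, s, h) {
  if (s <= 1e-12 && h <= 1e-12) return(NULL)
  # the cell smear is immaterial once the Gaussian sd dominates it
  if (h <= 1e-12 || h <= 0.02 * s) return(stats::pnorm(d / s))
  if (s <= 1e-12) return(pmin(pmax((d + h) / (2 * h), 0), 1))
  I <- function(z) {
    out <- z * stats::pnorm(z) + stats::dnorm(z)
    out[z > 1e8] <- z[z > 1e8]  # asymptote, avoids Inf - Inf upstream
    out
  }
  out <- (s / (2 * h)) * (I((d + h) / s) - I((d - h) / s))
  out[d == Inf] <- 1
  out[d == -Inf] <- 0
  pmin(pmax(out, 0), 1)
}

#' Posterior mass in coarse accumulator bins (analytic)
#'
#' Evaluates the posterior's probability mass directly in an arbitrary set
#' of accumulator bins (e.g. the tuning-map bins), without constructing a
#' fine grid: each slice is an exact Gaussian mixture, so bin masses are
#' CDF differences.
#'
#' @inheritParams backward_mixture
#' @param edges ascending bin edges (may include \code{-Inf}/\code{Inf}).
#' @param times evaluation times.
#' @return Matrix (length(edges)-1) x length(times); columns sum to 1.
#' @export
posterior_bin_mass <- function(trial, theta, choice, edges, times,
                               da = 0.1, a_max = NULL) {
  comp <- post_mixture(trial, theta, choice, times, da, a_max)
  mixture_bin_mass(comp, edges)
}

#' Posterior mean trace from a posterior grid
#'
#' Per-slice expectation of the accumulator over the grid's bin centers.
#'
#' @param pg a \code{dc_posterior} from \code{\link{posterior_grid}}.
#' @return Numeric vector of \code{E[a | t, y]} along \code{pg$times}.
#' @export
posterior_mean_trace <- function(pg) {
  stopifnot(inherits(pg, "dc_posterior"))
  as.numeric(crossprod(pg$mass, pg$a))
}

#' Analytic posterior mean of the accumulator
#'
#' The posterior mean at each time, computed from the closed-form mixture
#' representation (no accumulator grid); used for change-of-mind
#' detection at 1 ms resolution.
#'
#' @inheritParams backward_mixture
#' @param times evaluation times (default 1 ms grid over the trial).
#' @return Numeric vector of posterior means along \code{times}.
#' @export
posterior_mean <- function(trial, theta, choice, times = NULL, da = 0.1,
                           a_max = NULL) {
  if (is.null(times))
    times <- unique(c(seq(0, trial$duration, by = 0.001), trial$duration))
  comp <- post_mixture(trial, theta, choice, times, da, a_max)
  colSums(exp(comp$logw) * comp$m_p)
}
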