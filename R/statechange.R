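#' Detect model-predicted changes of mind
#'
#' Finds time points where a centered 100-sample running average of the
#' 1 ms posterior mean crosses the decision boundary B.  The crossing
#' time is the first sample past the boundary; the direction is "into
#' state 1" (go right) for upward crossings.  Crossings in the first and
#' last 200 ms of the trial are excluded, as are crossings failing either
#' change-strength criterion designed to remove immediately reversed
#' changes: (i) the running average must lie on the pre-change side of B
#' on average in the 100 ms before the crossing and on the post-change
#' side in the 100 ms after; (ii) the finite-difference slope of the
#' running average over +/-10 ms at the crossing must have the sign of
#' the new state.
#'
#' @param times 1 ms time grid of the posterior mean (s).
#' @param mean_trace posterior mean values on \code{times}.
#' @param B decision boundary.
#' @param trial the \code{dc_trial} (for its duration and id).
#' @param run_n running-average length in samples (default 100).
#' @param edge exclusion zone at each end of the trial (default 0.2 s).
#' @param strength_window pre/post strength window (default 0.1 s).
#' @param slope_halfwidth half-width for the slope criterion (default
#'   0.01 s).
#' @return data.frame with \code{trial_id}, \code{t_c},
#'   \code{direction} (1 = into go-right state, 2 = into go-left),
#'   \code{source = "model"}, \code{included}.  Zero rows when the trace
#'   is shorter than 400 ms or never crosses.
#' @export
detect_model_changes <- function(times, mean_trace, B, trial,
                                 run_n = 100, edge = 0.2,
                                 strength_window = 0.1,
                                 slope_halfwidth = 0.01) {
  empty <- data.frame(trial_id = integer(0), t_c = numeric(0),
                      direction = integer(0), source = character(0),
                      included = logical(0))
  if (length(times) < 2 || trial$duration < 2 * edge) return(empty)
  s <- running_mean(mean_trace, run_n)
  above <- s > B
  cross <- which(above[-1] != above[-length(above)]) + 1L
  if (!length(cross)) return(empty)
  dt <- times[2] - times[1]
  rows <- lapply(cross, function(i) {
    t_c <- times[i]
    dir <- if (above[i]) 1L else 2L
    new_sign <- if (dir == 1L) 1 else -1
    ok <- t_c >= edge && t_c <= trial$duration - edge
    if (ok) {
      pre <- s[times >= t_c - strength_window & times < t_c]
      post <- s[times > t_c & times <= t_c + strength_window]
      ok <- length(pre) > 0 && length(post) > 0 &&
        sign(mean(pre) - B) == -new_sign &&
        sign(mean(post) - B) == new_sign
    }
    if (ok) {
      k <- max(1L, round(slope_halfwidth / dt))
      i0 <- max(1L, i - k); i1 <- min(length(s), i + k)
      slope <- (s[i1] - s[i0]) / ((i1 - i0) * dt)
      ok <- sign(slope) == new_sign
    }
    data.frame(trial_id = as.integer(trial$trial_id), t_c = t_c,
               direction = dir, source = "model", included = ok)
  })
  do.call(rbind, rows)
}

#' Generative (veridical) state changes
#'
#' The true hidden-state change times of a trial, with the same edge
#' exclusion as the model-predicted changes for comparability.
#'
#' @param trial a \code{dc_trial}.
#' @param edge exclusion zone (default 0.2 s).
#' @return data.frame in the same format as
#'   \code{\link{detect_model_changes}} with \code{source =
#'   "generative"}.
#' @export
detect_generative_changes <- function(trial, edge = 0.2) {
  sc <- trial$state_changes
  if (!length(sc))
    return(data.frame(trial_id = integer(0), t_c = numeric(0),
                      direction = integer(0), source = character(0),
                      included = logical(0)))
  # state after the k-th change
  dir <- ifelse(seq_along(sc) %% 2 == 1, 3L - trial$initial_state,
                trial$initial_state)
  data.frame(trial_id = as.integer(trial$trial_id), t_c = sc,
             direction = as.integer(dir), source = "generative",
             included = sc >= edge & sc <= trial$duration - edge)
}

#' Detect changes of mind across a trial set
#'
#' Convenience wrapper: computes each trial's 1 ms analytic posterior
#' mean, applies \code{\link{detect_model_changes}}, and collects the
#' generative changes.
#'
#' @param trials a \code{dc_trials} list with choices.
#' @param theta a \code{\link{model_params}}.
#' @param ... passed to \code{\link{detect_model_changes}}.
#' @return data.frame of model and generative events.
#' @export
detect_changes <- function(trials, theta, ...) {
  rows <- lapply(trials, function(tr) {
    tt <- unique(c(seq(0, tr$duration, by = 0.001), tr$duration))
    pm <- posterior_mean(tr, theta, tr$choice, times = tt)
    rbind(detect_model_changes(tt, pm, theta$B, tr, ...),
          detect_generative_changes(tr))
  })
  do.call(rbind, rows)
}

# Residual rates: subtract the across-trial mean rate at each time bin
# (per unit, unmasked trials only).
residual_rates <- function(rates) {
  res <- rates$rate
  for (u in seq_along(rates$units)) {
    r <- rates$rate[, , u]
    r[!rates$mask] <- NA
    res[, , u] <- rates$rate[, , u] -
      matrix(colMeans(r, na.rm = TRUE), nrow(r), ncol(r), byrow = TRUE)
  }
  res
}

# Peri-event residual matrix for one unit: events x tau bins, with
# neighbor-event, trial-boundary and rate-mask masking applied (NA).
peri_event_matrix <- function(res_unit, mask, centers, trials,
                              trial_ids, events, tau, lag) {
  out <- matrix(NA_real_, nrow(events), length(tau))
  bin <- centers[2] - centers[1]
  for (e in seq_len(nrow(events))) {
    ti <- match(events$trial_id[e], trial_ids)
    if (is.na(ti)) next
    tr <- trials[[ti]]
    same <- events$t_c[events$trial_id == events$trial_id[e]]
    prev <- max(c(-Inf, same[same < events$t_c[e]]))
    nxt <- min(c(Inf, same[same > events$t_c[e]]))
    tt <- events$t_c[e] + lag + tau
    # sample time must fall between neighboring events (lag-shifted)
    ok <- events$t_c[e] + tau > prev & events$t_c[e] + tau < nxt
    bi <- round((tt - centers[1]) / bin) + 1L
    ok <- ok & bi >= 1 & bi <= length(centers)
    ok[ok] <- mask[ti, bi[ok]]
    out[e, ok] <- res_unit[ti, bi[ok]]
  }
  out
}

#' State-change triggered responses
#'
#' For each pre-movement side-selective unit, residual firing rates (rate
#' minus the across-trial mean at each time point) are realigned to the
#' included state-change events shifted by the neural response lag, with
#' data masked before the preceding and after the following state change,
#' and averaged separately for changes into the unit's preferred and
#' non-preferred state.  Discriminability per peri-event bin is measured
#' with d-prime and tested by permuting change-direction labels across
#' events.
#'
#' @param rates stimulus-aligned \code{dc_rates}.
#' @param trials the matching \code{dc_trials}.
#' @param events event table from \code{\link{detect_changes}} (one
#'   source).
#' @param classification output of \code{\link{classify_cells}}.
#' @param lag neural response lag in seconds (default 0.1).
#' @param window peri-event half-window (default 0.55 s).
#' @param min_events minimum included events per direction for a unit
#'   (default 5).
#' @param n_perm permutations for the d-prime test (default 250).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed for permutations.
#' @return Class \code{dc_str}: \code{tau} (peri-event bin centers),
#'   \code{units} (per-unit list: mean/SEM traces for preferred and
#'   non-preferred changes, \code{dprime}, \code{p}, \code{sig}, event
#'   counts), and \code{fraction_significant} across units per bin.
#' @export
compute_str <- function(rates, trials, events, classification,
                        lag = 0.1, window = 0.55, min_events = 5,
                        n_perm = 250, alpha = 0.05, seed = NULL) {
  stopifnot(rates$align == "stimulus")
  events <- events[events$included, , drop = FALSE]
  tau <- seq(-window + rates$bin / 2, window, by = rates$bin)
  res <- residual_rates(rates)
  sel <- classification[classification$selective, ]
  unit_out <- list()
  for (k in seq_len(nrow(sel))) {
    u <- sel$unit_id[k]
    ui <- match(u, rates$units)
    if (is.na(ui)) next
    peri <- peri_event_matrix(res[, , ui], rates$mask, rates$centers,
                              trials, rates$trial_ids, events, tau, lag)
    pref_state <- if (sel$preferred[k] == "right") 1L else 2L
    is_pref <- events$direction == pref_state
    if (sum(is_pref) < min_events || sum(!is_pref) < min_events) {
      warning("unit ", u, " skipped: too few events per direction")
      next
    }
    dp <- dprime_significance(peri, is_pref, n_perm = n_perm,
                              alpha = alpha,
                              seed = derive_seed(seed, paste0("u", u)))
    mstat <- function(m) {
      n <- colSums(!is.na(m))
      list(mean = colMeans(m, na.rm = TRUE),
           sem = apply(m, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n, 1)),
           n = n)
    }
    unit_out[[as.character(u)]] <- c(
      list(unit_id = u,
           pref = mstat(peri[is_pref, , drop = FALSE]),
           nonpref = mstat(peri[!is_pref, , drop = FALSE]),
           n_pref = sum(is_pref), n_nonpref = sum(!is_pref)),
      dp)
  }
  frac_sig <- if (length(unit_out)) {
    sig <- vapply(unit_out, function(x) as.numeric(x$sig),
                  numeric(length(tau)))
    rowMeans(sig, na.rm = TRUE)
  } else rep(NA_real_, length(tau))
  structure(list(tau = tau, units = unit_out,
                 fraction_significant = frac_sig),
            class = "dc_str")
}

#' d-prime discriminability with permutation significance
#'
#' Per column (peri-event time bin) of an events x bins matrix, the
#' standardized mean difference between the two event directions, with
#' event-count-weighted pooled SD (zero pooled SD gives d' = 0).
#' Significance is assessed by permuting direction labels across events
#' (two-tailed, min-tail doubling with the add-one rule).
#'
#' @param peri events x bins matrix (NA = masked).
#' @param is_pref logical event labels.
#' @param n_perm number of permutations (default 250).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @return List with \code{dprime}, \code{p}, \code{sig} per bin.
#' @export
dprime_significance <- function(peri, is_pref, n_perm = 250,
                                alpha = 0.05, seed = NULL) {
  if (sum(is_pref) < 2 || sum(!is_pref) < 2)
    stop("need >= 2 events per direction")
  dprime_col <- function(lab) {
    apply(peri, 2, function(x) {
      x1 <- x[lab & !is.na(x)]; x2 <- x[!lab & !is.na(x)]
      n1 <- length(x1); n2 <- length(x2)
      if (n1 < 2 || n2 < 2) return(NA_real_)
      sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
        (n1 + n2 - 2)
      if (sp2 <= 0) return(0)
      (mean(x1) - mean(x2)) / sqrt(sp2)
    })
  }
  obs <- dprime_col(is_pref)
  nb <- ncol(peri)
  p <- rep(NA_real_, nb)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm),
                   function(k) dprime_col(sample(is_pref)),
                   numeric(nb))
    if (nb == 1) perm <- matrix(perm, nrow = 1)
    for (b in seq_len(nb)) {
      if (is.na(obs[b])) next
      pd <- perm[b, !is.na(perm[b, ])]
      if (!length(pd)) next
      hi <- (1 + sum(pd >= obs[b])) / (length(pd) + 1)
      lo <- (1 + sum(pd <= obs[b])) / (length(pd) + 1)
      p[b] <- min(1, 2 * min(hi, lo))
    }
  })
  list(dprime = obs, p = p, sig = !is.na(p) & p < alpha)
}

#' State-change-aligned evidence tuning
#'
#' Rebuilds the joint distribution of rate, accumulator value, and time
#' with time measured relative to state-change events: for each included
#' event and peri-event bin, the posterior accumulator mass at that
#' absolute time and the unit's rate in the bin containing it (shifted by
#' the response lag) enter the joint.  Data in the 300 ms around the
#' event are excluded (the accumulator distribution is too narrow there
#' to estimate tuning), as are samples beyond the neighboring events.
#'
#' @param rate trials x bins rate (or z-scored rate) matrix for one unit.
#' @param mask the rate validity mask.
#' @param rates_centers stimulus-aligned bin centers of \code{rate}.
#' @param trials the \code{dc_trials}.
#' @param trial_ids trial ids indexing \code{rate} rows.
#' @param events included events (one source).
#' @param event_mass per-event posterior masses from
#'   \code{\link{state_change_mass}} (shared across units).
#' @param lag neural response lag applied to the rate samples (default
#'   0.1 s).
#' @param n_r_bins,r_range rate discretization (see
#'   \code{\link{build_joint}}).
#' @return A \code{dc_joint} over peri-event time bins (attribute
#'   \code{"tau"} holds the bin centers).
#' @export
state_change_joint <- function(rate, mask, rates_centers, trials,
                               trial_ids, events, event_mass,
                               lag = 0.1, n_r_bins = 100,
                               r_range = NULL) {
  tau <- attr(event_mass, "tau")
  nt <- length(tau)
  na <- nrow(event_mass[[1]]$mass)
  if (is.null(r_range)) r_range <- range(rate[mask], finite = TRUE)
  if (diff(r_range) <= 0) r_range <- r_range + c(-0.5, 0.5)
  r_edges <- seq(r_range[1], r_range[2], length.out = n_r_bins + 1)
  r_centers <- r_edges[-length(r_edges)] + diff(r_edges) / 2
  bin <- rates_centers[2] - rates_centers[1]
  mass <- array(0, dim = c(n_r_bins, na, nt))
  n_ev <- integer(nt)
  for (e in seq_len(nrow(events))) {
    ti <- match(events$trial_id[e], trial_ids)
    if (is.na(ti)) next
    em <- event_mass[[e]]
    tt <- events$t_c[e] + lag + tau
    bi <- round((tt - rates_centers[1]) / bin) + 1L
    for (b in which(em$valid)) {
      if (bi[b] < 1 || bi[b] > length(rates_centers)) next
      if (!mask[ti, bi[b]]) next
      rb <- min(max(findInterval(rate[ti, bi[b]], r_edges,
                                 rightmost.closed = TRUE), 1L),
                n_r_bins)
      mass[rb, , b] <- mass[rb, , b] + em$mass[, b]
      n_ev[b] <- n_ev[b] + 1L
    }
  }
  for (b in which(n_ev > 0)) mass[, , b] <- mass[, , b] / n_ev[b]
  structure(list(mass = mass, r_centers = r_centers, n_trials = n_ev,
                 tau = tau),
            class = "dc_joint")
}

#' Posterior accumulator mass around state-change events
#'
#' For each included event, evaluates the analytic posterior bin masses
#' at the peri-event bin centers (absolute times \code{t_c + tau}),
#' masking the 300 ms around the event, times outside the trial, and
#' times beyond the neighboring events.  Shared across units.
#'
#' @param trials a \code{dc_trials} with choices.
#' @param theta a \code{\link{model_params}}.
#' @param events included events (one source).
#' @param window peri-event half-window (default 0.55 s).
#' @param bin peri-event bin width (default 0.025 s).
#' @param exclude half-width of the exclusion zone around the event
#'   (default 0.3 s).
#' @param a_edges accumulator bin edges.
#' @return List per event: \code{mass} (a-bins x tau-bins, NA where
#'   masked) and \code{valid}; attribute \code{"tau"} holds bin centers.
#' @export
state_change_mass <- function(trials, theta, events, window = 0.55,
                              bin = 0.025, exclude = 0.3,
                              a_edges = tuning_a_bins()$edges) {
  tau <- seq(-window + bin / 2, window, by = bin)
  trial_ids <- vapply(trials, function(x) as.integer(x$trial_id), 1L)
  out <- lapply(seq_len(nrow(events)), function(e) {
    ti <- match(events$trial_id[e], trial_ids)
    tr <- trials[[ti]]
    same <- events$t_c[events$trial_id == events$trial_id[e]]
    prev <- max(c(-Inf, same[same < events$t_c[e]]))
    nxt <- min(c(Inf, same[same > events$t_c[e]]))
    tt <- events$t_c[e] + tau
    valid <- abs(tau) > exclude & tt >= 0 & tt <= tr$duration &
      tt > prev & tt < nxt
    mass <- matrix(NA_real_, length(a_edges) - 1, length(tau))
    if (any(valid))
      mass[, valid] <- posterior_bin_mass(tr, theta, tr$choice,
                                          a_edges, tt[valid])
    list(mass = mass, valid = valid)
  })
  attr(out, "tau") <- tau
  out
}
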