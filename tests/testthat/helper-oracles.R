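# Independent brute-force oracles used to freeze expected values.

# Fine-step Euler integration of the adaptation ODE with multiplicative
# jumps at clicks; independent of the closed-form recursion in the package.
ode_adapt_oracle <- function(times, phi, tau_phi, dt = 1e-6) {
  C <- 1
  t <- 0
  mags <- numeric(length(times))
  for (i in seq_along(times)) {
    nstep <- round((times[i] - t) / dt)
    for (k in seq_len(nstep)) C <- C + dt * (1 - C) / tau_phi
    mags[i] <- C
    C <- phi * C
    t <- times[i]
  }
  mags
}

# Exhaustive path enumeration for the telegraph-state filter on a coarse
# chain: per-bin right/left click counts, bin width dt, switch probability
# h*dt between bins.  Returns the log-odds of state 1 after each bin.
enum_ideal_oracle <- function(nr, nl, dt, hazard, kappa) {
  n <- length(nr)
  h <- hazard * dt
  out <- numeric(n)
  for (m in seq_len(n)) {
    states <- as.matrix(expand.grid(rep(list(c(1L, 2L)), m)))
    logp <- apply(states, 1, function(s) {
      lp <- log(0.5)
      for (b in seq_len(m)) {
        if (b > 1)
          lp <- lp + log(ifelse(s[b] == s[b - 1], 1 - h, h))
        # likelihood ratio form: state-1 bins contribute kappa*(nr-nl)
        if (s[b] == 1L) lp <- lp + kappa * (nr[b] - nl[b])
      }
      lp
    })
    p1 <- sum(exp(logp[states[, m] == 1L]))
    p2 <- sum(exp(logp[states[, m] == 2L]))
    out[m] <- log(p1) - log(p2)
  }
  out
}

# Naive double-loop construction of the joint (r, a, t) distribution,
# mirroring the verbal definition cell by cell.
naive_joint_oracle <- function(rate, mask, coarse_mass, n_r_bins,
                               r_range) {
  nt <- ncol(rate)
  na <- nrow(coarse_mass[[1]]$mass)
  r_edges <- seq(r_range[1], r_range[2], length.out = n_r_bins + 1)
  mass <- array(0, dim = c(n_r_bins, na, nt))
  n_trials <- integer(nt)
  for (i in seq_along(coarse_mass)) {
    for (b in seq_len(nt)) {
      if (!coarse_mass[[i]]$valid[b] || !mask[i, b]) next
      rb <- findInterval(rate[i, b], r_edges, rightmost.closed = TRUE)
      rb <- min(max(rb, 1L), n_r_bins)
      for (a in seq_len(na))
        mass[rb, a, b] <- mass[rb, a, b] + coarse_mass[[i]]$mass[a, b]
      n_trials[b] <- n_trials[b] + 1L
    }
  }
  for (b in which(n_trials > 0)) mass[, , b] <- mass[, , b] / n_trials[b]
  list(mass = mass, n_trials = n_trials)
}

# AUC by explicit pair counting over all right-left trial pairs (ties 1/2).
auc_pair_oracle <- function(x, is_right) {
  xr <- x[is_right]
  xl <- x[!is_right]
  tot <- 0
  for (a in xr) for (b in xl)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xr) * length(xl))
}

# Build a trial by hand (clicks and state path fixed, no randomness).
make_trial <- function(duration, left = numeric(0), right = numeric(0),
                       changes = numeric(0), initial_state = 1L,
                       id = 1L, movement = NULL) {
  structure(list(
    trial_id = id, duration = duration, left_clicks = left,
    right_clicks = right, state_changes = changes,
    initial_state = initial_state,
    final_state = if (length(changes) %% 2 == 0) initial_state else
      3L - initial_state,
    movement = if (is.null(movement)) duration + 0.3 else movement,
    choice = NA_integer_, hit = NA), class = "dc_trial")
}
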