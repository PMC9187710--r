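test_that("a constructed ramp is detected once, at the crossing", {
  tr <- make_trial(1.2, id = 5L)
  tt <- seq(0, 1.2, by = 0.001)
  trace <- -0.5 + (tt > 0.45) * (tt - 0.45) * 2  # crosses 0 at 0.7 s
  ev <- detect_model_changes(tt, trace, B = 0, tr)
  inc <- ev[ev$included, ]
  expect_identical(nrow(inc), 1L)
  expect_lt(abs(inc$t_c - 0.7), 0.002)
  expect_identical(inc$direction, 1L)
  expect_identical(inc$trial_id, 5L)
  # downward version mirrors the direction
  ev2 <- detect_model_changes(tt, -trace, B = 0, tr)
  expect_identical(ev2$direction[ev2$included], 2L)
})

test_that("monotone traces and short traces yield no events", {
  tr <- make_trial(1)
  tt <- seq(0, 1, by = 0.001)
  expect_identical(nrow(detect_model_changes(tt, tt - 2, 0, tr)), 0L)
  # shorter than 400 ms: empty, no error
  tr_s <- make_trial(0.3)
  tt_s <- seq(0, 0.3, by = 0.001)
  ev <- detect_model_changes(tt_s, sin(20 * tt_s), 0, tr_s)
  expect_identical(sum(ev$included), 0L)
})

test_that("edge crossings and immediate reversals are excluded", {
  tr <- make_trial(1)
  tt <- seq(0, 1, by = 0.001)
  # crossing at 150 ms: excluded by the 200 ms edge rule
  trace <- -0.5 + (tt > 0.1) * (tt - 0.1) * 10
  ev <- detect_model_changes(tt, trace, B = 0, tr)
  early <- ev[ev$t_c < 0.2, ]
  expect_true(all(!early$included))
  # a brief blip that immediately reverses fails the strength criteria
  blip <- -0.5 + 0.6 * exp(-((tt - 0.5) / 0.01)^2)
  ev2 <- detect_model_changes(tt, blip, B = 0, tr)
  expect_identical(sum(ev2$included), 0L)
})

test_that("detection is invariant to a common offset of trace and B", {
  th <- study_theta()
  tr <- simulate_choices(generate_trials(1, seed = 101), th,
                         seed = 102)[[1]]
  tt <- seq(0, tr$duration, by = 0.001)
  pm <- posterior_mean(tr, th, tr$choice, times = tt)
  e0 <- detect_model_changes(tt, pm, 0, tr)
  e5 <- detect_model_changes(tt, pm + 5, 5, tr)
  expect_equal(e0$t_c, e5$t_c)
  expect_identical(e0$included, e5$included)
})

test_that("generative events: zero hazard, counts, and edge window", {
  tr0 <- generate_trials(5, task_params(hazard_rate = 0), seed = 103)
  for (tr in tr0)
    expect_identical(nrow(detect_generative_changes(tr)), 0L)
  trs <- generate_trials(50, seed = 104)
  for (tr in trs) {
    ev <- detect_generative_changes(tr)
    expect_identical(nrow(ev), length(tr$state_changes))
    inwin <- tr$state_changes >= 0.2 &
      tr$state_changes <= tr$duration - 0.2
    expect_identical(ev$included, inwin)
    # direction alternates away from the initial state
    if (nrow(ev) > 0)
      expect_identical(ev$direction[1], 3L - tr$initial_state)
  }
})

test_that("model changes lag generative changes on agent data", {
  ds <- big_dataset()
  ev <- big_events()
  mod <- ev[ev$source == "model" & ev$included, ]
  gen <- ev[ev$source == "generative" & ev$included, ]
  # pair each generative change with the nearest later model change in
  # the same trial and direction
  lags <- numeric(0)
  for (i in seq_len(nrow(gen))) {
    cand <- mod$t_c[mod$trial_id == gen$trial_id[i] &
                      mod$direction == gen$direction[i]]
    cand <- cand[cand > gen$t_c[i] - 0.05]
    if (length(cand)) lags <- c(lags, min(cand) - gen$t_c[i])
  }
  expect_gt(length(lags), 50)
  expect_gt(mean(lags), 0)
})

test_that("d-prime: closed-form separation and zero-variance convention", {
  set.seed(105)
  n <- 400
  peri <- cbind(c(rnorm(n, 1), rnorm(n, -1)),
                rep(0, 2 * n))
  is_pref <- rep(c(TRUE, FALSE), each = n)
  dp <- dprime_significance(peri, is_pref, n_perm = 100, seed = 106)
  expect_lt(abs(dp$dprime[1] - 2), 0.15)
  expect_true(dp$sig[1])
  expect_equal(dp$dprime[2], 0)   # zero pooled SD convention
  expect_error(dprime_significance(peri[1:3, ], c(TRUE, TRUE, FALSE)))
})

test_that("d-prime permutation test is calibrated under the null", {
  set.seed(107)
  n_units <- 200
  is_pref <- rep(c(TRUE, FALSE), 15)
  ps <- vapply(seq_len(n_units), function(u) {
    peri <- matrix(rnorm(30), ncol = 1)
    dprime_significance(peri, is_pref, n_perm = 99, seed = u)$p[1]
  }, 1)
  fpr <- mean(ps < 0.05)
  expect_lt(abs(fpr - 0.05), 3 * sqrt(0.05 * 0.95 / n_units) + 0.015)
})

test_that("STR: identical rates give identical traces; masking respected", {
  # two events in one trial, one unit with direction-independent rates
  trs <- structure(list(make_trial(1.6, changes = c(0.5, 1.0))),
                   class = "dc_trials")
  trs[[1]]$choice <- 1L; trs[[1]]$hit <- TRUE
  events <- data.frame(trial_id = 1L, t_c = c(0.5, 1.0),
                       direction = c(2L, 1L), source = "generative",
                       included = TRUE)
  centers <- seq(-0.9875, 2, by = 0.025)
  nbin <- length(centers)
  res <- matrix(rep(sin(centers), 1), 1, nbin)
  mask <- matrix(TRUE, 1, nbin)
  tau <- seq(-0.55 + 0.0125, 0.55, by = 0.025)
  peri <- dynclicks:::peri_event_matrix(res, mask, centers, trs, 1L,
                                        events, tau, lag = 0)
  # event 1: samples at t > 1.0 (the following change) are masked
  expect_true(all(is.na(peri[1, 0.5 + tau > 1.0])))
  expect_false(anyNA(peri[1, 0.5 + tau > -0.4 & 0.5 + tau < 1.0]))
  # event 2: samples before the preceding change at 0.5 are masked
  expect_true(all(is.na(peri[2, 1.0 + tau < 0.5])))
  # sampled values equal the residual trace at the aligned bins
  k <- which.min(abs(tau - 0.2))
  bin_idx <- round((1.0 + tau[k] - centers[1]) / 0.025) + 1
  expect_equal(peri[2, k], res[1, bin_idx])
})

test_that("change-of-mind responses cross at the model change", {
  ds <- big_dataset()
  rates <- big_rates()
  cls <- big_classification()
  ev <- big_events()
  str_m <- compute_str(rates, ds$trials,
                       ev[ev$source == "model", ], cls, seed = 108)
  expect_gt(length(str_m$units), 10)
  u1 <- str_m$units[[1]]
  # preferred-state trace rises from below to above the non-preferred
  early <- str_m$tau < -0.3
  late <- str_m$tau > 0.3
  expect_lt(mean(u1$pref$mean[early] - u1$nonpref$mean[early]), 0)
  expect_gt(mean(u1$pref$mean[late] - u1$nonpref$mean[late]), 0)
  # significance drops near the change: the population trace dips
  frac <- str_m$fraction_significant
  mid <- which(abs(str_m$tau) < 0.15)
  expect_lt(min(frac[mid]), min(frac[early]) - 0.05)
})

test_that("state-change-aligned tuning recovers a separable code", {
  ds <- big_dataset()
  rates <- big_rates()
  cls <- big_classification()
  ev <- big_events()
  evm <- ev[ev$source == "model" & ev$included, ]
  scm <- fixture("big_scm", function()
    state_change_mass(ds$trials, study_theta(), evm))
  sel <- cls[cls$selective & cls$preferred == "right", ]
  u <- sel$unit_id[1]
  ui <- match(u, rates$units)
  jt <- state_change_joint(rates$rate[, , ui], rates$mask,
                           rates$centers, ds$trials, rates$trial_ids,
                           evm, scm)
  # the 300 ms exclusion zone holds no mass
  tau <- jt$tau
  excl <- abs(tau) <= 0.3
  expect_true(all(jt$mass[, , excl] == 0))
  expect_true(all(jt$n_trials[excl] == 0))
  tm <- tuning_map(jt, min_trials = 20)
  r1 <- rank1(tm, preferred = "right")
  expect_gt(r1$ve, 0.5)
  f_true <- neuron_tuning(ds$specs[[u]], tuning_a_bins()$centers)
  fc <- r1$f; ft <- f_true[r1$cols]
  cosine <- sum(fc * ft) / sqrt(sum(fc^2) * sum(ft^2))
  expect_gt(cosine, 0.9)
})
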