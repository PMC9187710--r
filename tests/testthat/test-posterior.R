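test_that("backward mixture is a point-mass comb at trial end", {
  th <- study_theta()
  tr <- generate_trials(1, seed = 31)[[1]]
  bw <- backward_mixture(tr, th, choice = 1,
                         times = c(0.3, tr$duration))
  # final column: each component sits exactly at its grid value with
  # zero variance, and all grid values are on the choice side of B
  expect_equal(bw$means[, 2], bw$x, tolerance = 1e-9)
  expect_equal(bw$var[2], 0, tolerance = 1e-12)
  expect_true(all(bw$x > th$B))
  bw_l <- backward_mixture(tr, th, choice = -1,
                           times = c(0.3, tr$duration))
  expect_true(all(bw_l$x < th$B))
})

test_that("frozen dynamics keep backward components as narrow deltas", {
  tr <- make_trial(1)
  th <- model_params(sigma_i2 = 0.5, sigma_a2 = 0, sigma_s2 = 0, lam = 0,
                    phi = 1, lapse = 0)
  bw <- backward_mixture(tr, th, choice = 1, times = c(0, 0.5, 1))
  expect_true(all(bw$var < 1e-12))
  expect_equal(bw$means[, 1], bw$x, tolerance = 1e-9)
})

test_that("backward density is proportional to the final-side tail probability", {
  # b(a, t) should match P(final side | a(t) = a) up to one constant per
  # time slice; the tail probability has a closed form
  th <- study_theta()
  tr <- generate_trials(1, seed = 32)[[1]]
  t0 <- 0.4
  ac <- adapt_clicks(tr, th$phi, th$tau_phi)
  lam <- th$lam
  later <- ac$times > t0
  drift <- sum(ac$sides[later] * exp(lam * (tr$duration - ac$times[later])) *
                 ac$magnitudes[later])
  vnoise <- th$sigma_a2 * (tr$duration - t0) *
    dynclicks:::exprel(2 * lam * (tr$duration - t0)) +
    th$sigma_s2 * sum(exp(2 * lam * (tr$duration - ac$times[later])) *
                        ac$magnitudes[later])
  agrid <- seq(-6, 6, by = 0.05)
  tail_p <- stats::pnorm((agrid * exp(lam * (tr$duration - t0)) + drift -
                            th$B) / sqrt(vnoise))
  bw <- backward_mixture(tr, th, choice = 1, da = 0.05, times = t0)
  dens <- colSums(vapply(seq_along(agrid), function(i)
    stats::dnorm(agrid[i], bw$means[, 1], sqrt(bw$var[1])),
    numeric(length(bw$x))))
  p1 <- tail_p / sum(tail_p)
  p2 <- dens / sum(dens)
  kl <- sum(ifelse(p1 > 0, p1 * log(p1 / pmax(p2, 1e-300)), 0))
  expect_lt(kl, 1e-3)
})

test_that("posterior slices are normalized and respect the choice constraint", {
  th <- study_theta()
  tr <- generate_trials(1, seed = 33)[[1]]
  pg <- posterior_grid(tr, th, choice = 1, dt_eval = 0.02)
  expect_equal(colSums(pg$mass), rep(1, length(pg$times)),
               tolerance = 1e-9)
  # at t_N all mass lies on the choice side of B
  final <- pg$mass[, ncol(pg$mass)]
  expect_lt(sum(final[pg$a < th$B]), 1e-12)
  # mean trace from the grid agrees with the analytic mixture mean
  m_grid <- posterior_mean_trace(pg)
  m_ana <- posterior_mean(tr, th, 1, times = pg$times)
  expect_lt(max(abs(m_grid - m_ana)), 0.05)
})

test_that("symmetric stimulus with rightward choice biases the posterior up", {
  tr <- make_trial(1, right = c(0.2, 0.5), left = c(0.2, 0.5))
  th <- model_params(B = 0)
  pg <- posterior_grid(tr, th, choice = 1, dt_eval = 0.05)
  m <- posterior_mean_trace(pg)
  expect_gt(m[length(m)], 0)
})

test_that("posterior matches rejection-sampled paths (KL oracle)", {
  th <- study_theta()
  tr <- generate_trials(1, seed = 34)[[1]]
  tt <- seq(0.1, tr$duration - 0.02, length.out = 5)
  set.seed(35)
  en <- simulate_ensemble(tr, th, 40000, times = tt)
  edges <- c(-Inf, seq(-7, 7, by = 1), Inf)
  for (ch in c(1, -1)) {
    keep <- (en$a_N > th$B) == (ch == 1)
    if (sum(keep) < 3000) next
    pm <- posterior_bin_mass(tr, th, ch, edges, tt)
    for (k in seq_along(tt)) {
      emp <- tabulate(findInterval(en$at[keep, k], edges),
                      length(edges) - 1)
      emp <- emp / sum(emp)
      q <- pmax(pm[, k], 1e-12)
      kl <- sum(ifelse(emp > 0, emp * log(emp / q), 0))
      expect_lt(kl, 0.01)
    }
    m_emp <- colMeans(en$at[keep, , drop = FALSE])
    se <- apply(en$at[keep, , drop = FALSE], 2, stats::sd) /
      sqrt(sum(keep))
    m_mod <- posterior_mean(tr, th, ch, times = tt)
    expect_lt(max(abs(m_emp - m_mod) / se), 4)
  }
})

test_that("posterior is stable under component-grid refinement", {
  th <- study_theta()
  tr <- generate_trials(1, seed = 36)[[1]]
  tt <- seq(0.05, tr$duration, length.out = 8)
  edges <- c(-Inf, seq(-8, 8, by = 0.5), Inf)
  m1 <- posterior_bin_mass(tr, th, 1, edges, tt, da = 0.1)
  m2 <- posterior_bin_mass(tr, th, 1, edges, tt, da = 0.05)
  tv <- max(colSums(abs(m1 - m2)) / 2)
  expect_lt(tv, 1e-3)
})

test_that("choice-weighted posteriors recompose the forward distribution", {
  th <- study_theta()
  tr <- generate_trials(1, seed = 37)[[1]]
  tt <- seq(0.1, tr$duration - 0.01, length.out = 6)
  edges <- c(-Inf, seq(-8, 8, by = 0.5), Inf)
  fm <- forward_moments(tr, th, times = c(tt, tr$duration))
  p_right <- dynclicks:::tail_above(
    fm$mu[length(tt) + 1], fm$var[length(tt) + 1], th$B)
  post_r <- posterior_bin_mass(tr, th, 1, edges, tt, da = 0.05)
  post_l <- posterior_bin_mass(tr, th, -1, edges, tt, da = 0.05)
  mix <- post_r * p_right + post_l * (1 - p_right)
  fwd <- vapply(seq_along(tt), function(k)
    diff(stats::pnorm(edges, fm$mu[k], sqrt(fm$var[k]))),
    numeric(length(edges) - 1))
  expect_lt(max(colSums(abs(mix - fwd)) / 2), 2e-3)
})

test_that("posterior mean trace degenerate cases", {
  # all mass in one bin: the mean is that bin's center
  pg <- structure(list(a = c(-1, 0, 1), times = c(0, 1),
                       mass = cbind(c(0, 0, 1), c(0, 1, 0))),
                  class = "dc_posterior")
  expect_equal(posterior_mean_trace(pg), c(1, 0))
  # symmetric mass: zero mean
  pg$mass <- cbind(c(0.5, 0, 0.5), c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(posterior_mean_trace(pg), c(0, 0))
})

test_that("invalid posterior parameters error", {
  th <- study_theta()
  tr <- generate_trials(1, seed = 38)[[1]]
  expect_error(posterior_bin_mass(tr, th, 1, c(-Inf, 0, Inf), 0.1,
                                  da = -0.1))
  expect_error(posterior_bin_mass(tr, th, 0, c(-Inf, 0, Inf), 0.1))
})
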