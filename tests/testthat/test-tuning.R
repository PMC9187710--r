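test_that("joint construction matches the naive double-loop oracle", {
  th <- study_theta()
  trs <- simulate_choices(generate_trials(5, seed = 91), th, seed = 92)
  t_edges <- seq(0, 0.5, by = 0.1)
  pcm <- posterior_coarse_mass(trs, th, t_edges)
  set.seed(93)
  rate <- matrix(runif(5 * 5, 5, 30), 5, 5)
  mask <- matrix(TRUE, 5, 5)
  mask[2, 4] <- FALSE
  jt <- build_joint(rate, mask, pcm, n_r_bins = 20)
  oracle <- naive_joint_oracle(rate, mask, pcm, 20,
                               range(rate[mask]))
  expect_equal(jt$mass, oracle$mass, tolerance = 1e-12)
  expect_equal(jt$n_trials, oracle$n_trials)
  # every populated time slab carries unit mass
  for (b in which(jt$n_trials > 0))
    expect_equal(sum(jt$mass[, , b]), 1, tolerance = 1e-9)
  expect_error(build_joint(rate[1:3, ], mask[1:3, ], pcm))
})

test_that("analytic coarse masses agree with fine-grid downsampling", {
  th <- study_theta()
  tr <- simulate_choices(generate_trials(1, seed = 94), th,
                         seed = 95)[[1]]
  t_edges <- seq(0, 0.5, by = 0.125)
  a_edges <- tuning_a_bins()$edges
  pg <- posterior_grid(tr, th, tr$choice, da_eval = 0.02,
                       dt_eval = 0.005)
  ds <- downsample_posterior(pg, t_edges, a_edges)
  # analytic coarse masses on exactly the fine grid's slice times
  ana <- vapply(seq_len(length(t_edges) - 1), function(b) {
    sl <- which(pg$times > t_edges[b] & pg$times <= t_edges[b + 1])
    rowMeans(posterior_bin_mass(tr, th, tr$choice, a_edges,
                                pg$times[sl]))
  }, numeric(length(a_edges) - 1))
  expect_lt(max(abs(ds - ana), na.rm = TRUE), 0.01)
})

test_that("tuning map: flat tuning, residual identity, and masking", {
  th <- study_theta()
  trs <- simulate_choices(generate_trials(60, seed = 96), th, seed = 97)
  t_edges <- seq(0, 0.5, by = 0.1)
  pcm <- posterior_coarse_mass(trs, th, t_edges)
  # rate independent of a: residual map vanishes where estimated
  set.seed(98)
  rate <- matrix(rep(runif(60, 10, 20), 5), 60, 5)  # varies by trial only
  mask <- matrix(TRUE, 60, 5)
  jt <- build_joint(rate, mask, pcm, n_r_bins = 30)
  tm <- tuning_map(jt, min_trials = 5)
  # per-slice weighted residual is identically zero (algebraic identity)
  for (b in seq_len(nrow(tm$dEr))) {
    ok <- tm$mask[b, ]
    if (!any(ok)) next
    expect_lt(abs(sum(tm$pa[b, ok] * tm$dEr[b, ok]) /
                    sum(tm$pa[b, ok])), 1e-9)
  }
  # rate uncorrelated with a: residuals small relative to rate scale
  expect_lt(max(abs(tm$dEr), na.rm = TRUE), 2)
  # sparse cells are masked, not estimated
  expect_true(any(!tm$mask) || all(tm$pa > 1e-4))
})

test_that("rank-1 machinery is exact on separable maps", {
  t_grid <- seq(0.0125, 0.8, by = 0.025)
  a_grid <- tuning_a_bins()$centers
  g <- pmin(1, t_grid / 0.5) * 12
  h <- stats::plogis(1.1 * a_grid) - 0.5
  M <- outer(g, h)
  r1 <- rank1(M, preferred = "right")
  expect_equal(r1$ve, 1, tolerance = 1e-10)
  expect_lt(max(abs(r1$recon - M)), 1e-10)
  # the tuning curve has unit range by construction
  expect_equal(diff(range(r1$f)), 1, tolerance = 1e-12)
  # m * f reproduces the map through the outer product identity
  expect_equal(outer(r1$m, r1$f), r1$recon)
})

test_that("variance explained follows the two-singular-value construction", {
  t_grid <- seq(0, 1, length.out = 20)
  a_grid <- seq(-4, 4, length.out = 10)
  u1 <- sin(pi * t_grid) + 2
  v1 <- tanh(a_grid)
  u1 <- u1 / sqrt(sum(u1^2)); v1 <- v1 / sqrt(sum(v1^2))
  # orthogonal second pair via Gram-Schmidt
  u2 <- cos(2 * pi * t_grid)
  u2 <- u2 - sum(u2 * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
  v2 <- a_grid^2
  v2 <- v2 - sum(v2 * v1) * v1; v2 <- v2 / sqrt(sum(v2^2))
  for (eps in c(0.1, 0.5)) {
    M <- outer(u1, v1) + eps * outer(u2, v2)
    r1 <- rank1(M, preferred = "right")
    expect_equal(r1$ve, 1 / (1 + eps), tolerance = 1e-10)
  }
})

test_that("variance explained is invariant to inversion and scaling", {
  set.seed(99)
  M <- outer(runif(15, 1, 3), tanh(seq(-3, 3, length.out = 8))) +
    matrix(rnorm(120, sd = 0.1), 15, 8)
  ve0 <- rank1(M, "right")$ve
  expect_equal(rank1(M[, 8:1], "left")$ve, ve0, tolerance = 1e-12)
  expect_equal(rank1(5 * M, "right")$ve, ve0, tolerance = 1e-12)
  # orientation: right-preferring tuning increases, left decreases
  expect_gt(stats::cor(rank1(M, "right")$f, seq_len(8)), 0)
  expect_lt(stats::cor(rank1(M[, 8:1], "left")$f, seq_len(8)), 0)
})

test_that("population averaging: identity and mirror pairs", {
  t_grid <- seq(0, 1, length.out = 12)
  a_grid <- seq(-4, 4, length.out = 10)
  M <- outer(pmin(1, t_grid / 0.5) + 0.2, tanh(a_grid))
  mk <- function(m) structure(list(dEr = m), class = "dc_map")
  # identical right-preferring cells: the average is the map itself
  pop <- population_map(list(mk(M), mk(M)), c("right", "right"))
  expect_equal(pop$map, M, tolerance = 1e-12)
  # a left-preferring mirror cell must reinforce, not cancel
  M_l <- M[, 10:1]
  pop2 <- population_map(list(mk(M), mk(M_l)), c("right", "left"))
  expect_equal(pop2$map, M, tolerance = 1e-12)
  expect_error(population_map(list(), character(0)))
})

test_that("synthetic tuned units are recovered from their own spikes", {
  ds <- small_dataset()
  rates <- small_rates()
  cls <- small_classification()
  pcm <- fixture("small_pcm", function()
    posterior_coarse_mass(ds$trials, ds$theta, tuning_t_edges()))
  tcol <- which(rates$centers > 0 & rates$centers < 2)
  abins <- tuning_a_bins()
  u <- 1  # strongly tuned right-preferring unit
  ui <- match(u, rates$units)
  jt <- build_joint(rates$rate[, tcol, ui], rates$mask[, tcol], pcm)
  tm <- tuning_map(jt)
  r1 <- rank1(tm, preferred = "right")
  # recovered tuning correlates with the generator's sigmoid
  f_true <- neuron_tuning(ds$specs[[u]], abins$centers)
  expect_gt(stats::cor(r1$f, f_true[r1$cols]), 0.9)
  # map correlates with the generator's separable surface
  t_centers <- tuning_t_edges()[-1] - 0.0125
  truth <- outer(neuron_gain(ds$specs[[u]], t_centers - 0.1), f_true)
  ok <- tm$mask & is.finite(truth)
  expect_gt(stats::cor(tm$dEr[ok], truth[ok]), 0.8)
})
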