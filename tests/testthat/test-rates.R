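test_that("rate construction: empty train, unit mass, and causality", {
  trs <- structure(list(make_trial(1)), class = "dc_trials")
  # no spikes: all-zero rates
  empty <- data.frame(unit_id = integer(0), trial_id = integer(0),
                      spike_time = numeric(0))
  r0 <- compute_rates(empty, trs, units = 1L)
  expect_true(all(r0$rate == 0))
  # one spike: the smoothed bump integrates to one spike
  one <- data.frame(unit_id = 1L, trial_id = 1L, spike_time = 0.5)
  r1 <- compute_rates(one, trs, units = 1L)
  expect_equal(sum(r1$rate[1, , 1]) * r1$bin, 1, tolerance = 1e-9)
  # causality: no contribution to bins ending before the spike
  before <- r1$centers + r1$bin / 2 <= 0.5 + 1e-9
  expect_true(all(r1$rate[1, before, 1] == 0))
  expect_gt(r1$rate[1, which(!before)[1], 1], 0)
  expect_error(compute_rates(one, trs, bin = 0))
})

test_that("constant-rate Poisson spiking is recovered", {
  set.seed(81)
  trs <- structure(lapply(1:300, function(i) make_trial(1.5, id = i)),
                   class = "dc_trials")
  spk <- do.call(rbind, lapply(1:300, function(i) {
    n <- rpois(1, 10 * 2.5)
    data.frame(unit_id = 1L, trial_id = i,
               spike_time = sort(runif(n, -1, 1.5)))
  }))
  r <- compute_rates(spk, trs, units = 1L)
  mid <- r$centers > 0.3 & r$centers < 1.2
  m <- mean(r$rate[, mid, 1])
  expect_lt(abs(m - 10), 3 * sqrt(10 / (300 * sum(mid) * 0.025)))
})

test_that("classification finds tuned units and their preferred side", {
  ds <- small_dataset()
  cls <- small_classification()
  truth <- ds$units$preferred
  expect_true(all(cls$active))
  expect_true(all(cls$selective[truth != "none"]))
  expect_equal(cls$preferred[truth != "none"], truth[truth != "none"])
})

test_that("a silent unit is inactive", {
  trs <- structure(list(make_trial(1)), class = "dc_trials")
  trs[[1]]$choice <- 1L
  spk <- data.frame(unit_id = 1L, trial_id = 1L, spike_time = 0.2)
  cls <- classify_cells(spk, trs)
  expect_false(cls$active)
  expect_false(cls$selective)
})

test_that("selectivity t-test is calibrated near its nominal level", {
  # untuned Poisson units with choice-independent rates
  set.seed(82)
  n_units <- 300
  n_tr <- 60
  choice <- rep(c(1L, -1L), n_tr / 2)
  hits <- 0
  for (u in seq_len(n_units)) {
    counts <- rpois(n_tr, 20)
    p <- stats::t.test(counts[choice == 1L],
                       counts[choice == -1L])$p.value
    hits <- hits + (p < 0.05)
  }
  fpr <- hits / n_units
  expect_lt(abs(fpr - 0.05), 3 * sqrt(0.05 * 0.95 / n_units) + 0.01)
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  x <- c(3.1, 2.0, 2.0, 5.5, 1.2, 2.0)
  lab <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(dynclicks:::auc_mw(x, lab), auc_pair_oracle(x, lab))
  # identical distributions: 0.5 by tie convention
  expect_equal(dynclicks:::auc_mw(rep(2, 6), lab), 0.5)
  # perfect separation: 1
  expect_equal(dynclicks:::auc_mw(c(5, 6, 7, 1, 2, 3),
                                  c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                    FALSE)), 1)
})

test_that("AUC timecourse: antisymmetry and significance behavior", {
  set.seed(83)
  n <- 60
  choice <- rep(c(1L, -1L), n / 2)
  rate <- cbind(rnorm(n), rnorm(n, mean = ifelse(choice == 1L, 3, 0)))
  a1 <- auc_timecourse(rate, choice, n_perm = 200, run_len = 2,
                       seed = 84)
  a2 <- auc_timecourse(rate, -choice, n_perm = 200, run_len = 2,
                       seed = 84)
  expect_equal(a1$auc, 1 - a2$auc, tolerance = 1e-12)
  # separated bin significant, null bin not
  expect_true(a1$sig[2])
  expect_gt(a1$auc[2], 0.9)
  expect_false(a1$sig[1])
  expect_identical(a1$latency, NA_integer_)
  expect_error(auc_timecourse(rate, rep(1L, n)))
})

test_that("permutation p-values are near-uniform under the null", {
  set.seed(85)
  n_units <- 200
  choice <- rep(c(1L, -1L), 20)
  ps <- vapply(seq_len(n_units), function(u) {
    rate <- matrix(rnorm(40), ncol = 1)
    auc_timecourse(rate, choice, n_perm = 99, seed = u)$p[1]
  }, 1)
  fpr <- mean(ps < 0.05)
  expect_lt(abs(fpr - 0.05), 3 * sqrt(0.05 * 0.95 / n_units) + 0.015)
})

test_that("population PSTH: single condition equals the trial mean, flip swaps", {
  ds <- small_dataset()
  rates <- small_rates()
  cls <- small_classification()
  psth <- population_psth(rates, ds$trials, cls)
  expect_true(all(c("condition", "time", "mean", "sem") %in%
                    names(psth)))
  # one selective cell, one condition: equals that cell's trial mean
  one <- cls[cls$selective, ][1, ]
  ui <- match(one$unit_id, rates$units)
  pref_choice <- if (one$preferred == "right") 1L else -1L
  choice <- vapply(ds$trials, function(x) x$choice, 1L)
  fsd <- vapply(ds$trials, dynclicks:::final_state_duration, 1)
  sel_tr <- which(choice == pref_choice & fsd > 1 & fsd <= 1.5)
  cls1 <- cls[cls$unit_id == one$unit_id, ]
  p1 <- population_psth(rates, ds$trials, cls1)
  cond <- grep("fsd=\\(1,1.5\\]\\|pref", unique(p1$condition),
               value = TRUE)
  got <- p1$mean[p1$condition == cond]
  r <- rates$rate[sel_tr, , ui, drop = FALSE]
  dim(r) <- dim(r)[1:2]
  r[!rates$mask[sel_tr, ]] <- NA
  want <- colMeans(r, na.rm = TRUE)
  n_ok <- colSums(!is.na(r)) > 0
  expect_equal(got[n_ok], want[n_ok], tolerance = 1e-9)
  # flipping all preferred sides swaps pref and nonpref traces
  cls_f <- cls
  cls_f$preferred <- ifelse(cls_f$preferred == "right", "left",
                            ifelse(cls_f$preferred == "left", "right",
                                   "none"))
  p_f <- population_psth(rates, ds$trials, cls_f)
  for (cc in unique(psth$condition)) {
    swapped <- if (grepl("nonpref", cc))
      sub("nonpref", "pref", cc) else sub("pref", "nonpref", cc)
    expect_equal(psth$mean[psth$condition == cc],
                 p_f$mean[p_f$condition == swapped], tolerance = 1e-9)
  }
})

test_that("choice divergence latency grows with final-state duration", {
  ds <- big_dataset()
  rates <- big_rates()
  cls <- big_classification()
  psth <- population_psth(rates, ds$trials, cls,
                          fsd_breaks = c(0, 0.5, 2))
  # divergence (pref - nonpref) at a fixed early time is larger for
  # short final states (changes happened earlier)
  t_idx <- which.min(abs(rates$centers - 0.45))
  gap <- function(fsd_lab) {
    p <- psth$mean[psth$condition == paste0("fsd=", fsd_lab, "|pref")]
    np <- psth$mean[psth$condition ==
                      paste0("fsd=", fsd_lab, "|nonpref")]
    (p - np)[t_idx]
  }
  expect_gt(gap("(0.5,2]"), gap("[0,0.5]"))
})
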