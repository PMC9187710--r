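#' Binned, causally smoothed firing rates
#'
#' Spikes are binned into 25 ms bins (half-open intervals, labeled by bin
#' center) and smoothed with a causal one-sided Gaussian filter (SD 100
#' ms, truncated at 4 SD, renormalized to unit mass), so a spike
#' contributes nothing to bins that end before it.  Stimulus-aligned rates
#' are masked after the movement; movement-aligned rates are masked before
#' stimulus onset.
#'
#' @param spikes long data.frame with \code{unit_id}, \code{trial_id},
#'   \code{spike_time} (seconds, stimulus-aligned).
#' @param trials the \code{dc_trials} list the spikes refer to.
#' @param align \code{"stimulus"} (t = 0 at stimulus onset) or
#'   \code{"movement"} (t = 0 at movement).
#' @param window rate window in aligned time (defaults: [-1, max
#'   movement] for stimulus alignment, [-(max movement), 0.2] for
#'   movement alignment).
#' @param bin bin width in seconds (default 0.025).
#' @param smooth_sd causal Gaussian SD in seconds (default 0.1).
#' @param units unit ids to include (default: all in \code{spikes}).
#' @return Class \code{dc_rates}: list with \code{align}, bin
#'   \code{centers}, \code{units}, \code{rate} (array trials x bins x
#'   units, spikes/s), \code{mask} (trials x bins, TRUE = valid), and
#'   \code{trial_ids}.
#' @export
compute_rates <- function(spikes, trials, align = c("stimulus",
                                                    "movement"),
                          window = NULL, bin = 0.025, smooth_sd = 0.1,
                          units = NULL) {
  align <- match.arg(align)
  if (bin <= 0 || smooth_sd <= 0) stop("bin and smooth_sd must be > 0")
  if (is.null(units)) units <- sort(unique(spikes$unit_id))
  trial_ids <- vapply(trials, function(x) as.integer(x$trial_id), 1L)
  mv <- vapply(trials, function(x) x$movement, 1)
  if (is.null(window))
    window <- if (align == "stimulus") c(-1, max(mv)) else
      c(-max(mv), 0.2)
  edges <- seq(window[1], window[2], by = bin)
  nb <- length(edges) - 1
  centers <- edges[-length(edges)] + bin / 2
  ntr <- length(trials)

  # validity mask by alignment
  mask <- matrix(TRUE, ntr, nb)
  for (i in seq_len(ntr)) {
    if (align == "stimulus") {
      mask[i, edges[-1] > mv[i]] <- FALSE
    } else {
      mask[i, edges[-(nb + 1)] < -mv[i]] <- FALSE
    }
  }

  kern <- causal_gaussian_kernel(smooth_sd, bin)
  rate <- array(0, dim = c(ntr, nb, length(units)),
                dimnames = list(NULL, NULL, units))
  offset <- if (align == "movement") mv else rep(0, ntr)
  tr_index <- match(spikes$trial_id, trial_ids)
  u_index <- match(spikes$unit_id, units)
  keep <- !is.na(tr_index) & !is.na(u_index)
  st <- spikes$spike_time[keep] - offset[tr_index[keep]]
  bi <- findInterval(st, edges, left.open = FALSE)
  inb <- bi >= 1 & bi <= nb
  tab <- table(factor(u_index[keep][inb], levels = seq_along(units)),
               factor(tr_index[keep][inb], levels = seq_len(ntr)),
               factor(bi[inb], levels = seq_len(nb)))
  for (u in seq_along(units)) {
    counts <- matrix(tab[u, , ], ntr, nb) / bin
    rate[, , u] <- causal_smooth(counts, kern)
  }
  structure(list(align = align, centers = centers, bin = bin,
                 units = units, rate = rate, mask = mask,
                 trial_ids = trial_ids),
            class = "dc_rates")
}

#' Classify units as active and pre-movement side-selective
#'
#' A unit is active if its mean stimulus-onset-aligned firing rate from
#' 1 s before stimulus onset to the movement exceeds 1 Hz.  It is
#' pre-movement side-selective if its per-trial spike counts between
#' stimulus onset and movement differ between right- and left-choice
#' trials (two-tailed Welch t-test, p < alpha); the side with the higher
#' firing rate is its preferred side.  Selectivity implies activity.
#'
#' @param spikes long spike data.frame (stimulus-aligned seconds).
#' @param trials a \code{dc_trials} list with choices.
#' @param rate_threshold active-cell threshold in Hz (default 1).
#' @param alpha selectivity test level (default 0.05).
#' @param units unit ids (default: all in \code{spikes}).
#' @return data.frame with \code{unit_id}, \code{active},
#'   \code{selective}, \code{preferred} ("right"/"left"/"none"),
#'   \code{t_stat}, \code{p_value}.
#' @export
classify_cells <- function(spikes, trials, rate_threshold = 1,
                           alpha = 0.05, units = NULL) {
  if (is.null(units)) units <- sort(unique(spikes$unit_id))
  trial_ids <- vapply(trials, function(x) as.integer(x$trial_id), 1L)
  mv <- vapply(trials, function(x) x$movement, 1)
  choice <- vapply(trials, function(x) as.integer(x$choice), 1L)
  rows <- lapply(units, function(u) {
    sp <- spikes[spikes$unit_id == u, ]
    ti <- match(sp$trial_id, trial_ids)
    # counts from -1 s to movement (activity) and 0 to movement
    in_act <- sp$spike_time >= -1 & sp$spike_time <= mv[ti]
    n_act <- tabulate(ti[in_act], length(trials))
    active <- mean(n_act / (mv + 1)) > rate_threshold
    in_stim <- sp$spike_time >= 0 & sp$spike_time <= mv[ti]
    n_stim <- tabulate(ti[in_stim], length(trials))
    r_cnt <- n_stim[choice == 1L]
    l_cnt <- n_stim[choice == -1L]
    t_stat <- p <- NA_real_
    selective <- FALSE
    preferred <- "none"
    if (active && length(r_cnt) >= 2 && length(l_cnt) >= 2 &&
        (stats::sd(r_cnt) > 0 || stats::sd(l_cnt) > 0)) {
      tt <- stats::t.test(r_cnt, l_cnt)
      t_stat <- unname(tt$statistic)
      p <- tt$p.value
      selective <- p < alpha
      if (selective)
        preferred <- if (mean(r_cnt) > mean(l_cnt)) "right" else "left"
    }
    data.frame(unit_id = u, active = active, selective = selective,
               preferred = preferred, t_stat = t_stat, p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# AUC of rate classifying right (positive class) vs left choices for one
# bin's values; ties count 1/2 (Mann-Whitney with midranks).
auc_mw <- function(x, is_right) {
  nr <- sum(is_right); nl <- sum(!is_right)
  if (nr == 0 || nl == 0) return(NA_real_)
  r <- rank(x)
  (sum(r[is_right]) - nr * (nr + 1) / 2) / (nr * nl)
}

#' Choice-AUC timecourse with permutation significance
#'
#' Per 25 ms bin, the area under the ROC curve treating the smoothed rate
#' as a classifier of right versus left choice.  Significance per bin is
#' assessed against a permutation distribution obtained by shuffling
#' choice labels across trials (one relabeling applied to all bins);
#' two-tailed p-values use min-tail doubling with the add-one rule.  The
#' latency is the first bin starting a run of \code{run_len} consecutive
#' significant bins.
#'
#' @param rate trials x bins matrix of rates for one unit.
#' @param choice per-trial choices (+1/-1).
#' @param mask optional trials x bins validity mask.
#' @param n_perm number of permutations (default 250).
#' @param run_len run length defining latency (default 8 bins = 200 ms).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed for the permutations.
#' @return List with per-bin \code{auc}, \code{p}, \code{sig}, and
#'   \code{latency} (bin index, NA if never reached).
#' @export
auc_timecourse <- function(rate, choice, mask = NULL, n_perm = 250,
                           run_len = 8, alpha = 0.05, seed = NULL) {
  if (length(unique(choice)) < 2) stop("need >= 2 trials per choice")
  nb <- ncol(rate)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(rate), nb)
  obs <- p <- rep(NA_real_, nb)
  with_seed(seed, {
    perms <- replicate(n_perm, sample(choice))
    for (b in seq_len(nb)) {
      v <- which(mask[, b])
      if (length(v) < 4) next
      x <- rate[v, b]
      is_r <- choice[v] == 1L
      if (sum(is_r) == 0 || sum(!is_r) == 0) next
      obs[b] <- auc_mw(x, is_r)
      pa <- vapply(seq_len(n_perm), function(k)
        auc_mw(x, perms[v, k] == 1L), 1)
      hi <- (1 + sum(pa >= obs[b])) / (n_perm + 1)
      lo <- (1 + sum(pa <= obs[b])) / (n_perm + 1)
      p[b] <- min(1, 2 * min(hi, lo))
    }
  })
  sig <- !is.na(p) & p < alpha
  latency <- NA_integer_
  run <- rle(sig)
  pos <- cumsum(c(1, run$lengths))
  hit <- which(run$values & run$lengths >= run_len)
  if (length(hit)) latency <- pos[hit[1]]
  list(auc = obs, p = p, sig = sig, latency = latency)
}

#' Condition-averaged population PSTHs
#'
#' Averages smoothed rates over all trials from all pre-movement
#' side-selective cells, conditioned either on final-state-duration bin
#' crossed with whether the trial ended in a choice to the cell's
#' preferred side (\code{by = "fsd_pref"}), or on choice crossed with
#' outcome (\code{by = "choice_outcome"}).
#'
#' @param rates a \code{dc_rates} object.
#' @param trials the matching \code{dc_trials}.
#' @param classification output of \code{\link{classify_cells}}.
#' @param by conditioning scheme (see above).
#' @param fsd_breaks final-state-duration bin edges (s).
#' @return data.frame with \code{condition}, \code{time}, \code{mean},
#'   \code{sem}, \code{n}; empty conditions are omitted.
#' @export
population_psth <- function(rates, trials, classification,
                            by = c("fsd_pref", "choice_outcome"),
                            fsd_breaks = c(0, 0.5, 1, 1.5, 2)) {
  by <- match.arg(by)
  sel <- classification[classification$selective, ]
  if (nrow(sel) == 0) stop("no selective cells")
  choice <- vapply(trials, function(x) as.integer(x$choice), 1L)
  hit <- vapply(trials, function(x) as.logical(x$hit), NA)
  fsd <- vapply(trials, final_state_duration, 1)
  fsd_bin <- cut(fsd, fsd_breaks, include.lowest = TRUE)
  acc <- list()  # condition -> list(sum, sumsq, n) per bin
  for (u in sel$unit_id) {
    ui <- match(u, rates$units)
    if (is.na(ui)) next
    pref_choice <- if (sel$preferred[sel$unit_id == u] == "right") 1L
      else -1L
    cond <- if (by == "fsd_pref") {
      paste0("fsd=", as.character(fsd_bin), "|",
             ifelse(choice == pref_choice, "pref", "nonpref"))
    } else {
      paste0(ifelse(choice == 1L, "right", "left"), "|",
             ifelse(hit, "hit", "error"))
    }
    for (cc in unique(cond)) {
      i <- which(cond == cc)
      r <- rates$rate[i, , ui, drop = FALSE]
      dim(r) <- dim(r)[1:2]
      m <- rates$mask[i, , drop = FALSE]
      r[!m] <- NA
      if (is.null(acc[[cc]]))
        acc[[cc]] <- list(sum = 0, sumsq = 0, n = 0)
      acc[[cc]]$sum <- acc[[cc]]$sum + colSums(r, na.rm = TRUE)
      acc[[cc]]$sumsq <- acc[[cc]]$sumsq + colSums(r^2, na.rm = TRUE)
      acc[[cc]]$n <- acc[[cc]]$n + colSums(!is.na(r))
    }
  }
  out <- do.call(rbind, lapply(names(acc), function(cc) {
    a <- acc[[cc]]
    n <- pmax(a$n, 1)
    m <- a$sum / n
    v <- pmax(a$sumsq / n - m^2, 0)
    data.frame(condition = cc, time = rates$centers, mean = m,
               sem = sqrt(v / n), n = a$n)
  }))
  rownames(out) <- NULL
  out
}
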