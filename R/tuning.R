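#' Accumulator bin edges for tuning maps
#'
#' Eight inner bins of width \code{width} placed symmetrically about 0
#' plus two unbounded outer bins capturing the tails (10 bins total).
#'
#' @param width inner bin width in a-units (default 1.625).
#' @param n_inner number of inner bins (default 8, must be even).
#' @return List with \code{edges} (length 11, outer edges infinite) and
#'   \code{centers} (outer bins get pseudo-centers half a width beyond
#'   the last finite edge).
#' @export
tuning_a_bins <- function(width = 1.625, n_inner = 8) {
  stopifnot(n_inner %% 2 == 0)
  half <- n_inner / 2
  inner <- seq(-half * width, half * width, by = width)
  edges <- c(-Inf, inner, Inf)
  centers <- c(inner[1] - width / 2, inner[-length(inner)] + width / 2,
               inner[length(inner)] + width / 2)
  list(edges = edges, centers = centers)
}

#' Coarse posterior accumulator mass per trial and time bin
#'
#' Evaluates each trial's posterior at \code{dt_eval} resolution and
#' averages the analytic bin masses of the accumulator bins over the
#' evaluation slices falling in each coarse time bin.  A time bin is
#' valid for a trial only if it lies entirely within [0, duration].
#'
#' @param trials a \code{dc_trials} list with choices.
#' @param theta a \code{\link{model_params}}.
#' @param t_edges coarse time bin edges (s, stimulus-aligned).
#' @param a_edges accumulator bin edges (default \code{tuning_a_bins()}).
#' @param dt_eval posterior evaluation step (default 5 ms).
#' @return List per trial: \code{mass} (a-bins x time-bins; invalid
#'   columns NA) and \code{valid} (logical per time bin).
#' @export
posterior_coarse_mass <- function(trials, theta, t_edges,
                                  a_edges = tuning_a_bins()$edges,
                                  dt_eval = 0.005) {
  nt <- length(t_edges) - 1
  lapply(trials, function(tr) {
    valid <- t_edges[-length(t_edges)] >= 0 & t_edges[-1] <= tr$duration
    mass <- matrix(NA_real_, length(a_edges) - 1, nt)
    if (any(valid)) {
      tt <- unlist(lapply(which(valid), function(b)
        seq(t_edges[b] + dt_eval / 2, t_edges[b + 1], by = dt_eval)))
      bm <- posterior_bin_mass(tr, theta, tr$choice, a_edges, tt)
      bin_of <- findInterval(tt, t_edges, left.open = TRUE)
      for (b in which(valid))
        mass[, b] <- rowMeans(bm[, bin_of == b, drop = FALSE])
    }
    list(mass = mass, valid = valid)
  })
}

#' Downsample a fine posterior grid into coarse (a, t) bins
#'
#' The fine-grid counterpart of \code{\link{posterior_coarse_mass}} for a
#' single trial: probability mass from a \code{\link{posterior_grid}} is
#' summed into coarse accumulator bins and averaged over the fine time
#' slices within each coarse time bin.
#'
#' @param pg a \code{dc_posterior}.
#' @param t_edges,a_edges coarse bin edges.
#' @return Matrix (a-bins x time-bins); columns with no fine slices are
#'   NA.
#' @export
downsample_posterior <- function(pg, t_edges,
                                 a_edges = tuning_a_bins()$edges) {
  nt <- length(t_edges) - 1
  na <- length(a_edges) - 1
  abin <- pmin(pmax(findInterval(pg$a, a_edges), 1L), na)
  tbin <- findInterval(pg$times, t_edges, left.open = TRUE)
  out <- matrix(NA_real_, na, nt)
  for (b in seq_len(nt)) {
    cols <- which(tbin == b)
    if (!length(cols)) next
    m <- rowMeans(pg$mass[, cols, drop = FALSE])
    out[, b] <- as.numeric(tapply(m, factor(abin, levels = seq_len(na)),
                                  sum, default = 0))
  }
  out
}

#' Joint distribution of firing rate, accumulator value, and time
#'
#' For each trial and valid time bin, the trial's posterior accumulator
#' mass is added to the joint cell indexed by that time bin, each
#' accumulator bin, and the firing-rate bin containing the trial's rate
#' in that time bin (rates are discretized into \code{n_r_bins} bins
#' spanning the unit's observed range).  Each time slab is normalized by
#' the number of contributing trials, so it sums to one.
#'
#' @param rate trials x time-bins rate matrix for one unit.
#' @param mask trials x time-bins validity mask for the rates.
#' @param coarse_mass output of \code{\link{posterior_coarse_mass}} on
#'   the same trials and time bins.
#' @param n_r_bins number of firing-rate bins (default 100).
#' @param r_range rate range to span (default: observed min/max).
#' @return Class \code{dc_joint}: \code{mass} array (r-bins x a-bins x
#'   time-bins), \code{r_centers}, \code{n_trials} per time bin.
#' @export
build_joint <- function(rate, mask, coarse_mass, n_r_bins = 100,
                        r_range = NULL) {
  if (nrow(rate) != length(coarse_mass))
    stop("rate matrix and posterior masses refer to different trials")
  nt <- ncol(rate)
  na <- nrow(coarse_mass[[1]]$mass)
  if (is.null(r_range)) r_range <- range(rate[mask], finite = TRUE)
  if (diff(r_range) <= 0) r_range <- r_range + c(-0.5, 0.5)
  r_edges <- seq(r_range[1], r_range[2], length.out = n_r_bins + 1)
  r_centers <- r_edges[-length(r_edges)] + diff(r_edges) / 2
  mass <- array(0, dim = c(n_r_bins, na, nt))
  n_trials <- integer(nt)
  for (i in seq_along(coarse_mass)) {
    cm <- coarse_mass[[i]]
    for (b in which(cm$valid & mask[i, ])) {
      rb <- min(max(findInterval(rate[i, b], r_edges,
                                 rightmost.closed = TRUE), 1L), n_r_bins)
      mass[rb, , b] <- mass[rb, , b] + cm$mass[, b]
      n_trials[b] <- n_trials[b] + 1L
    }
  }
  for (b in which(n_trials > 0)) mass[, , b] <- mass[, , b] / n_trials[b]
  structure(list(mass = mass, r_centers = r_centers,
                 n_trials = n_trials),
            class = "dc_joint")
}

#' Evidence tuning map from a joint distribution
#'
#' Conditional expectation of the firing rate given accumulator value and
#' time, \code{E[r|a,t]}, its residual \code{E[dr|a,t] = E[r|a,t] -
#' E[r|t]} after subtracting the \code{P(a|t)}-weighted slice mean, and
#' the time-averaged tuning curve \code{E[dr|a]}.
#'
#' @param joint a \code{dc_joint}.
#' @param min_trials minimum contributing trials for a time bin to enter
#'   the map (default 10).
#' @param min_mass minimum accumulator-bin probability for a cell to be
#'   estimated (default 1e-4); sparser cells are masked.
#' @return Class \code{dc_map}: \code{Er}, \code{dEr} (time x a), slice
#'   means \code{Ert}, occupancy \code{pa} (time x a), \code{mask},
#'   \code{curve} (data.frame a-bin mean and sem over time bins).
#' @export
tuning_map <- function(joint, min_trials = 10, min_mass = 1e-4) {
  dims <- dim(joint$mass)
  na <- dims[2]; nt <- dims[3]
  Er <- matrix(NA_real_, nt, na)
  pa <- matrix(0, nt, na)
  tvalid <- joint$n_trials >= min_trials
  for (b in which(tvalid)) {
    sl <- joint$mass[, , b]          # r x a
    pa[b, ] <- colSums(sl)
    ok <- pa[b, ] > min_mass
    Er[b, ok] <- as.numeric(crossprod(sl[, ok, drop = FALSE],
                                      joint$r_centers)) / pa[b, ok]
  }
  mask <- !is.na(Er)
  Ert <- rep(NA_real_, nt)
  for (b in which(tvalid)) {
    w <- pa[b, mask[b, ]]
    if (sum(w) > 0)
      Ert[b] <- sum(Er[b, mask[b, ]] * w) / sum(w)
  }
  dEr <- Er - Ert
  curve <- data.frame(
    a_bin = seq_len(na),
    mean = colMeans(dEr, na.rm = TRUE),
    sem = apply(dEr, 2, function(x)
      stats::sd(x, na.rm = TRUE) / sqrt(max(sum(!is.na(x)), 1))))
  structure(list(Er = Er, dEr = dEr, Ert = Ert, pa = pa, mask = mask,
                 n_trials = joint$n_trials, curve = curve),
            class = "dc_map")
}

#' Rank-1 decomposition of a residual tuning map
#'
#' Singular value decomposition of \code{E[dr|a,t]} keeping the first
#' component: the map is approximated by the outer product of a temporal
#' gain \code{m(t) = u1 * s1 * range(v1)} (same units as the rates) and a
#' tuning curve \code{f(a) = v1 / range(v1)} with unit range.  Variance
#' explained is \code{s1 / sum(s_i)}.  The sign is fixed so that the
#' tuning curve increases toward the unit's preferred side.  Masked cells
#' are set to zero when they cover less than \code{max_masked} of the
#' map; otherwise the worst rows/columns are dropped first.
#'
#' @param map a \code{dc_map} or a numeric time x a matrix.
#' @param preferred "right" (tuning increases with a) or "left".
#' @param max_masked maximum masked fraction zero-filled (default 0.05).
#' @return Class \code{dc_rank1}: \code{m} (per time bin), \code{f} (per
#'   a bin), \code{ve}, \code{recon} (the rank-1 map), \code{rows},
#'   \code{cols} (retained indices).
#' @export
rank1 <- function(map, preferred = c("right", "left"),
                  max_masked = 0.05) {
  preferred <- match.arg(preferred)
  M <- if (inherits(map, "dc_map")) map$dEr else map
  rows <- which(rowSums(!is.na(M)) > 1)
  cols <- which(colSums(!is.na(M[rows, , drop = FALSE])) > 1)
  M <- M[rows, cols, drop = FALSE]
  # drop worst rows/cols until the masked fraction is tolerable
  while (anyNA(M) && mean(is.na(M)) > max_masked) {
    rna <- rowMeans(is.na(M)); cna <- colMeans(is.na(M))
    if (max(rna) >= max(cna)) {
      keep <- rna < max(rna); rows <- rows[keep]
      M <- M[keep, , drop = FALSE]
    } else {
      keep <- cna < max(cna); cols <- cols[keep]
      M <- M[, keep, drop = FALSE]
    }
  }
  if (nrow(M) < 2 || ncol(M) < 2)
    stop("map too masked for a rank-1 decomposition")
  M[is.na(M)] <- 0
  sv <- svd(M)
  u1 <- sv$u[, 1]; v1 <- sv$v[, 1]; s1 <- sv$d[1]
  # orient the tuning curve toward the preferred side
  slope <- stats::cov(v1, seq_along(v1))
  want <- if (preferred == "right") 1 else -1
  if (sign(slope) != 0 && sign(slope) != want) {
    u1 <- -u1; v1 <- -v1
  }
  rng <- diff(range(v1))
  if (rng == 0) rng <- 1
  m <- u1 * s1 * rng
  f <- v1 / rng
  structure(list(m = m, f = f, ve = s1 / sum(sv$d),
                 recon = outer(m, f), rows = rows, cols = cols),
            class = "dc_rank1")
}

#' Z-score a unit's rates over its unmasked bins
#'
#' @param rate trials x bins rate matrix.
#' @param mask validity mask; statistics use unmasked cells only.
#' @return The rate matrix in z-units.
#' @export
zscore_rates <- function(rate, mask) {
  v <- rate[mask]
  mu <- mean(v); s <- stats::sd(v)
  if (!is.finite(s) || s == 0) s <- 1
  (rate - mu) / s
}

#' Population-average residual tuning map and its rank-1 decomposition
#'
#' Per-cell residual maps computed from z-scored rates are averaged after
#' inverting the accumulator axis of left-preferring cells, and the
#' rank-1 decomposition is applied to the average.
#'
#' @param maps list of \code{dc_map} objects built from z-scored rates.
#' @param preferred character vector of the cells' preferred sides.
#' @return List with \code{map} (the averaged time x a residual matrix),
#'   \code{rank1} (its decomposition, oriented rightward), and
#'   \code{n_cells} contributing per cell.
#' @export
population_map <- function(maps, preferred) {
  stopifnot(length(maps) == length(preferred))
  if (length(maps) == 0) stop("need at least one selective cell")
  stack <- lapply(seq_along(maps), function(i) {
    M <- maps[[i]]$dEr
    if (preferred[i] == "left") M <- M[, rev(seq_len(ncol(M)))]
    M
  })
  dims <- dim(stack[[1]])
  arr <- array(unlist(stack), dim = c(dims, length(stack)))
  avg <- apply(arr, c(1, 2), function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  list(map = avg, rank1 = rank1(avg, preferred = "right"),
       n_cells = length(maps))
}
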