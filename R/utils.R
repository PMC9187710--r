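# Internal numeric helpers shared across modules.

# (e^x - 1)/x with the x -> 0 limit handled; used for the variance term
# (e^{2*lambda*t} - 1)/(2*lambda) = t * exprel(2*lambda*t).
exprel <- function(x) {
  out <- ifelse(abs(x) < 1e-8, 1 + x / 2, expm1(x) / x)
  out[x == 0] <- 1
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Wilson score 95% interval for a binomial proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  cbind(lower = ctr - hw, upper = ctr + hw)
}

# Causal (one-sided) Gaussian kernel on a regular grid with step `dt`,
# truncated at 4 SD and renormalized to unit mass.  Weight i corresponds to
# a lag of i*dt (i >= 0), so a spike only influences later (or current) bins.
causal_gaussian_kernel <- function(sd, dt) {
  n <- max(1L, ceiling(4 * sd / dt))
  lags <- (0:n) * dt
  k <- exp(-lags^2 / (2 * sd^2))
  k / sum(k)
}

# Causal filter of a numeric vector (or each row of a matrix) with the kernel
# above; zero-padded at the left edge.
causal_smooth <- function(x, kernel) {
  f <- function(v) {
    out <- stats::filter(c(rep(0, length(kernel) - 1), v), kernel,
                         method = "convolution", sides = 1)
    as.numeric(out[-seq_len(length(kernel) - 1)])
  }
  if (is.matrix(x)) t(apply(x, 1, f)) else f(x)
}

# Centered running mean over `n` samples (partial windows at the edges).
running_mean <- function(x, n) {
  if (n <= 1) return(x)
  cs <- cumsum(c(0, x))
  len <- length(x)
  half_lo <- floor((n - 1) / 2)
  half_hi <- n - 1 - half_lo
  lo <- pmax(seq_len(len) - half_lo, 1L)
  hi <- pmin(seq_len(len) + half_hi, len)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Derive a per-stage RNG seed from a master seed (kept below 2^31).
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + 1000003L * (h %% 1000L)) %% 2147483647L
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}
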