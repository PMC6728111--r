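# Independent test oracles. These deliberately use naive explicit loops and
# closed-form small-model fits so they share no code path with the package
# implementations they check.

# Brute-force RQA: enumerate every cell and walk every diagonal/column run
# with a manual counter. Maximum-norm distance; Theiler band |i-j| <= w
# excluded from counts and breaking vertical runs.
oracle_rqa <- function(x, m = 1, tau = 1, eps, w = 0, lmin = 2) {
  n <- length(x) - (m - 1) * tau
  V <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (k in seq_len(m)) V[i, k] <- x[i + (k - 1) * tau]
  R <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- 0
    for (k in seq_len(m)) d <- max(d, abs(V[i, k] - V[j, k]))
    if (d <= eps) R[i, j] <- 1L
  }
  n_off <- 0L; n_rec <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) > w) {
      n_off <- n_off + 1L
      n_rec <- n_rec + R[i, j]
    }
  }
  REC <- n_rec / n_off
  if (n_rec == 0L) {
    return(list(REC = 0, DET = NA_real_, LAM = NA_real_, Lmean = NA_real_,
                Lmax = NA_integer_, DIV = NA_real_))
  }
  dlens <- integer(0)
  for (off in seq(-(n - 1), n - 1)) {
    if (abs(off) <= w) next
    run <- 0L
    for (i in seq_len(n)) {
      j <- i + off
      if (j < 1 || j > n) next
      if (R[i, j] == 1L) {
        run <- run + 1L
      } else {
        if (run > 0L) dlens <- c(dlens, run)
        run <- 0L
      }
    }
    if (run > 0L) dlens <- c(dlens, run)
  }
  vlens <- integer(0)
  for (j in seq_len(n)) {
    run <- 0L
    for (i in seq_len(n)) {
      if (abs(i - j) > w && R[i, j] == 1L) {
        run <- run + 1L
      } else {
        if (run > 0L) vlens <- c(vlens, run)
        run <- 0L
      }
    }
    if (run > 0L) vlens <- c(vlens, run)
  }
  list(REC = REC,
       DET = sum(dlens[dlens >= lmin]) / n_rec,
       LAM = sum(vlens[vlens >= lmin]) / n_rec,
       Lmean = if (any(dlens >= lmin)) mean(dlens[dlens >= lmin]) else NA_real_,
       Lmax = max(dlens),
       DIV = 1 / max(dlens))
}

expect_rqa_equal <- function(f, o, label = "") {
  for (nm in c("REC", "DET", "LAM", "Lmean", "DIV")) {
    expect_equal(as.numeric(f[[nm]]), as.numeric(o[[nm]]),
                 tolerance = 1e-12, label = paste(label, nm))
  }
  expect_equal(as.integer(f$Lmax), as.integer(o$Lmax),
               label = paste(label, "Lmax"))
}

# Grid-search cosinor oracle: scan the peak time at `step`-hour resolution,
# fitting mesor and (signed) amplitude by closed-form simple regression at
# each grid point, and return the minimal SSE.
oracle_cosinor_grid <- function(y, t, period = 24, step = 0.01) {
  w <- 2 * pi / period
  best_sse <- Inf; best_peak <- NA_real_; best_b <- NA_real_
  my <- mean(y)
  for (peak in seq(0, period - step, by = step)) {
    cc <- cos(w * (t - peak))
    mc <- mean(cc)
    sxx <- sum((cc - mc)^2)
    b <- if (sxx == 0) 0 else sum((cc - mc) * (y - my)) / sxx
    sse <- sum((y - my - b * (cc - mc))^2)
    if (sse < best_sse) {
      best_sse <- sse
      best_peak <- peak
      best_b <- b
    }
  }
  # a negative fitted amplitude is the same curve peaking half a period later
  if (!is.na(best_b) && best_b < 0) {
    best_peak <- (best_peak + period / 2) %% period
  }
  list(sse = best_sse, peak = best_peak)
}

# Full 2^n enumeration of the Wilcoxon signed-rank null (handles mid-ranked
# ties); two-sided p = min(1, 2 * min(lower tail, upper tail)).
oracle_wilcoxon_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  all_W <- numeric(2^n)
  for (s in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(s))[seq_len(n)]
    all_W[s + 1] <- sum(r[bits == 1L])
  }
  p_le <- mean(all_W <= W + 1e-9)
  p_ge <- mean(all_W >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Two-group rank-sum z-test (no continuity correction); with k = 2 groups
# the Kruskal-Wallis chi-square statistic is exactly this z squared.
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (W - mu) / sqrt(sig2)
  2 * pnorm(-abs(z))
}

# Circular difference between two clock times on a `period`-hour dial.
circ_diff_h <- function(a, b, period = 24) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

# Small synthetic series: cosine plus white noise, for RQA noise sweeps.
noisy_cosine <- function(n = 24, A = 0.4, peak = 19, M = 37, sd = 0.1) {
  t <- 9 + seq_len(n) - 1
  M + A * cos(2 * pi * (t - peak) / 24) + rnorm(n, 0, sd)
}

with_seed_runif <- function(seed, n, min, max) {
  set.seed(seed)
  runif(n, min, max)
}

with_seed_rnorm <- function(seed, n, mean, sd) {
  set.seed(seed)
  rnorm(n, mean, sd)
}
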