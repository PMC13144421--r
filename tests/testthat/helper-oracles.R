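# Independent oracles used to check the package's computational cores.
# Each is written as the plainest possible implementation of its
# definition, sharing no code with the package internals.

# Exhaustive affine-gap local alignment (Gotoh three-state DP) with the
# same gap-cost convention as the scan: a gap of length L costs
# gap_open + gap_ext * L.
gotoh_local_score <- function(a, b, match = 2, mismatch = -3,
                              gap_open = 5, gap_ext = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Exhaustive optimal anchor chain: enumerate every subset (n <= ~18),
# keep those forming a monotone chain under the rank-gap constraint,
# return the maximum size.
chain_oracle_best <- function(rank_a, rank_b, max_gap) {
  n <- length(rank_a)
  stopifnot(n <= 18)
  ord <- order(rank_a)
  ra <- rank_a[ord]
  rb <- rank_b[ord]
  chain_ok <- function(idx, sgn) {
    if (length(idx) < 2) return(TRUE)
    da <- diff(ra[idx])
    db <- diff(sgn * rb[idx])
    all(da > 0 & db > 0 & da <= max_gap & abs(diff(rb[idx])) <= max_gap)
  }
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    if (chain_ok(idx, 1) || chain_ok(idx, -1)) best <- length(idx)
  }
  best
}

# Brute-force PWM p-values: enumerate all 4^w words, accumulating the
# score column-by-column (left to right, like any scanner would).
pwm_enum <- function(pwm) {
  w <- pwm$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words))
  pr <- rep(1, nrow(words))
  for (j in seq_len(w)) {
    sc <- sc + pwm$log_odds[words[, j], j]
    pr <- pr * pwm$background[words[, j]]
  }
  list(scores = sc, probs = pr,
       pvalue = function(s) sum(pr[sc >= s]))
}

# Forward-simulate a K2P substitution process: per-site probabilities of
# a transition / each transversion after divergence K_true = (a + 2b)t,
# using the analytic K2P transition probabilities.
simulate_k2p_pair <- function(n_sites, alpha, beta, t) {
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * t) -
    0.5 * exp(-2 * (alpha + beta) * t)
  p_tv <- 0.25 - 0.25 * exp(-4 * beta * t)  # per transversion target
  bases <- c("A", "C", "G", "T")
  ts_of <- c(A = "G", C = "T", G = "A", T = "C")
  tv_of <- list(A = c("C", "T"), C = c("A", "G"),
                G = c("C", "T"), T = c("A", "G"))
  anc <- sample(bases, n_sites, replace = TRUE)
  u <- runif(n_sites)
  der <- anc
  is_ts <- u < p_ts
  is_tv <- !is_ts & u < p_ts + 2 * p_tv
  der[is_ts] <- ts_of[anc[is_ts]]
  pick <- runif(sum(is_tv)) < 0.5
  der[is_tv] <- mapply(function(b, first) tv_of[[b]][1 + !first],
                       anc[is_tv], pick)
  list(a = paste(anc, collapse = ""), b = paste(der, collapse = ""),
       K_true = (alpha + 2 * beta) * t)
}

# Asymptotic standard error of the K2P estimator (Kimura 1980).
k2p_se <- function(P, Q, n) {
  c1 <- 1 / (1 - 2 * P - Q)
  c2 <- 1 / (1 - 2 * Q)
  c3 <- (c1 + c2) / 2
  sqrt((c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n)
}
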