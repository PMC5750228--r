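# Independent oracles: small, self-contained reimplementations used only to
# verify the package's operations from a second route.

# Needleman-Wunsch oracle: exhaustive dynamic programming with linear gap
# penalty; returns the optimal global score and the identity (identical
# columns / alignment length) of the traceback alignment (ties prefer
# diagonal, then up, then left).
nw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- S[i, j] + if (A[i] == B[j]) match else mismatch
      S[i + 1, j + 1] <- max(sub, S[i, j + 1] + gap, S[i + 1, j] + gap)
    }
  }
  # traceback
  i <- n; j <- m; cols <- 0L; idents <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (A[i] == B[j]) match else mismatch)) {
      idents <- idents + (A[i] == B[j])
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1L
  }
  list(score = S[n + 1, m + 1], identity = 100 * idents / cols)
}

# Spearman's rank-difference formula, valid for tie-free vectors.
spearman_formula_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Benjamini-Hochberg step-up by hand: sort ascending, m*p/i, cumulative
# minimum from the largest rank, cap at 1, unsort.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact two-sided binomial p at p0 = 0.5 by brute-force enumeration of all
# 2^n equally likely outcome sequences.
binom_enum_oracle <- function(k, n) {
  stopifnot(n <= 16)
  succ <- vapply(0:(2^n - 1), function(x) sum(bitwAnd(x, bitwShiftL(1, 0:(n - 1))) > 0),
                 numeric(1))
  lower <- sum(succ <= k) / 2^n
  upper <- sum(succ >= k) / 2^n
  min(1, 2 * min(lower, upper))
}

# Fine-step forward Euler for a single metabolite with one consumer at
# constant abundance: dM/dt = -u * B * M / (K + M), independent loop.
ode_uptake_oracle <- function(M0, u, B, K, t_end, dt = 0.001) {
  M <- M0
  t <- 0
  while (t < t_end - 1e-12) {
    h <- min(dt, t_end - t)
    M <- max(0, M - h * u * B * M / (K + M))
    t <- t + h
  }
  M
}

# Sequential (type-I) F-tests for condition and condition:time from first
# principles: nested least-squares fits and SSE differences.
ols_f_oracle <- function(y, condition, time) {
  fit_sse <- function(X) {
    beta <- qr.solve(qr(X), y)
    sum((y - X %*% beta)^2)
  }
  cond <- as.numeric(factor(condition)) - 1
  one <- rep(1, length(y))
  X0 <- cbind(one)
  X1 <- cbind(one, cond)
  X2 <- cbind(one, cond, time)
  X3 <- cbind(one, cond, time, cond * time)
  n <- length(y)
  sse3 <- fit_sse(X3)
  mse <- sse3 / (n - 4)
  F_cond <- ((fit_sse(X0) - fit_sse(X1)) / 1) / mse
  F_int <- ((fit_sse(X2) - sse3) / 1) / mse
  c(
    p_condition = stats::pf(F_cond, 1, n - 4, lower.tail = FALSE),
    p_interaction = stats::pf(F_int, 1, n - 4, lower.tail = FALSE)
  )
}
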