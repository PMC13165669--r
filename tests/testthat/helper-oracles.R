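## Independent reference implementations used as oracles.  These are
## deliberately naive (direct sums, textbook recursions, exhaustive
## enumeration) and share no code with the package internals they check.

## Direct-sum MODWT per the pyramid definition, O(N * filter * J).
naive_modwt <- function(x, g, h, J) {
  n <- length(x)
  gt <- g / sqrt(2)
  ht <- h / sqrt(2)
  W <- vector("list", J)
  v <- x
  for (j in seq_len(J)) {
    step <- 2^(j - 1)
    wj <- numeric(n)
    vj <- numeric(n)
    for (t in seq_len(n)) {
      aw <- 0
      av <- 0
      for (l in seq_along(gt)) {
        idx <- ((t - 1 - step * (l - 1)) %% n) + 1
        aw <- aw + ht[l] * v[idx]
        av <- av + gt[l] * v[idx]
      }
      wj[t] <- aw
      vj[t] <- av
    }
    W[[j]] <- wj
    v <- vj
  }
  list(W = W, V = v)
}

## db4 scaling filter and its quadrature mirror, written out directly.
oracle_db4 <- function() {
  g <- c(0.2303778133088552, 0.7148465705525415, 0.6308807679295904,
         -0.0279837694169839, -0.1870348117188811, 0.0308413818359870,
         0.0328830116669829, -0.0105974017849973)
  h <- (-1)^(0:7) * rev(g)
  list(g = g, h = h)
}

## Textbook fixed-covariance scalar Kalman filter (random-walk state).
ref_kalman <- function(x, q, r) {
  n <- length(x)
  out <- numeric(n)
  est <- x[1]
  P <- r
  for (t in seq_len(n)) {
    P_pred <- P + q
    K <- P_pred / (P_pred + r)
    est <- est + K * (x[t] - est)
    P <- (1 - K) * P_pred
    out[t] <- est
  }
  out
}

## Exhaustive peak matcher: maximizes matched pairs within the window,
## breaking ties by minimum total absolute error.
brute_force_match <- function(hat, ref, window) {
  best <- list(n = -1L, total = Inf, errors = numeric(0))
  recurse <- function(ri, used_h, errors) {
    if (ri > length(ref)) {
      n <- length(errors)
      tot <- sum(errors)
      if (n > best$n || (n == best$n && tot < best$total))
        best <<- list(n = n, total = tot, errors = errors)
      return(invisible(NULL))
    }
    recurse(ri + 1L, used_h, errors)          # leave ref[ri] unmatched
    for (hi in seq_along(hat)) {
      d <- abs(hat[hi] - ref[ri])
      if (!used_h[hi] && d <= window) {
        used_h[hi] <- TRUE
        recurse(ri + 1L, used_h, c(errors, d))
        used_h[hi] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(hat)), numeric(0))
  list(errors = sort(best$errors), misses = length(ref) - best$n)
}

## One standard simulated segment pair used across tests.
make_test_displacement <- function() {
  t <- (0:999) / 100
  list(t = t, x = 0.2 * sin(2 * pi * 1.2 * t) + 4 * sin(2 * pi * 0.25 * t))
}
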