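# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: closed-form matrix algebra for 2SLS, recursive
# exhaustive search for CART, sort-based order statistics, O(n^2) pair
# counting for partition agreement, and a hand-rolled IRLS loop for the
# logistic fit.

# closed-form just-identified 2SLS: beta = (Z'X)^{-1} Z'y, homoskedastic
# covariance sigma^2 (Xhat'Xhat)^{-1} with residuals against original X
oracle_2sls <- function(y, w, z, controls = NULL) {
  X <- cbind(1, w, controls)
  Zm <- cbind(1, z, controls)
  beta <- solve(t(Zm) %*% X, t(Zm) %*% y)
  r <- y - X %*% beta
  P <- Zm %*% solve(t(Zm) %*% Zm) %*% t(Zm)
  Xh <- P %*% X
  V <- as.numeric(t(r) %*% r) / (length(y) - ncol(X)) * solve(t(Xh) %*% Xh)
  fs <- lm(w ~ Zm - 1)
  tz <- summary(fs)$coefficients[2, 3]
  list(ive = beta[2], se = sqrt(V[2, 2]), F = tz^2)
}

# recursive exhaustive variance-reduction tree (depth-limited)
oracle_cart <- function(x, tau, max_depth, min_node) {
  splits <- list()
  recurse <- function(idx, id, depth) {
    if (depth >= max_depth || length(idx) < 2 * min_node) return()
    n <- length(idx)
    best <- NULL
    best_sse <- sum((tau[idx] - mean(tau[idx]))^2) - 1e-12 * max(1, sum((tau[idx] - mean(tau[idx]))^2))
    for (v in seq_len(ncol(x))) {
      for (c in sort(unique(x[idx, v]))) {
        l <- idx[x[idx, v] <= c]
        r <- idx[x[idx, v] > c]
        if (length(l) < min_node || length(r) < min_node) next
        sse <- sum((tau[l] - mean(tau[l]))^2) + sum((tau[r] - mean(tau[r]))^2)
        if (sse < best_sse) {
          best_sse <- sse
          best <- list(var = v, threshold = c, l = l, r = r)
        }
      }
    }
    if (is.null(best)) return()
    splits[[as.character(id)]] <<- c(var = best$var, threshold = best$threshold)
    recurse(best$l, 2 * id, depth + 1)
    recurse(best$r, 2 * id + 1, depth + 1)
  }
  recurse(seq_len(nrow(x)), 1, 0)
  splits
}

# adjusted Rand index by brute-force pair counting (n small)
oracle_pair_agreement <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  total <- n * (n - 1) / 2
  expected <- (n11 + n10) * (n11 + n01) / total
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(1)
  (n11 - expected) / (maxi - expected)
}

# type-7 (linear interpolation) quantile from a sorted copy
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# patient-count quintiles by explicit sort-and-cut with ties to the lower
oracle_quintiles <- function(v) {
  n <- length(v)
  s <- sort(v)
  cuts <- s[ceiling(n * (1:4) / 5)]
  vapply(v, function(x) {
    q <- 1L
    for (c in cuts) if (x > c) q <- q + 1L
    q
  }, integer(1))
}

# logistic ML by hand-rolled iteratively reweighted least squares
oracle_irls_logit <- function(X, y, iter = 30) {
  beta <- rep(0, ncol(X))
  for (k in seq_len(iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    wt <- mu * (1 - mu)
    zr <- eta + (y - mu) / wt
    beta <- solve(t(X) %*% (X * wt), t(X) %*% (wt * zr))
  }
  as.numeric(beta)
}
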