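# Independent oracles used to check the package implementations.
# These deliberately share no code with the package: enumeration, hand
# formulas and plain-R reference algorithms only.

# Exhaustive forward-backward: sum over all 3^n state paths.
enum_fb <- function(x, mu, sd, start, trans) {
  n <- length(x)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  probs <- apply(paths, 1, function(s) {
    p <- start[s[1]] * dnorm(x[1], mu[s[1]], sd[s[1]])
    if (n > 1) for (t in 2:n)
      p <- p * trans[s[t - 1], s[t]] * dnorm(x[t], mu[s[t]], sd[s[t]])
    p
  })
  total <- sum(probs)
  gamma <- sapply(1:3, function(k)
    sapply(1:n, function(t) sum(probs[paths[, t] == k]) / total))
  list(gamma = matrix(gamma, nrow = n), loglik = log(total))
}

# Plain-R maximum-likelihood Baum-Welch (log-space E-step), no priors.
ml_bw_ref <- function(seqs, mu, sd, start, trans, n_iter) {
  logsumexp <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  for (it in seq_len(n_iter)) {
    g_sum <- gx <- gx2 <- g_first <- numeric(3)
    xi_sum <- matrix(0, 3, 3)
    for (x in seqs) {
      n <- length(x)
      lb <- sapply(1:3, function(k) dnorm(x, mu[k], sd[k], log = TRUE))
      lb <- matrix(lb, nrow = n)
      la <- matrix(-Inf, n, 3); lbt <- matrix(-Inf, n, 3)
      la[1, ] <- log(start) + lb[1, ]
      if (n > 1) for (t in 2:n) for (j in 1:3)
        la[t, j] <- logsumexp(la[t - 1, ] + log(trans[, j])) + lb[t, j]
      lbt[n, ] <- 0
      if (n > 1) for (t in (n - 1):1) for (i in 1:3)
        lbt[t, i] <- logsumexp(log(trans[i, ]) + lb[t + 1, ] + lbt[t + 1, ])
      ll <- logsumexp(la[n, ])
      lg <- la + lbt - ll
      g <- exp(lg)
      g_first <- g_first + g[1, ]
      g_sum <- g_sum + colSums(g)
      gx <- gx + colSums(g * x)
      gx2 <- gx2 + colSums(g * x^2)
      if (n > 1) for (t in 1:(n - 1)) for (i in 1:3) for (j in 1:3)
        xi_sum[i, j] <- xi_sum[i, j] +
          exp(la[t, i] + log(trans[i, j]) + lb[t + 1, j] + lbt[t + 1, j] - ll)
    }
    mu <- gx / g_sum
    s2 <- pmax(gx2 / g_sum - mu^2, 1e-6)
    sd <- sqrt(s2)
    start <- g_first / sum(g_first)
    trans <- xi_sum / rowSums(xi_sum)
  }
  list(mu = mu, sd = sd, start = start, trans = trans)
}

# One-sided hypergeometric upper tail P(X >= a) for the 2x2 table
# (a, b; c, d): X ~ Hypergeom(N = a+b+c+d, K = a+b successes, n = a+c draws).
hyper_tail_p <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + b; n <- a + c
  ks <- max(0, n - (N - K)):min(K, n)
  pm <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pm[ks >= a])
}

# Benjamini-Hochberg step-up by the textbook formula.
bh_ref <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- running
  }
  pmin(q, 1)
}

# Exact one-sided Wilcoxon rank-sum by enumeration of rank assignments:
# P(W >= w_obs) where W = rank-sum statistic of the first group minus its
# minimum (the wilcox.test convention).
wilcox_enum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- combn(m + n, m)
  ws <- apply(combos, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  mean(ws >= w_obs)
}

# Naive ward.D2 agglomeration via the Lance-Williams update on squared
# distances; returns the list of merged leaf sets (topology only).
ward_ref_sets <- function(d) {
  labels <- attr(d, "Labels")
  n <- attr(d, "Size")
  D2 <- as.matrix(d)^2
  active <- seq_len(n)
  members <- lapply(seq_len(n), function(i) labels[i])
  sizes <- rep(1, n)
  sets <- list()
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestv <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii < jj) {
        i <- active[ii]; j <- active[jj]
        if (D2[i, j] < bestv) { bestv <- D2[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    new_members <- sort(c(members[[i]], members[[j]]))
    sets[[step]] <- new_members
    for (k in active) {
      if (k == i || k == j) next
      D2[i, k] <- D2[k, i] <-
        ((sizes[i] + sizes[k]) * D2[i, k] + (sizes[j] + sizes[k]) * D2[j, k] -
           sizes[k] * D2[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    members[[i]] <- new_members
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  sets
}

# Random row-stochastic 3x3 matrix / simplex, for parameterised oracle tests.
random_simplex <- function() { p <- runif(3, 0.05, 1); p / sum(p) }
random_trans <- function() t(replicate(3, random_simplex()))
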