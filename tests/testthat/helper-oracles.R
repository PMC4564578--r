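# Independent brute-force oracles. These deliberately share no code with
# the package implementations they audit.

# Hypergeometric upper tail by direct term-by-term summation.
oracle_fisher_p <- function(N, K, n, k) {
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  if (k > hi) return(0)
  j <- max(k, lo):hi
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# BH adjusted p-values via the defining minimization over larger ranks.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Conditional NB exact test by naive split enumeration on the probability
# scale (no log-space trick, unnormalized masses).
oracle_nb_exact <- function(kA, kB, sfA, sfB, alpha) {
  KA <- sum(kA); KB <- sum(kB); S <- KA + KB
  if (S == 0) return(1)
  sA <- sum(sfA); sB <- sum(sfB)
  q <- S / (sA + sB)
  muA <- q * sA; muB <- q * sB
  dens <- function(x, mu, ssum, ssqsum) {
    if (alpha < 1e-12) dpois(x, mu)
    else dnbinom(x, mu = mu, size = ssum^2 / (alpha * ssqsum))
  }
  pr <- numeric(S + 1)
  for (a in 0:S) {
    pr[a + 1] <- dens(a, muA, sA, sum(sfA^2)) *
      dens(S - a, muB, sB, sum(sfB^2))
  }
  p_obs <- pr[KA + 1]
  sum(pr[pr <= p_obs * (1 + 1e-9)]) / sum(pr)
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every
# assignment of the pooled ranks to group A (untied data only).
oracle_wilcoxon <- function(x, y) {
  nA <- length(x)
  n <- nA + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  combos <- utils::combn(n, nA)
  u_all <- apply(combos, 2, function(ix) sum(ix) - nA * (nA + 1) / 2)
  pl <- mean(u_all <= u_obs)
  pu <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pu))
}
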