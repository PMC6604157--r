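# Independent brute-force oracles used to pin down the exact-test
# conventions. Each enumerates the relevant null distribution directly from
# combinatorial first principles, without calling the implementation path.

# exact HWE p by full enumeration of the conditional distribution of the
# heterozygote count given the allele counts
hwe_enum_p <- function(hom_min, het, hom_maj) {
  n <- hom_min + het + hom_maj
  n1 <- min(2 * hom_min + het, 2 * n - (2 * hom_min + het))
  if (n1 == 0) return(1)
  hs <- seq(n1 %% 2, n1, by = 2)
  pr <- vapply(hs, function(k) {
    mm <- (n1 - k) / 2
    MM <- n - mm - k
    exp(lfactorial(n) - lfactorial(mm) - lfactorial(k) - lfactorial(MM) +
          k * log(2) +
          lfactorial(n1) + lfactorial(2 * n - n1) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(min(het, n1), hs)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# over-representation tail P(X >= k) by direct enumeration of overlap counts
hypergeom_enum_p <- function(k, K, n, N) {
  ks <- max(0, K + n - N):min(K, n)
  pr <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pr[ks >= k])
}

# two-sided exact signed-rank p by enumerating all 2^n sign assignments
signed_rank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.vector(signs %*% r)
  p_lo <- mean(v_null <= v_obs)
  p_hi <- mean(v_null >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# two-sided exact binomial p (minlike) by enumerating outcome probabilities
binom_enum_p <- function(k, n, p = 0.5) {
  pr <- dbinom(0:n, n, p)
  sum(pr[pr <= pr[k + 1] * (1 + 1e-7)])
}

# brute-force optimal assignment total distance over all pairings (nA <= 6)
assignment_optimum <- function(D) {
  na <- nrow(D)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- Inf
  for (jj in perms(seq_len(ncol(D)))) {
    tot <- sum(D[cbind(seq_len(na), jj[seq_len(na)])])
    if (tot < best) best <- tot
  }
  best
}
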