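# Independent oracles the implementation is checked against.

# Brute-force latent-clonal-arm enumeration: explicit products over arms,
# no algebraic simplification. States in {-1, 0, 1}; pg/pl are the clipped
# per-arm gain/loss probabilities.
llr_oracle <- function(sa, sb, pg, pl, floor = -50) {
  K <- length(sa)
  p_state <- function(k, s) {
    if (s == 1) pg[k] else if (s == -1) pl[k] else 1 - pg[k] - pl[k]
  }
  L0 <- 1
  for (k in seq_len(K)) L0 <- L0 * p_state(k, sa[k]) * p_state(k, sb[k])
  L1 <- 0
  for (j in seq_len(K)) {
    term <- if (sa[j] == sb[j] && sa[j] != 0) p_state(j, sa[j]) else 0
    for (k in seq_len(K)) {
      if (k != j) term <- term * p_state(k, sa[k]) * p_state(k, sb[k])
    }
    L1 <- L1 + term / K
  }
  if (L1 == 0) floor else log10(L1 / L0)
}

# Exact Fisher p by enumerating every table with the observed margins and
# the classical factorial probability formula (no dhyper).
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ptab <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (min(b, cc, d) < 0) return(NA_real_)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
          lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(cc) -
          lfactorial(d))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, ptab, numeric(1))
  obs <- ptab(m[1, 1])
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Textbook Pearson correlation written out by hand.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}
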