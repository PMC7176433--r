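# Independent oracles, kept deliberately naive and separate from the
# implementations they check.

# Exhaustive Polya-urn evaluation of the Dirichlet-multinomial pmf for one
# count column x (total N = sum(x) small): enumerate every ordered draw
# sequence, accumulate urn probabilities of sequences whose tabulation
# equals x. log(pmf) - log(multinomial coefficient) must equal dm_loglik.
polya_urn_logpmf_noperm <- function(x, pi, phi) {
  s <- length(x)
  n <- sum(x)
  if (n == 0) return(0)
  alpha <- phi * pi
  seqs <- as.matrix(expand.grid(rep(list(seq_len(s)), n)))
  total <- 0
  for (r in seq_len(nrow(seqs))) {
    draw <- seqs[r, ]
    if (!all(tabulate(draw, nbins = s) == x)) next
    cnt <- numeric(s)
    p <- 1
    for (t in seq_len(n)) {
      k <- draw[t]
      p <- p * (alpha[k] + cnt[k]) / (phi + t - 1)
      cnt[k] <- cnt[k] + 1
    }
    total <- total + p
  }
  log(total) - (lfactorial(n) - sum(lfactorial(x)))
}

# Brute-force single-linkage clustering of integer positions on a line.
brute_single_linkage <- function(pos, gap) {
  pos <- sort(unique(pos))
  groups <- list()
  cur <- pos[1]
  for (p in pos[-1]) {
    if (p - max(cur) <= gap) cur <- c(cur, p)
    else { groups <- c(groups, list(cur)); cur <- p }
  }
  c(groups, list(cur))
}

# Direct-sum Gaussian convolution with explicit reflect padding.
direct_gaussian <- function(x, sigma) {
  n <- length(x)
  r <- as.integer(ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  refl <- function(i) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq(-r, r)) acc <- acc + k[j + r + 1] * x[refl(i + j)]
    out[i] <- acc
  }
  out
}

# Textbook step-up BH.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
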