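# Independent oracles used to cross-check the exact-test implementations.
# They deliberately take different computational routes (stats::dhyper and
# direct binomial-coefficient products) from the package's log-space
# enumeration.

# two-sided Fisher 2x2 p-value via the hypergeometric density
oracle_fisher_2x2 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) return(1)
  k <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
  d <- stats::dhyper(k, cs[1], cs[2], rs[1])
  obs <- stats::dhyper(tab[1, 1], cs[1], cs[2], rs[1])
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

# brute-force 2x3 Freeman-Halton oracle by direct enumeration with
# binomial-coefficient products (safe for row totals up to ~20 against
# arbitrary column sums)
oracle_fisher_2x3 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || sum(cs > 0) < 2) return(1)
  if (rs[2] < rs[1]) tab <- tab[2:1, , drop = FALSE]
  n1 <- sum(tab[1, ]); n <- sum(tab)
  point <- function(a, b, c) {
    choose(cs[1], a) * choose(cs[2], b) * choose(cs[3], c) / choose(n, n1)
  }
  obs <- point(tab[1, 1], tab[1, 2], tab[1, 3])
  total <- 0
  for (a in 0:min(n1, cs[1])) for (b in 0:min(n1 - a, cs[2])) {
    c <- n1 - a - b
    if (c > cs[3]) next
    pr <- point(a, b, c)
    if (pr <= obs * (1 + 1e-7)) total <- total + pr
  }
  min(1, total)
}

# literal step-up rule, independent of stats::p.adjust
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0L, which(ps <= seq_len(m) * q / m)))
  reject <- logical(m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  # ties share a fate
  if (k > 0) reject[p <= ps[k]] <- TRUE
  reject
}

# random valid 2xK table with given row sums
random_table <- function(n1, n2, K, rng_probs = NULL) {
  pr <- if (is.null(rng_probs)) rep(1 / K, K) else rng_probs
  rbind(as.vector(stats::rmultinom(1, n1, pr)),
        as.vector(stats::rmultinom(1, n2, pr)))
}
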