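# Independent oracles used across the suite.  These deliberately take the
# slow, literal route (per-read products, explicit enumeration,
# hypergeometric summation) so they share no code with the implementation
# they check.

# per-read product likelihoods, independent errors, e = 10^(-min(bq,mq)/10)
# clamped at 0.75; het term exactly 1/2 for either allele, e/3 otherwise
brute_log10_lik <- function(alleles, bq, mq, ref, alt) {
  e <- pmin(10^(-pmin(bq, mq, 63) / 10), 0.75)
  l <- c(0, 0, 0)
  for (i in seq_along(alleles)) {
    b <- alleles[i]
    p0 <- if (b == ref) 1 - e[i] else e[i] / 3
    p2 <- if (b == alt) 1 - e[i] else e[i] / 3
    p1 <- if (b %in% c(ref, alt)) 0.5 else e[i] / 3
    l <- l + log10(c(p0, p1, p2))
  }
  l
}

# joint P(D | k) by explicit enumeration over all 3^n genotype vectors
brute_joint_lik <- function(log10_liks) {
  n <- length(log10_liks)
  grid <- expand.grid(rep(list(0:2), n))
  out <- numeric(2 * n + 1)
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ])
    term <- prod(vapply(seq_len(n), function(i)
      choose(2, g[i]) * 10^log10_liks[[i]]$log10_lik[g[i] + 1], 0))
    out[sum(g) + 1] <- out[sum(g) + 1] + term
  }
  out / choose(2 * n, 0:(2 * n))
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins
brute_fisher2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  probs <- dhyper(max(0, c1 - r2):min(r1, c1), r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# pileup of d reads at BQ30/MQ60, na carrying the alternate, simulator-style
bq30_pileup <- function(d, na, ref = "G", alt = "A") {
  site_pileup("chr1", 500, ref, "t",
              allele = c(rep(ref, d - na), rep(alt, na)),
              base_quality = rep(30, d), mapping_quality = rep(60, d),
              strand = rep_len(c("+", "-"), d),
              tail_dist = rep(49L, d))
}

table2_gl <- list(p1 = gl_from_pl(c(185L, 0L, 236L)),
                  p2 = gl_from_pl(c(12L, 0L, 233L)),
                  p3 = gl_from_pl(c(179L, 0L, 197L)))
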