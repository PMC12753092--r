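# Independent oracles used to check the simulator and the JC correction.
# These deliberately avoid the package's code paths: the simulator is checked
# against the closed-form binomial marginalization of the Poisson
# event-placement process, and the JC inversion against an explicit per-site
# mutation chain.

# Closed-form oracle for the fast-path simulator: conditional on TMRCA the
# number of differing sites is Binomial(L, 3/4*(1 - exp(-8*mu*t/3))).
oracle_sim_ks <- function(ne, mu, t_div, seq_len = 1000, n_loci = 10000) {
  tm <- t_div + stats::rexp(n_loci, rate = 1 / (2 * ne))
  p <- 0.75 * (1 - exp(-8 * mu * tm / 3))
  nd <- stats::rbinom(n_loci, seq_len, p)
  ph <- nd / seq_len
  ph <- ph[ph < 0.75]
  -0.75 * log1p(-4 * ph / 3)
}

# Explicit JC site chain: evolve n sites over a branch of d expected
# substitutions/site (events Poisson(d); each event moves to one of the
# other three bases) and return the realized p-distance.
oracle_jc_p <- function(d, n_sites) {
  k <- stats::rpois(n_sites, d)
  base <- rep(1L, n_sites)
  active <- which(k > 0)
  for (i in active) {
    b <- 1L
    for (j in seq_len(k[i])) b <- sample((1:4)[-b], 1)
    base[i] <- b
  }
  mean(base != 1L)
}

# tiny interleaved pair FASTA writer for reader tests
write_tiny_fasta <- function(records, path) {
  writeLines(unlist(lapply(names(records), function(nm)
    c(paste0(">", nm), records[[nm]]))), path)
}
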