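test_that("configuration validation enforces the model's domain", {
  expect_error(sim_config(ne = 0, mu = 1e-8, t_div = 1e6), "'ne'")
  expect_error(sim_config(ne = 1e4, mu = 0, t_div = 1e6), "'mu'")
  expect_error(sim_config(ne = 1e4, mu = 1e-8, t_div = -1), "'t_div'")
  expect_error(sim_config(1e4, 1e-8, 1e6, bottleneck_fraction = 0),
               "bottleneck_fraction")
  expect_error(sim_config(1e4, 1e-8, 1e6, bottleneck_fraction = 1.5),
               "bottleneck_fraction")
  cfg <- sim_config(1e4, 1e-8, 1e6, bottleneck_fraction = 1)
  expect_s3_class(cfg, "sim_config")
})

test_that("ms-style (theta, t) input converts to native (ne, mu, T) units", {
  cfg <- sim_config_ms(theta = 4 * 5e4 * 1e-8, t = 5, mu = 1e-8)
  expect_equal(cfg$ne, 5e4)
  expect_equal(cfg$t_div, 1e6)
  # round trip: native -> ms -> native
  ne <- 12345; t_div <- 2.5e5
  cfg2 <- sim_config_ms(theta = 4 * ne * 1e-9, t = t_div / (4 * ne), mu = 1e-9)
  expect_equal(cfg2$ne, ne, tolerance = 1e-12)
  expect_equal(cfg2$t_div, t_div, tolerance = 1e-12)
})

test_that("TMRCA draws follow t_div plus an exponential with mean 2*Ne", {
  set.seed(101)
  cfg <- sim_config(ne = 5e4, mu = 1e-8, t_div = 1e6, n_loci = 1e5)
  tm <- sample_tmrca(cfg)
  expect_true(all(tm >= 1e6))
  se <- 2 * 5e4 / sqrt(1e5)
  expect_lt(abs(mean(tm) - 1.1e6), 3 * se)
  # exponential variance (2*Ne)^2
  expect_lt(abs(stats::var(tm) / (4 * 5e4^2) - 1), 0.05)

  # pure ancestral coalescent at t_div = 0
  cfg0 <- sim_config(ne = 500, mu = 1e-8, t_div = 0, n_loci = 1e5)
  tm0 <- sample_tmrca(cfg0)
  expect_true(all(tm0 > 0))
  expect_lt(abs(mean(tm0) - 1000), 3 * 1000 / sqrt(1e5))
})

test_that("fast-path Ks distribution matches coalescent moments and the binomial oracle", {
  cfg <- sim_config(ne = 5e4, mu = 1e-8, t_div = 1e6, n_loci = 1e4, seed = 7)
  ks <- simulate_ks_values(cfg)
  # E[Ks] = 2*mu*(T + 2*Ne)
  se <- sqrt(ks$var_ks / ks$n_loci)
  expect_lt(abs(ks$mean_ks - 0.022), 3 * se)
  # per-locus invariants
  expect_true(all(ks$loci$tmrca >= 1e6))
  expect_true(all(ks$loci$p_dist >= 0 & ks$loci$p_dist < 1))
  ok <- !is.na(ks$loci$ks)
  expect_true(all(ks$loci$ks[ok] >= ks$loci$p_dist[ok]))
  # full distribution against the closed-form binomial oracle
  set.seed(8)
  oracle <- oracle_sim_ks(5e4, 1e-8, 1e6, n_loci = 1e4)
  expect_lt(abs(ks$mean_ks / mean(oracle) - 1), 0.02)
  expect_lt(abs(ks$var_ks / stats::var(oracle) - 1), 0.10)
  expect_gt(stats::wilcox.test(ks$values, oracle)$p.value, 0.01)
})

test_that("at tiny Ne the Ks variance collapses to the finite-site sampling floor", {
  # ne = 5: coalescent spread is negligible; variance is the mutational
  # sampling term, checked against the binomial oracle at the same config
  cfg <- sim_config(ne = 5, mu = 1e-8, t_div = 1e6, n_loci = 2e4, seed = 11)
  ks <- simulate_ks_values(cfg)
  set.seed(12)
  oracle <- oracle_sim_ks(5, 1e-8, 1e6, n_loci = 2e4)
  expect_lt(abs(ks$var_ks / stats::var(oracle) - 1), 0.10)
  # and the coalescent term 16*mu^2*ne^2 is irrelevant here
  expect_gt(ks$var_ks, 100 * 16 * 1e-16 * 25)
})

test_that("identical seeds give byte-identical runs", {
  cfg <- sim_config(ne = 2e4, mu = 1e-8, t_div = 1e5, n_loci = 500, seed = 42)
  a <- simulate_ks_values(cfg)
  b <- simulate_ks_values(cfg)
  expect_identical(a$values, b$values)
  expect_identical(a$loci, b$loci)
  f1 <- tempfile(); f2 <- tempfile()
  write_locus_table(a, f1); write_locus_table(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulation fails when expected divergence saturates the correction", {
  cfg <- sim_config(ne = 1e4, mu = 1e-5, t_div = 1e6, n_loci = 10)
  expect_error(simulate_ks_values(cfg), "saturation")
})

test_that("explicit sequence pairs conserve counts and encode the divergence", {
  cfg <- sim_config(ne = 1e4, mu = 1e-8, t_div = 1e5, n_loci = 50,
                    seq_len = 120, seed = 3)
  pairs <- simulate_sequence_pairs(cfg)
  expect_length(pairs$sequences, 100)
  expect_true(all(Biostrings::width(pairs$sequences) == 120))
  expect_identical(names(pairs$sequences)[1:2], c("locus1_A", "locus1_B"))

  # vanishing mutation rate: pairs are identical
  cfg0 <- sim_config(ne = 10, mu = 1e-15, t_div = 0, n_loci = 20,
                     seq_len = 100, seed = 4)
  p0 <- simulate_sequence_pairs(cfg0)
  a <- as.character(p0$sequences[c(TRUE, FALSE)])
  b <- as.character(p0$sequences[c(FALSE, TRUE)])
  expect_identical(unname(a), unname(b))
})

test_that("sequence path and fast path agree in distribution", {
  cfg <- sim_config(ne = 5e4, mu = 1e-8, t_div = 1e6, n_loci = 3000, seed = 21)
  fa <- tempfile(fileext = ".fa")
  write_fasta_pairs(simulate_sequence_pairs(cfg), fa)
  ks_seq <- read_fasta_pairs(fa)
  cfg2 <- cfg; cfg2$seed <- 22L
  ks_fast <- simulate_ks_values(cfg2)
  expect_gt(stats::wilcox.test(ks_seq$values, ks_fast$values)$p.value, 0.01)
  expect_lt(abs(ks_seq$mean_ks / ks_fast$mean_ks - 1), 0.05)
})

test_that("bottleneck scenario requires the fraction and is branch-length neutral", {
  cfg <- sim_config(ne = 2e4, mu = 1e-8, t_div = 1e5, n_loci = 5000, seed = 31)
  expect_error(simulate_bottleneck_scenario(cfg), "bottleneck_fraction")
  cfg$bottleneck_fraction <- 1.0
  ks_b <- simulate_bottleneck_scenario(cfg)
  cfg2 <- sim_config(ne = 2e4, mu = 1e-8, t_div = 1e5, n_loci = 5000, seed = 32)
  ks_plain <- simulate_ks_values(cfg2)
  # fraction = 1 is a no-op scenario: same distribution as the plain path
  expect_gt(stats::wilcox.test(ks_b$values, ks_plain$values)$p.value, 0.01)
  expect_lt(abs(ks_b$mean_ks / ks_plain$mean_ks - 1), 0.05)
  # reduced fraction leaves branch lengths (hence Ks moments) unchanged:
  # one lineage per daughter cannot coalesce before the split
  cfg3 <- sim_config(ne = 2e4, mu = 1e-8, t_div = 1e5, n_loci = 5000,
                     seed = 33, bottleneck_fraction = 0.1)
  ks_01 <- simulate_bottleneck_scenario(cfg3)
  expect_gt(stats::wilcox.test(ks_01$values, ks_plain$values)$p.value, 0.001)
  expect_lt(abs(ks_01$mean_ks / ks_plain$mean_ks - 1), 0.05)
})
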