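test_that("p-distance counts differing sites over comparable sites only", {
  expect_equal(pairwise_p_distance("ACGT", "ACGT"), list(p_dist = 0, n_sites = 4))
  expect_equal(pairwise_p_distance("ACGT", "ACGA"), list(p_dist = 0.25, n_sites = 4))
  expect_equal(pairwise_p_distance("AC-T", "ACGT"), list(p_dist = 0, n_sites = 3))
  # ambiguity codes are missing data at that site, case-insensitive elsewhere
  expect_equal(pairwise_p_distance("ACNT", "acgt"), list(p_dist = 0, n_sites = 3))
  expect_error(pairwise_p_distance("ACG", "ACGT"), "unequal")
  expect_error(pairwise_p_distance("---", "NNN"), "comparable")
})

test_that("Jukes-Cantor correction matches its closed form and a site-chain oracle", {
  expect_equal(correct_multiple_hits(0), 0)
  # frozen from the closed form -(3/4)ln(1 - 4p/3) at p = 0.1
  expect_equal(correct_multiple_hits(0.1), 0.10732563, tolerance = 1e-7)
  # independent check: evolving sites at d = 0.10733 recovers E[p] = 0.1
  set.seed(5)
  expect_equal(oracle_jc_p(0.10733, 2e5), 0.1, tolerance = 0.005)
  expect_error(correct_multiple_hits(0.75), "saturated")
  expect_error(correct_multiple_hits(-0.01), ">= 0")
})

test_that("correction is monotone, dominates p, and inverts the expected-p map", {
  d <- seq(0, 3, by = 0.01)
  p <- jc_expected_p(d)
  expect_true(all(diff(correct_multiple_hits(p[-length(p)])) > 0))
  expect_true(all(correct_multiple_hits(p) >= p))
  expect_true(all(abs(correct_multiple_hits(p) - d) < 1e-12))
})

test_that("Ks summaries use the arithmetic mean and unbiased variance", {
  ks <- ks_distribution(c(0.01, 0.03))
  expect_equal(ks$mean_ks, 0.02)
  expect_equal(ks$var_ks, 2e-4)
  expect_equal(ks_distribution(rep(0.05, 10))$var_ks, 0)
  expect_error(ks_distribution(0.01), "at least 2")
  expect_error(ks_distribution(c(0.01, NA)), "finite")
  expect_error(ks_distribution(c(0.01, -0.02)), "non-negative")
  # permutation invariance
  set.seed(9)
  v <- stats::runif(100)
  a <- ks_distribution(v); b <- ks_distribution(sample(v))
  expect_equal(a$mean_ks, b$mean_ks)
  expect_equal(a$var_ks, b$var_ks)
})

test_that("simulated large-Ne variance is coalescent-dominated", {
  ks <- simulate_ks_values(sim_config(5e5, 1e-8, 1e6, n_loci = 1e4, seed = 13))
  coal <- 16 * 1e-16 * (5e5)^2
  # the coalescent term dominates the total variance at Ne = 500,000 ...
  expect_gt(coal / ks$var_ks, 0.85)
  # ... and the total matches the binomial-oracle variance
  set.seed(14)
  expect_lt(abs(ks$var_ks / stats::var(oracle_sim_ks(5e5, 1e-8, 1e6)) - 1), 0.10)
})

test_that("Ks tables are read with filtering and informative errors", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("pair\tdS", "p1\t0.01", "p2\t0.02", "p3\t0.03"), tsv)
  ks <- read_ks_table(tsv)
  expect_equal(ks$n_loci, 3)
  expect_equal(ks$mean_ks, 0.02)

  writeLines(c("pair\tdS", "p1\t0.01", "p2\t-1", "p3\t0.03", "p4\tNA",
               "p5\t9.9"), tsv)
  expect_message(ks2 <- read_ks_table(tsv), "dropped 3 of 5")
  expect_equal(ks2$n_loci, 2)
  expect_equal(ks2$dropped, 3L)
  # ceiling is configurable
  expect_message(ks3 <- read_ks_table(tsv, max_ks = 10), "dropped 2 of 5")
  expect_equal(ks3$n_loci, 3)

  expect_error(read_ks_table(tsv, column = "Ks"),
               "available columns: pair, dS")

  csv <- tempfile(fileext = ".csv")
  writeLines(c("pair,dS", "p1,0.04", "p2,0.06"), csv)
  expect_equal(read_ks_table(csv)$mean_ks, 0.05)
})

test_that("FASTA pair reader matches the simulator round trip", {
  cfg <- sim_config(ne = 5e4, mu = 1e-8, t_div = 1e6, n_loci = 1000, seed = 15)
  pairs <- simulate_sequence_pairs(cfg)
  fa <- tempfile(fileext = ".fa"); fb <- tempfile(fileext = ".fa")
  write_fasta_pairs(pairs, fa)
  ks <- read_fasta_pairs(fa)
  expect_equal(ks$n_loci, 1000)
  se <- sqrt(ks$var_ks / ks$n_loci)
  expect_lt(abs(ks$mean_ks - 0.022), 4 * se)
  # two parallel files, record by record
  write_fasta_pairs(pairs, fa, path_b = fb)
  ks2 <- read_fasta_pairs(fa, path_b = fb)
  expect_equal(sort(ks2$values), sort(ks$values))
})

test_that("FASTA pair reader rejects orphans and flags saturated pairs", {
  fa <- tempfile(fileext = ".fa")
  write_tiny_fasta(list(locus1_A = "ACGTACGT", locus1_B = "ACGTACGA",
                        locus2_A = "ACGTACGT"), fa)
  expect_error(read_fasta_pairs(fa), "unpaired records: locus2")

  writeLines(character(0), fa)
  expect_error(read_fasta_pairs(fa), "no FASTA records")

  # one saturated pair among normal ones is excluded with a warning
  write_tiny_fasta(list(locus1_A = "AAAAAAAAAA", locus1_B = "CCCCCCCCGG",
                        locus2_A = "ACGTACGTAC", locus2_B = "ACGTACGTAA",
                        locus3_A = "ACGTACGTAC", locus3_B = "ACGTACGTAC"), fa)
  expect_warning(ks <- read_fasta_pairs(fa), "saturated")
  expect_equal(ks$n_loci, 2)
  expect_equal(ks$dropped, 1L)
})

test_that("Ks distributions serialize to TSV and a JSON summary", {
  ks <- ks_distribution(c(0.01, 0.02, 0.03))
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_ks_distribution(ks, tsv_path = tsv, json_path = js)
  tab <- utils::read.delim(tsv)
  expect_equal(tab$ks, c(0.01, 0.02, 0.03))
  summ <- jsonlite::read_json(js)
  expect_equal(summ$n_loci, 3)
  expect_equal(summ$mean_ks, 0.02)
})
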