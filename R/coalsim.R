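#' Simulation configuration for a two-species ortholog divergence scenario
#'
#' Bundles the parameters of a single coalescent simulation: one lineage is
#' sampled from each of two species that split `t_div` generations ago, and
#' the two lineages coalesce in a panmictic ancestral population of constant
#' (diploid) effective size `ne`. Mutations accumulate at `mu` per site per
#' generation under a Jukes-Cantor model over loci of `seq_len` bp.
#'
#' @param ne Ancestral effective population size (diploid individuals).
#' @param mu Substitution rate per site per generation.
#' @param t_div Species divergence time in generations (>= 0).
#' @param seq_len Locus length in bp (default 1000).
#' @param n_loci Number of ortholog pairs (default 10000).
#' @param seed Optional integer RNG seed; when set, every simulation run from
#'   this config is byte-identical.
#' @param bottleneck_fraction Optional post-divergence size fraction in (0, 1]
#'   for one daughter population; used only by
#'   [simulate_bottleneck_scenario()].
#' @return An object of class `sim_config`.
#' @seealso [sim_config_ms()] for Hudson's (theta, t) parameterization.
#' @export
#' @examples
#' cfg <- sim_config(ne = 5e4, mu = 1e-8, t_div = 1e6, n_loci = 100, seed = 1)
#' cfg
sim_config <- function(ne, mu, t_div, seq_len = 1000, n_loci = 10000,
                       seed = NULL, bottleneck_fraction = NULL) {
  stopifnot(is.numeric(ne), length(ne) == 1, is.finite(ne),
            is.numeric(mu), length(mu) == 1, is.finite(mu),
            is.numeric(t_div), length(t_div) == 1, is.finite(t_div))
  if (ne <= 0) stop("'ne' must be > 0")
  if (mu <= 0) stop("'mu' must be > 0")
  if (t_div < 0) stop("'t_div' must be >= 0")
  if (seq_len < 1) stop("'seq_len' must be >= 1")
  if (n_loci < 1) stop("'n_loci' must be >= 1")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(length(seed) == 1, !is.na(seed))
  }
  if (!is.null(bottleneck_fraction)) {
    stopifnot(is.numeric(bottleneck_fraction), length(bottleneck_fraction) == 1)
    if (bottleneck_fraction <= 0 || bottleneck_fraction > 1)
      stop("'bottleneck_fraction' must be in (0, 1]")
  }
  structure(list(ne = as.numeric(ne), mu = as.numeric(mu),
                 t_div = as.numeric(t_div), seq_len = as.integer(seq_len),
                 n_loci = as.integer(n_loci), seed = seed,
                 bottleneck_fraction = bottleneck_fraction),
            class = "sim_config")
}

#' Build a simulation configuration from Hudson's ms parameterization
#'
#' Converts theta = 4*Ne*mu (per site) and t = T/(4*Ne) into the native
#' (ne, mu, t_div) units.
#'
#' @param theta Per-site population mutation rate, 4*Ne*mu.
#' @param t Divergence time in units of 4*Ne generations.
#' @param mu Substitution rate per site per generation (needed to recover Ne).
#' @inheritParams sim_config
#' @inheritDotParams sim_config seq_len n_loci seed bottleneck_fraction
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config_ms(theta = 4 * 5e4 * 1e-8, t = 5, mu = 1e-8)
#' cfg$ne    # 5e4
#' cfg$t_div # 1e6
sim_config_ms <- function(theta, t, mu, ...) {
  stopifnot(theta > 0, t >= 0, mu > 0)
  ne <- theta / (4 * mu)
  sim_config(ne = ne, mu = mu, t_div = t * 4 * ne, ...)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-species coalescent simulation config\n")
  cat(sprintf("  ne = %g, mu = %g /site/gen, t_div = %g generations\n",
              x$ne, x$mu, x$t_div))
  cat(sprintf("  %d loci x %d bp; seed = %s; bottleneck fraction = %s\n",
              x$n_loci, x$seq_len,
              if (is.null(x$seed)) "none" else x$seed,
              if (is.null(x$bottleneck_fraction)) "none"
              else format(x$bottleneck_fraction)))
  invisible(x)
}

#' Sample per-locus gene divergence times (TMRCA)
#'
#' With one lineage per species, lineages can only coalesce in the ancestral
#' population, so TMRCA = t_div + c where c is exponential with mean 2*ne
#' generations (discrete generations approximated by the continuous
#' exponential).
#'
#' @param config A [sim_config()].
#' @param n Number of draws (defaults to `config$n_loci`).
#' @return Numeric vector of TMRCAs in generations, all >= `t_div`.
#' @export
#' @examples
#' cfg <- sim_config(ne = 500, mu = 1e-8, t_div = 0, n_loci = 1000, seed = 1)
#' mean(sample_tmrca(cfg))  # ~ 2 * 500
sample_tmrca <- function(config, n = config$n_loci) {
  stopifnot(inherits(config, "sim_config"))
  config$t_div + stats::rexp(n, rate = 1 / (2 * config$ne))
}

# Expected Ks beyond which the JC inversion is numerically meaningless for
# finite loci; used as the simulator's saturation guard.
.ks_saturation_bound <- 3

# Place `n_events` substitution events per locus uniformly over `seq_len`
# sites and collapse multiple hits at a site with the Jukes-Cantor k-step
# transition: after k events on the ancestor->A->B path a site differs with
# probability 3/4 * (1 - (-1/3)^k). Returns the per-locus count of differing
# sites.
.collapse_events <- function(n_events, seq_len, n_loci) {
  total <- sum(n_events)
  if (total == 0) return(integer(n_loci))
  locus <- rep.int(seq_len(n_loci), n_events)
  site <- sample.int(seq_len, total, replace = TRUE)
  key <- sort.int((locus - 1) * as.double(seq_len) + site, method = "quick")
  runs <- rle(key)
  k <- runs$lengths
  hit_locus <- as.integer((runs$values - 1) %/% seq_len) + 1L
  p_diff <- 0.75 * (1 - (-1 / 3)^k)
  differs <- stats::runif(length(k)) < p_diff
  tabulate(hit_locus[differs], nbins = n_loci)
}

# Shared tail of the two fast-path simulators: event counts -> Ks distribution
.events_to_ksdist <- function(config, tmrca, n_events) {
  n_diff <- .collapse_events(n_events, config$seq_len, config$n_loci)
  p <- n_diff / config$seq_len
  loci <- data.frame(locus = seq_len(config$n_loci), tmrca = tmrca,
                     n_diff = n_diff, p_dist = p, ks = NA_real_)
  ok <- p < 0.75
  if (any(!ok))
    warning(sprintf("%d locus/loci with saturated p-distance (>= 0.75) dropped",
                    sum(!ok)))
  loci$ks[ok] <- correct_multiple_hits(p[ok])
  ks_distribution(loci$ks[ok], mu_per_gen = config$mu, source = "simulator",
                  loci = loci, dropped = sum(!ok))
}

.check_saturation <- function(config) {
  exp_ks <- 2 * config$mu * (config$t_div + 2 * config$ne)
  if (exp_ks >= .ks_saturation_bound)
    stop(sprintf(paste0("expected divergence (%.3g substitutions/site) reaches ",
                        "the multiple-hit correction's saturation bound (%g); ",
                        "parameters are outside the model's validity"),
                 exp_ks, .ks_saturation_bound))
}

#' Simulate a Ks distribution for one scenario (fast path)
#'
#' For each locus: draws a TMRCA, draws the number of raw substitution events
#' on the two-branch path as Poisson with mean `2*mu*seq_len*tmrca`, places
#' events uniformly over sites, collapses multiple hits at a site under
#' Jukes-Cantor dynamics, and converts the observed p-distance back to Ks via
#' the multiple-hit correction. No explicit sequences are generated.
#'
#' @param config A [sim_config()]. If `config$seed` is set the run is
#'   reproducible bit-for-bit.
#' @return A [ks_distribution()] with a per-locus table (`$loci`: columns
#'   locus, tmrca, n_diff, p_dist, ks).
#' @export
#' @examples
#' cfg <- sim_config(ne = 5e4, mu = 1e-8, t_div = 1e6, n_loci = 500, seed = 1)
#' ks <- simulate_ks_values(cfg)
#' ks$mean_ks  # ~ 2 * mu * (t_div + 2 * ne) = 0.022
simulate_ks_values <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .check_saturation(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  tmrca <- sample_tmrca(config)
  n_events <- stats::rpois(config$n_loci,
                           2 * config$mu * config$seq_len * tmrca)
  .events_to_ksdist(config, tmrca, n_events)
}

#' Simulate a Ks distribution under a post-divergence bottleneck
#'
#' One daughter population is instantaneously reduced to
#' `config$bottleneck_fraction` of the ancestral size right after the split.
#' With a single lineage sampled per species the TMRCA distribution is
#' unchanged (coalescence is only possible in the ancestral population) and
#' the per-generation mutation rate does not depend on population size, but
#' the mutation accumulation is simulated explicitly per branch segment: one
#' Poisson draw for each daughter lineage over `t_div` generations and one
#' for the ancestral two-lineage path. The scenario exists to confirm
#' estimator robustness to post-divergence Ne dynamics.
#'
#' @param config A [sim_config()] with `bottleneck_fraction` set.
#' @return A [ks_distribution()], as from [simulate_ks_values()].
#' @export
simulate_bottleneck_scenario <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$bottleneck_fraction))
    stop("'bottleneck_fraction' must be set in the config for a bottleneck scenario")
  .check_saturation(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  tmrca <- sample_tmrca(config)
  rate_site <- config$mu * config$seq_len
  ev_daughter_a <- stats::rpois(config$n_loci, rate_site * config$t_div)
  ev_daughter_b <- stats::rpois(config$n_loci, rate_site * config$t_div)
  ev_ancestral <- stats::rpois(config$n_loci,
                               2 * rate_site * (tmrca - config$t_div))
  .events_to_ksdist(config, tmrca, ev_daughter_a + ev_daughter_b + ev_ancestral)
}

# JC k-step transition applied to explicit bases: given start bases (1..4) and
# per-site event counts k >= 1, sample final bases. P(stay) = 1/4 + 3/4 *
# (-1/3)^k; otherwise uniform over the three other bases.
.mutate_sites <- function(start, k) {
  stay <- stats::runif(length(k)) < 0.25 + 0.75 * (-1 / 3)^k
  out <- start
  shift <- sample.int(3, sum(!stay), replace = TRUE)
  out[!stay] <- (start[!stay] - 1L + shift) %% 4L + 1L
  out
}

# Mutate an ancestral base matrix (n_loci x seq_len, values 1..4) along one
# branch of `tmrca` generations per locus.
.mutate_branch <- function(bases, mu, tmrca) {
  n_loci <- nrow(bases)
  seq_len_ <- ncol(bases)
  n_events <- stats::rpois(n_loci, mu * seq_len_ * tmrca)
  total <- sum(n_events)
  if (total == 0) return(bases)
  locus <- rep.int(seq_len(n_loci), n_events)
  site <- sample.int(seq_len_, total, replace = TRUE)
  key <- sort.int((locus - 1) * as.double(seq_len_) + site, method = "quick")
  runs <- rle(key)
  idx <- cbind(as.integer((runs$values - 1) %/% seq_len_) + 1L,
               as.integer((runs$values - 1) %% seq_len_) + 1L)
  bases[idx] <- .mutate_sites(bases[idx], runs$lengths)
  bases
}

.BASES <- c("A", "C", "G", "T")

.base_matrix_to_strings <- function(bases) {
  chars <- matrix(.BASES[bases], nrow = nrow(bases))
  do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
}

#' Simulate explicit aligned ortholog sequence pairs
#'
#' For each locus a random ancestral sequence is mutated independently along
#' the two branches (each of length TMRCA generations) under the same
#' Jukes-Cantor dynamics as the fast path. Records are named
#' `locus<i>_A` / `locus<i>_B`.
#'
#' @param config A [sim_config()].
#' @return An object of class `ortholog_pairs`: a list with `sequences`
#'   (a [Biostrings::DNAStringSet] of 2*n_loci interleaved records), `tmrca`
#'   and `config`.
#' @seealso [write_fasta_pairs()], [read_fasta_pairs()]
#' @export
#' @examples
#' cfg <- sim_config(ne = 5e4, mu = 1e-8, t_div = 1e6, n_loci = 5, seed = 1)
#' pairs <- simulate_sequence_pairs(cfg)
#' pairs$sequences
simulate_sequence_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .check_saturation(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  tmrca <- sample_tmrca(config)
  ancestral <- matrix(sample.int(4L, config$n_loci * config$seq_len,
                                 replace = TRUE),
                      nrow = config$n_loci)
  seq_a <- .mutate_branch(ancestral, config$mu, tmrca)
  seq_b <- .mutate_branch(ancestral, config$mu, tmrca)
  strings <- character(2 * config$n_loci)
  strings[c(TRUE, FALSE)] <- .base_matrix_to_strings(seq_a)
  strings[c(FALSE, TRUE)] <- .base_matrix_to_strings(seq_b)
  names(strings) <- paste0("locus", rep(seq_len(config$n_loci), each = 2),
                           c("_A", "_B"))
  structure(list(sequences = Biostrings::DNAStringSet(strings),
                 tmrca = tmrca, config = config),
            class = "ortholog_pairs")
}

#' @export
print.ortholog_pairs <- function(x, ...) {
  cat(sprintf("%d simulated ortholog pairs of %d bp (mean TMRCA %.4g generations)\n",
              x$config$n_loci, x$config$seq_len, mean(x$tmrca)))
  invisible(x)
}

#' Write simulated ortholog pairs to FASTA
#'
#' @param pairs An `ortholog_pairs` object from [simulate_sequence_pairs()].
#' @param path Output FASTA path (single interleaved file with `locus<i>_A` /
#'   `locus<i>_B` records).
#' @param path_b Optional second path; when given, all `_A` records go to
#'   `path` and all `_B` records to `path_b` (paired files, record-by-record).
#' @return Invisibly, the path(s) written.
#' @export
write_fasta_pairs <- function(pairs, path, path_b = NULL) {
  stopifnot(inherits(pairs, "ortholog_pairs"))
  seqs <- pairs$sequences
  if (is.null(path_b)) {
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
  } else {
    Biostrings::writeXStringSet(seqs[c(TRUE, FALSE)], path)
    Biostrings::writeXStringSet(seqs[c(FALSE, TRUE)], path_b)
    invisible(c(path, path_b))
  }
}

#' Write the per-locus simulation table as TSV
#'
#' Columns `locus, tmrca, n_diff, p_dist, ks`, tab-separated with a header;
#' missing Ks (saturated loci) written as ".".
#'
#' @param ks A [ks_distribution()] carrying a `$loci` table (i.e. produced by
#'   the simulator).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_locus_table <- function(ks, path) {
  stopifnot(inherits(ks, "ks_dist"))
  if (is.null(ks$loci)) stop("this Ks distribution has no per-locus table")
  tab <- ks$loci
  tab$ks <- ifelse(is.na(tab$ks), ".", format(tab$ks, digits = 10))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
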