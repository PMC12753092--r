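#' Run the simulator over a (ne, mu, T) grid
#'
#' One Ks distribution per grid cell; returns the summary table used for
#' variance-surface exploration.
#'
#' @param ne_values,mu_values,t_values Grid axes (each non-empty).
#' @param n_loci,seq_len Per-cell simulation size.
#' @param seed Optional master seed for the whole grid run.
#' @param out_dir Optional directory; when given, each cell's per-locus Ks
#'   TSV is written there as `ks_ne<ne>_mu<mu>_T<T>.tsv`.
#' @return data.frame with columns ne, mu, t_div, mean_ks, var_ks, n_loci.
#' @export
run_simulation_grid <- function(ne_values, mu_values, t_values,
                                n_loci = 10000, seq_len = 1000,
                                seed = NULL, out_dir = NULL) {
  if (length(ne_values) == 0 || length(mu_values) == 0 || length(t_values) == 0)
    stop("empty grid: each of ne_values, mu_values, t_values must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(ne = ne_values, mu = mu_values, t_div = t_values)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- sim_config(ne = cells$ne[i], mu = cells$mu[i],
                      t_div = cells$t_div[i], seq_len = seq_len,
                      n_loci = n_loci)
    ks <- simulate_ks_values(cfg)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_ks_distribution(ks, tsv_path = file.path(out_dir,
        sprintf("ks_ne%g_mu%g_T%g.tsv", cells$ne[i], cells$mu[i],
                cells$t_div[i])))
    }
    data.frame(ne = cells$ne[i], mu = cells$mu[i], t_div = cells$t_div[i],
               mean_ks = ks$mean_ks, var_ks = ks$var_ks, n_loci = ks$n_loci)
  })
  do.call(rbind, rows)
}

#' Bottleneck robustness sweep
#'
#' Simulates the post-divergence bottleneck scenarios (one daughter
#' population reduced to the given fractions of the ancestral size), runs the
#' full Ne-corrected dating pipeline on each replicate, and summarizes the
#' relative accuracy RA = (T_hat - T_true)/T_true.
#'
#' @param fractions Post-divergence size fractions (default the three
#'   reduction scenarios 1/2, 1/5, 1/10).
#' @param ne,mu,t_div,n_loci,seq_len Scenario parameters (defaults: the
#'   canonical Ne = 5e4, mu = 1e-8 /site/gen, T = 1e6 generations, 10000
#'   loci of 1000 bp).
#' @param reps Replicates per fraction (default 5).
#' @param models Model store for [predict_ne()].
#' @param seed Optional master seed.
#' @return List with `table` (fraction, rep, var_ks, ne_hat, t_hat, ra) and
#'   `mean_abs_ra`.
#' @export
run_bottleneck_sweep <- function(fractions = c(0.5, 0.2, 0.1),
                                 ne = 5e4, mu = 1e-8, t_div = 1e6,
                                 n_loci = 10000, seq_len = 1000, reps = 5,
                                 models = load_model_store(), seed = NULL) {
  if (length(fractions) == 0) stop("'fractions' must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  store <- .as_model_store(models)
  rows <- lapply(seq_along(fractions), function(i) {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      cfg <- sim_config(ne = ne, mu = mu, t_div = t_div, seq_len = seq_len,
                        n_loci = n_loci, bottleneck_fraction = fractions[i])
      ks <- simulate_bottleneck_scenario(cfg)
      est <- date_divergence(ks, mu, models = store)
      data.frame(fraction = fractions[i], rep = r, var_ks = ks$var_ks,
                 ne_hat = est$ne_used$ne, t_hat = est$t_species_gen,
                 ra = relative_accuracy(est$t_species_gen, t_div))
    }))
  })
  tab <- do.call(rbind, rows)
  list(table = tab, mean_abs_ra = mean(abs(tab$ra)))
}

#' Sequence-length robustness sweep
#'
#' Simulates ortholog pairs at several locus lengths with all other
#' parameters held constant, computes the normalized variance (CV^2 =
#' Var(Ks)/mean(Ks)^2) of each Ks distribution, and reports each length's
#' relative deviation from the mean normalized variance of the stable
#' lengths (L >= `stable_min`). Short loci inflate Var(Ks) through the
#' per-site sampling term, which scales as 1/L, so their normalized variance
#' deviates strongly.
#'
#' @param lengths Locus lengths in bp (default c(500, 1000, 1500, 2000)).
#' @param ne,mu,t_div,n_loci Scenario parameters (defaults as in
#'   [run_bottleneck_sweep()]).
#' @param reps Replicates per length (default 5; the per-length normalized
#'   variance is averaged over replicates).
#' @param stable_min Lengths >= this value form the stable reference set
#'   (default 1000).
#' @param seed Optional master seed.
#' @return List with `table` (length, norm_var, deviation), `reference`
#'   (mean normalized variance over the stable set) and `mean_dev_stable`
#'   (mean deviation of the stable lengths).
#' @export
run_length_sweep <- function(lengths = c(500, 1000, 1500, 2000),
                             ne = 5e4, mu = 1e-8, t_div = 1e6,
                             n_loci = 10000, reps = 5, stable_min = 1000,
                             seed = NULL) {
  if (length(lengths) == 0) stop("'lengths' must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  nv <- vapply(lengths, function(L) {
    mean(vapply(seq_len(reps), function(r) {
      cfg <- sim_config(ne = ne, mu = mu, t_div = t_div, seq_len = L,
                        n_loci = n_loci)
      normalized_var_ks(simulate_ks_values(cfg))
    }, numeric(1)))
  }, numeric(1))
  stable <- lengths >= stable_min
  if (!any(stable)) stop(sprintf("no lengths >= %g in the sweep", stable_min))
  ref <- mean(nv[stable])
  tab <- data.frame(length = lengths, norm_var = nv,
                    deviation = abs(nv - ref) / ref)
  list(table = tab, reference = ref,
       mean_dev_stable = mean(tab$deviation[stable]))
}
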