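#' Convert a per-year substitution rate to a per-generation rate
#'
#' @param mu_per_year Rate per site per year (> 0).
#' @param g Generation time in years per generation (> 0).
#' @return Rate per site per generation, `mu_per_year * g`.
#' @export
#' @examples
#' convert_rate(3.02e-9, 30)  # 9.06e-8
convert_rate <- function(mu_per_year, g) {
  if (!is.numeric(mu_per_year) || any(mu_per_year <= 0))
    stop("'mu_per_year' must be > 0")
  if (!is.numeric(g) || any(g <= 0)) stop("'g' must be > 0")
  mu_per_year * g
}

#' Signed relative accuracy of a divergence-time estimate
#'
#' (t_est - t_true) / t_true.
#'
#' @param t_est Estimated time (generations or years, as long as both match).
#' @param t_true True time (> 0).
#' @return Dimensionless signed relative error.
#' @export
#' @examples
#' relative_accuracy(1.056e6, 1e6)  # 0.056
relative_accuracy <- function(t_est, t_true) {
  if (any(t_true <= 0)) stop("'t_true' must be > 0")
  (t_est - t_true) / t_true
}

#' Correct a mean-Ks divergence time for the 2Ne coalescent bias
#'
#' The mean gene divergence in generations is `mean_ks / (2*mu)`; genes
#' coalesce on average 2Ne generations before the species split, so the
#' species divergence is the gene divergence minus `2*ne`. When the
#' correction exceeds the signal the negative time is reported with a
#' warning, not clamped: the user must see that the Ne correction exceeded
#' the gene divergence.
#'
#' @param ks A [ks_distribution()] (its `mean_ks` must already be
#'   multiple-hit-corrected, as the package's readers and simulator ensure).
#' @param ne An `ne_estimate` from [predict_ne()], or a bare number.
#' @param mu Substitution rate per site per generation (convert per-year
#'   rates first with [convert_rate()]).
#' @param g Optional generation time (years/generation) to also report times
#'   in years.
#' @return An object of class `divergence_estimate` with fields
#'   `t_gene_gen`, `t_species_gen`, `dt_gen` (= 2*ne), `t_species_years`,
#'   `t_uncorrected_years`, `g`, `ne_used`, `warnings`.
#' @export
#' @examples
#' ks <- ks_distribution(c(0.021, 0.023))  # mean 0.022
#' est <- correct_divergence(ks, ne = 5e4, mu = 1e-8)
#' est$t_species_gen  # 1e6
correct_divergence <- function(ks, ne, mu, g = NULL) {
  stopifnot(inherits(ks, "ks_dist"))
  if (!is.numeric(mu) || mu <= 0) stop("'mu' must be > 0")
  if (is.numeric(ne))
    ne <- structure(list(ne = ne, regime = "fixed", var_ks_used = ks$var_ks,
                         mu_used = mu, model_id = NA_character_),
                    class = "ne_estimate")
  stopifnot(inherits(ne, "ne_estimate"))
  if (!is.null(g) && g <= 0) stop("'g' must be > 0")
  t_gene <- ks$mean_ks / (2 * mu)
  dt <- 2 * ne$ne
  t_species <- t_gene - dt
  warnings <- character(0)
  if (t_species < 0) {
    warnings <- "negative corrected time: 2Ne correction exceeds the mean gene divergence"
    warning(warnings)
  }
  structure(list(t_gene_gen = t_gene, t_species_gen = t_species, dt_gen = dt,
                 t_species_years = if (is.null(g)) NA_real_ else t_species * g,
                 t_uncorrected_years = if (is.null(g)) NA_real_ else t_gene * g,
                 g = if (is.null(g)) NA_real_ else g,
                 mean_ks = ks$mean_ks, var_ks = ks$var_ks, n_loci = ks$n_loci,
                 mu_per_gen = mu, ne_used = ne, warnings = warnings),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat("Species divergence estimate\n")
  cat(sprintf("  mean Ks = %.6g over %d loci (Var = %.4g)\n",
              x$mean_ks, x$n_loci, x$var_ks))
  cat(sprintf("  gene divergence:    %.4g generations (uncorrected date)\n",
              x$t_gene_gen))
  cat(sprintf("  ancestral Ne:       %.4g (%s regime); correction 2Ne = %.4g\n",
              x$ne_used$ne, x$ne_used$regime, x$dt_gen))
  cat(sprintf("  species divergence: %.4g generations\n", x$t_species_gen))
  if (!is.na(x$g))
    cat(sprintf("  in years (g = %g):  %.4g (uncorrected %.4g)\n",
                x$g, x$t_species_years, x$t_uncorrected_years))
  for (w in x$warnings) cat("  WARNING:", w, "\n")
  invisible(x)
}

#' One-call dating pipeline: Ks distribution to corrected divergence time
#'
#' Estimates the ancestral Ne from Var(Ks) via [predict_ne()] and applies the
#' 2Ne correction via [correct_divergence()]. When the rate is given per
#' year, it is first converted with the generation time (the estimated Ne
#' then depends on g, since the model works in per-generation units).
#'
#' @param ks A [ks_distribution()].
#' @param mu Substitution rate; per generation by default.
#' @param mu_units "generation" (default) or "year".
#' @param g Generation time in years; required when `mu_units = "year"`,
#'   optional otherwise (adds year-scaled outputs).
#' @param models Model store for [predict_ne()] (default: bundled store).
#' @return A `divergence_estimate`.
#' @export
date_divergence <- function(ks, mu, mu_units = c("generation", "year"),
                            g = NULL, models = load_model_store()) {
  mu_units <- match.arg(mu_units)
  if (mu_units == "year") {
    if (is.null(g)) stop("a generation time 'g' is required when mu is per year")
    mu <- convert_rate(mu, g)
  }
  ne <- predict_ne(ks$var_ks, mu, models = models)
  correct_divergence(ks, ne, mu, g = g)
}

#' Write a divergence report as JSON
#'
#' @param est A `divergence_estimate`.
#' @param path Output path.
#' @param mu_input Optionally, the rate exactly as the user supplied it
#'   (e.g. per year), echoed alongside the per-generation rate.
#' @return Invisibly, `path`.
#' @export
write_divergence_report <- function(est, path, mu_input = NULL) {
  stopifnot(inherits(est, "divergence_estimate"))
  payload <- list(mean_ks = est$mean_ks, var_ks = est$var_ks,
                  n_loci = est$n_loci,
                  mu_input = if (is.null(mu_input)) est$mu_per_gen else mu_input,
                  mu_per_gen = est$mu_per_gen,
                  g = est$g,
                  ne = est$ne_used$ne, ne_regime = est$ne_used$regime,
                  t_gene_gen = est$t_gene_gen,
                  t_species_gen = est$t_species_gen,
                  t_species_years = est$t_species_years,
                  t_uncorrected_years = est$t_uncorrected_years,
                  warnings = est$warnings)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
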