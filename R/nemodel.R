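#' Canonical substitution-rate categories
#'
#' 23 log-spaced rates spanning 1e-10 to 1e-7 per site per generation, the
#' range of empirically reported neutral mutation rates across eukaryotes.
#' Variance-to-Ne models are trained per category.
#'
#' @return Numeric vector of length 23.
#' @export
mu_categories <- function() 10^seq(-10, -7, length.out = 23)

#' Match a substitution rate to the nearest category
#'
#' @param mu Rate per site per generation.
#' @param categories Candidate rates (default [mu_categories()]).
#' @param warn_gap Warn when the relative gap to the nearest category exceeds
#'   this fraction (default 0.25). Within-category rate variation has only a
#'   minor influence on the variance-Ne relationship.
#' @return The nearest category value.
#' @export
match_mu_category <- function(mu, categories = mu_categories(),
                              warn_gap = 0.25) {
  stopifnot(mu > 0, length(categories) >= 1)
  nearest <- categories[which.min(abs(log(categories) - log(mu)))]
  gap <- abs(mu - nearest) / mu
  if (gap > warn_gap)
    warning(sprintf("mu = %g is %.0f%% away from the nearest category (%g)",
                    mu, 100 * gap, nearest))
  nearest
}

# Regime switch: above this predicted Ne the coalescent variance dominates
# the mutational sampling variance and the closed-form estimator is used.
.ne_regime_threshold <- 450000

#' Analytic coalescent estimator of ancestral Ne
#'
#' Under the coalescent, SD(TMRCA) = 2*Ne generations, so
#' Var(Ks) = 16*mu^2*Ne^2 when the coalescent variance dominates; inverting
#' gives ne = sqrt(var_ks) / (4*mu). Accurate only for large Ne (the package
#' switches to this form when the model prediction exceeds 450,000).
#'
#' @param var_ks Variance of the Ks distribution (>= 0).
#' @param mu Substitution rate per site per generation (> 0).
#' @return Estimated Ne.
#' @export
#' @examples
#' estimate_ne_analytic(4e-4, 1e-8)  # 500000
estimate_ne_analytic <- function(var_ks, mu) {
  if (!is.numeric(mu) || any(mu <= 0)) stop("'mu' must be > 0")
  if (any(var_ks < 0)) stop("'var_ks' must be >= 0")
  sqrt(var_ks) / (4 * mu)
}

#' Train a variance-to-Ne model for one substitution-rate category
#'
#' Simulates a Ks distribution for every (ne, T) cell of the training grid,
#' fits a smooth curve Ne ~ s(log10 Var(Ks)) through the pooled cloud with
#' [mgcv::gam()] (divergence times are pooled: the trained curve is a single
#' smooth function of the variance), and freezes the fit as a dense monotone
#' prediction grid.
#'
#' @param mu Substitution rate (per site per generation) of this category.
#' @param ne_values Training Ne values; must span \[500, 500000\] with at
#'   least 10 distinct values. Default: 23 log-spaced values.
#' @param t_values Divergence times (generations) pooled in training;
#'   default c(1e4, 1e5, 1e6).
#' @param n_loci,seq_len Per-cell simulation size; defaults 10000 loci of
#'   1000 bp.
#' @param seed Optional integer seed; identical seeds give byte-identical
#'   models.
#' @param grid_size Number of frozen prediction-grid points (default 1000).
#' @return An object of class `ks_var_model`: list with `mu`, `grid`
#'   (data.frame `var_ks`, `ne`, strictly increasing in `var_ks`,
#'   non-decreasing in `ne`), `train_meta`, and `fit_r2` (the smoother's
#'   coefficient of determination on the raw-Ne response scale).
#' @export
train_variance_model <- function(mu,
                                 ne_values = 10^seq(log10(500), log10(5e5),
                                                    length.out = 23),
                                 t_values = c(1e4, 1e5, 1e6),
                                 n_loci = 10000, seq_len = 1000,
                                 seed = NULL, grid_size = 1000) {
  stopifnot(mu > 0, length(t_values) >= 1)
  ne_values <- sort(unique(ne_values))
  if (length(ne_values) < 10)
    stop("need at least 10 distinct training Ne values")
  if (min(ne_values) > 500 * 1.001 || max(ne_values) < 5e5 / 1.001)
    stop("training Ne values must span [500, 500000]")
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(ne = ne_values, t_div = t_values)
  cells$var_ks <- mapply(function(ne, t_div) {
    simulate_ks_values(sim_config(ne = ne, mu = mu, t_div = t_div,
                                  seq_len = seq_len, n_loci = n_loci))$var_ks
  }, cells$ne, cells$t_div)
  fit <- mgcv::gam(ne ~ s(log10(var_ks)), data = cells)
  fit_r2 <- summary(fit)$r.sq
  var_grid <- 10^seq(log10(min(cells$var_ks)), log10(max(cells$var_ks)),
                     length.out = grid_size)
  pred <- as.numeric(stats::predict(fit, data.frame(var_ks = var_grid)))
  dips <- -min(0, min(diff(pred)))
  if (dips > 0.05 * diff(range(pred)))
    stop("pooled variance-Ne relationship is non-monotone after smoothing; ",
         "increase n_loci or the grid density")
  pred <- pmax(cummax(pred), 1)  # monotone projection, Ne > 0
  structure(list(mu = mu,
                 grid = data.frame(var_ks = var_grid, ne = pred),
                 train_meta = list(ne_range = range(ne_values),
                                   n_ne = length(ne_values),
                                   t_values = t_values,
                                   n_loci = n_loci, seq_len = seq_len,
                                   seed = seed),
                 fit_r2 = fit_r2,
                 training = cells),
            class = "ks_var_model")
}

#' @export
print.ks_var_model <- function(x, ...) {
  cat(sprintf("Variance-to-Ne model for mu = %g /site/gen\n", x$mu))
  cat(sprintf("  trained on Ne in [%g, %g] (%d values) x T in {%s}, %d loci x %d bp\n",
              x$train_meta$ne_range[1], x$train_meta$ne_range[2],
              x$train_meta$n_ne,
              paste(format(x$train_meta$t_values), collapse = ", "),
              x$train_meta$n_loci, x$train_meta$seq_len))
  cat(sprintf("  fit R^2 = %.4f; grid of %d points, Var(Ks) in [%.3g, %.3g]\n",
              x$fit_r2, nrow(x$grid), min(x$grid$var_ks), max(x$grid$var_ks)))
  invisible(x)
}

#' Persist a variance-to-Ne model as JSON
#'
#' Schema: `{mu, grid: [[var, ne], ...], train_meta, fit_r2}`. The training
#' cloud itself is not persisted; the frozen grid is the portable model.
#'
#' @param model A `ks_var_model`.
#' @param path Output path (conventionally `mu-<rate>.json` in a model-store
#'   directory).
#' @return Invisibly, `path`.
#' @export
write_variance_model <- function(model, path) {
  stopifnot(inherits(model, "ks_var_model"))
  payload <- list(mu = model$mu,
                  grid = unname(lapply(seq_len(nrow(model$grid)), function(i)
                    c(model$grid$var_ks[i], model$grid$ne[i]))),
                  train_meta = model$train_meta,
                  fit_r2 = model$fit_r2)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a persisted variance-to-Ne model
#'
#' @param path JSON file written by [write_variance_model()].
#' @return A `ks_var_model`.
#' @export
read_variance_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- as.data.frame(raw$grid)
  names(grid) <- c("var_ks", "ne")
  meta <- raw$train_meta
  meta$ne_range <- as.numeric(meta$ne_range)
  meta$t_values <- as.numeric(meta$t_values)
  structure(list(mu = raw$mu, grid = grid, train_meta = meta,
                 fit_r2 = raw$fit_r2),
            class = "ks_var_model")
}

#' Load a directory of per-category models as a model store
#'
#' @param dir Directory containing `*.json` model files. Defaults to the
#'   pre-trained bundle shipped with the package.
#' @return A list of `ks_var_model` objects (class `ks_model_store`).
#' @export
load_model_store <- function(dir = system.file("extdata", "models",
                                               package = "ksdate")) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0) stop(sprintf("no model files (*.json) in '%s'", dir))
  models <- lapply(files, read_variance_model)
  names(models) <- vapply(models, function(m) format(m$mu, digits = 8),
                          character(1))
  structure(models, class = "ks_model_store")
}

#' Train and persist models for several rate categories
#'
#' @param mus Rates to train (default the two bundled categories).
#' @param dir Output directory (created if needed).
#' @param seed Optional master seed; per-category seeds are derived from it.
#' @inheritDotParams train_variance_model ne_values t_values n_loci seq_len grid_size
#' @return Invisibly, the paths written.
#' @export
train_model_store <- function(mus, dir, seed = NULL, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(mus)) {
    m <- train_variance_model(mus[i],
                              seed = if (is.null(seed)) NULL else seed + i - 1,
                              ...)
    p <- file.path(dir, sprintf("mu-%.3e.json", mus[i]))
    write_variance_model(m, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

.as_model_store <- function(models) {
  if (inherits(models, "ks_var_model")) {
    out <- list(models)
    names(out) <- format(models$mu, digits = 8)
    return(out)
  }
  if (is.character(models)) return(load_model_store(models))
  if (inherits(models, "ks_model_store") || is.list(models)) return(models)
  stop("'models' must be a ks_var_model, a model store, or a directory path")
}

#' Estimate ancestral Ne from a Ks-distribution variance
#'
#' Interpolates Ne from Var(Ks) on the frozen monotone grid of the model for
#' the nearest substitution-rate category (monotone cubic interpolation in
#' log-log space). When the interpolated value exceeds 450,000 -- the regime
#' in which the coalescent variance dominates the mutational sampling
#' variance -- the estimate is recomputed with the closed-form
#' [estimate_ne_analytic()] and flagged `regime = "analytic"`. Variances
#' below the trained range are refused (no extrapolation); variances above
#' it belong to the analytic regime by construction and are handled by the
#' closed form.
#'
#' @param var_ks Variance of the (multiple-hit-corrected) Ks distribution.
#' @param mu Substitution rate per site per generation.
#' @param models A `ks_var_model`, a model store from [load_model_store()],
#'   or a model-store directory path. Defaults to the bundled pre-trained
#'   store.
#' @param mu_tol Maximum relative gap between `mu` and the nearest available
#'   category (default 0.25); beyond it an error names the nearest
#'   categories.
#' @return An object of class `ne_estimate`: list with `ne`, `regime`
#'   ("trained-curve" or "analytic"), `var_ks_used`, `mu_used`, `model_id`.
#' @export
#' @examples
#' \dontrun{
#' predict_ne(4e-4, 1e-8)  # analytic regime, ne = 500000
#' }
predict_ne <- function(var_ks, mu, models = load_model_store(),
                       mu_tol = 0.25) {
  stopifnot(is.numeric(var_ks), length(var_ks) == 1, var_ks >= 0)
  if (mu <= 0) stop("'mu' must be > 0")
  store <- .as_model_store(models)
  mus <- vapply(store, function(m) m$mu, numeric(1))
  pick <- which.min(abs(log(mus) - log(mu)))
  gap <- abs(mus[pick] - mu) / mu
  if (gap > mu_tol)
    stop(sprintf("no model within %.0f%% of mu = %g; nearest categories: %s",
                 100 * mu_tol, mu,
                 paste(format(sort(mus)[seq_len(min(3, length(mus)))],
                              digits = 3), collapse = ", ")))
  model <- store[[pick]]
  rng <- range(model$grid$var_ks)
  if (var_ks < rng[1])
    stop(sprintf("var_ks = %g below the trained range [%.4g, %.4g] for mu = %g; no extrapolation",
                 var_ks, rng[1], rng[2], model$mu))
  if (var_ks > rng[2]) {
    # beyond the trained cloud the curve is not needed: large variances are
    # the analytic (coalescent-dominated) regime by construction
    ne_hat <- estimate_ne_analytic(var_ks, mu)
    if (ne_hat <= .ne_regime_threshold)
      stop(sprintf("var_ks = %g above the trained range [%.4g, %.4g] for mu = %g but below the analytic regime; no extrapolation",
                   var_ks, rng[1], rng[2], model$mu))
    regime <- "analytic"
  } else {
    interp <- stats::splinefun(log(model$grid$var_ks), log(model$grid$ne),
                               method = "monoH.FC")
    ne_hat <- exp(interp(log(var_ks)))
    regime <- "trained-curve"
    if (ne_hat > .ne_regime_threshold) {
      ne_hat <- estimate_ne_analytic(var_ks, mu)
      regime <- "analytic"
    }
  }
  structure(list(ne = ne_hat, regime = regime, var_ks_used = var_ks,
                 mu_used = mu,
                 model_id = if (regime == "trained-curve")
                   sprintf("mu-%.3e", model$mu) else NA_character_),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ancestral Ne estimate: %.4g (%s regime)\n", x$ne, x$regime))
  cat(sprintf("  from Var(Ks) = %.4g at mu = %g /site/gen\n",
              x$var_ks_used, x$mu_used))
  invisible(x)
}
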