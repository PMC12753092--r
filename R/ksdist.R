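#' Pairwise p-distance between two aligned sequences
#'
#' Proportion of differing sites among comparable sites. Sites where either
#' sequence carries a gap (`-`) or an ambiguity code (anything other than
#' A, C, G, T; case-insensitive) are excluded from both numerator and
#' denominator.
#'
#' @param seq_a,seq_b Aligned nucleotide sequences of equal length (character
#'   scalars or anything coercible via `as.character`).
#' @return A list with `p_dist` (proportion) and `n_sites` (comparable sites).
#' @export
#' @examples
#' pairwise_p_distance("ACGT", "ACGA")  # 0.25 over 4 sites
#' pairwise_p_distance("AC-T", "ACGT")  # 0 over 3 sites
pairwise_p_distance <- function(seq_a, seq_b) {
  a <- charToRaw(toupper(as.character(seq_a)))
  b <- charToRaw(toupper(as.character(seq_b)))
  if (length(a) != length(b))
    stop(sprintf("sequences have unequal lengths (%d vs %d)",
                 length(a), length(b)))
  acgt <- charToRaw("ACGT")
  comparable <- (a %in% acgt) & (b %in% acgt)
  n <- sum(comparable)
  if (n == 0) stop("no comparable (unambiguous, ungapped) sites")
  list(p_dist = sum(a[comparable] != b[comparable]) / n, n_sites = n)
}

#' Jukes-Cantor multiple-hit correction
#'
#' Converts an observed proportion of differing sites into the expected
#' number of substitutions per site, d = -(3/4) * ln(1 - 4p/3). Monotone
#' increasing and always >= p.
#'
#' @param p Observed p-distance(s), each in \[0, 3/4).
#' @return Corrected distance(s) in substitutions per site.
#' @seealso [jc_expected_p()], its exact inverse.
#' @export
#' @examples
#' correct_multiple_hits(0.1)  # 0.10733
correct_multiple_hits <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p))) stop("'p' must be finite numeric")
  if (any(p < 0)) stop("'p' must be >= 0")
  if (any(p >= 0.75))
    stop("p-distance >= 3/4: saturated, distance not estimable under Jukes-Cantor")
  -0.75 * log1p(-4 * p / 3)
}

#' Expected p-distance under Jukes-Cantor at a given distance
#'
#' p(d) = (3/4) * (1 - exp(-4d/3)); the exact inverse of
#' [correct_multiple_hits()].
#'
#' @param d Distance(s) in substitutions per site (>= 0).
#' @return Expected proportion(s) of differing sites.
#' @export
jc_expected_p <- function(d) {
  if (any(d < 0)) stop("'d' must be >= 0")
  0.75 * (1 - exp(-4 * d / 3))
}

#' Summarize per-locus Ks values into a Ks distribution
#'
#' @param values Numeric vector of per-locus Ks values (substitutions/site);
#'   at least 2 finite, non-negative values.
#' @param mu_per_gen Optional substitution rate tag (per site per generation).
#' @param source One of "simulator", "fasta", "table".
#' @param loci Optional per-locus data.frame (kept as `$loci`).
#' @param dropped Number of loci dropped upstream (saturation/filtering).
#' @return An object of class `ks_dist` with fields `values`, `n_loci`,
#'   `mean_ks` (arithmetic mean), `var_ks` (unbiased, n-1 denominator),
#'   `mu_per_gen`, `source`, `dropped`.
#' @export
#' @examples
#' ks_distribution(c(0.01, 0.03))  # mean 0.02, var 2e-4
ks_distribution <- function(values, mu_per_gen = NULL,
                            source = c("table", "simulator", "fasta"),
                            loci = NULL, dropped = 0L) {
  source <- match.arg(source)
  values <- as.numeric(values)
  if (length(values) < 2 || any(!is.finite(values)))
    stop("need at least 2 finite Ks values")
  if (any(values < 0)) stop("Ks values must be non-negative")
  structure(list(values = values, n_loci = length(values),
                 mean_ks = mean(values), var_ks = stats::var(values),
                 mu_per_gen = mu_per_gen, source = source,
                 loci = loci, dropped = as.integer(dropped)),
            class = "ks_dist")
}

#' @export
print.ks_dist <- function(x, ...) {
  cat(sprintf("Ks distribution (%s): %d loci\n", x$source, x$n_loci))
  cat(sprintf("  mean Ks = %.6g, var Ks = %.6g, normalized var (CV^2) = %.4g\n",
              x$mean_ks, x$var_ks, normalized_var_ks(x)))
  if (x$dropped > 0) cat(sprintf("  %d loci dropped\n", x$dropped))
  invisible(x)
}

#' Normalized variance (squared coefficient of variation) of a Ks distribution
#'
#' Var(Ks) / mean(Ks)^2, the dimensionless spread used to compare Ks
#' distributions across sequence lengths and rate scales.
#'
#' @param ks A [ks_distribution()].
#' @return A scalar.
#' @export
normalized_var_ks <- function(ks) {
  stopifnot(inherits(ks, "ks_dist"))
  ks$var_ks / ks$mean_ks^2
}

#' Read a per-locus Ks table (e.g. a wgd-style output)
#'
#' Loads finite, non-negative Ks values from a delimited file, dropping rows
#' that are missing, negative, or above a saturation ceiling; the number of
#' dropped rows is reported via `message()`.
#'
#' @param path TSV (default) or CSV file with a header.
#' @param column Name of the Ks column (default "dS", the wgd convention).
#' @param max_ks Saturation ceiling; values above it are dropped (default 5).
#' @param sep Field separator; guessed from the file extension when NULL
#'   ("," for .csv, tab otherwise).
#' @return A [ks_distribution()] with `source = "table"`.
#' @export
read_ks_table <- function(path, column = "dS", max_ks = 5, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!column %in% names(tab))
    stop(sprintf("column '%s' not found; available columns: %s",
                 column, paste(names(tab), collapse = ", ")))
  raw <- suppressWarnings(as.numeric(tab[[column]]))
  keep <- is.finite(raw) & raw >= 0 & raw <= max_ks
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("read_ks_table: dropped %d of %d rows (missing, negative, or Ks > %g)",
                    n_drop, length(raw), max_ks))
  if (sum(keep) < 2) stop("fewer than 2 usable Ks values in table")
  ks_distribution(raw[keep], source = "table", dropped = n_drop)
}

# Split an interleaved pair FASTA into matched _A/_B record indices.
.match_pair_names <- function(nm) {
  is_a <- grepl("_A$", nm)
  is_b <- grepl("_B$", nm)
  if (any(!is_a & !is_b))
    stop(sprintf("records without _A/_B pair suffix: %s",
                 paste(utils::head(nm[!is_a & !is_b], 5), collapse = ", ")))
  stem_a <- sub("_A$", "", nm[is_a])
  stem_b <- sub("_B$", "", nm[is_b])
  orphans <- c(setdiff(stem_a, stem_b), setdiff(stem_b, stem_a))
  if (length(orphans) > 0)
    stop(sprintf("unpaired records: %s",
                 paste(utils::head(orphans, 10), collapse = ", ")))
  list(a = which(is_a)[order(stem_a)], b = which(is_b)[order(stem_b)])
}

#' Compute a Ks distribution from aligned FASTA ortholog pairs
#'
#' Each pair is reduced to a p-distance ([pairwise_p_distance()]), corrected
#' for multiple hits ([correct_multiple_hits()]), and the resulting per-pair
#' Ks values are summarized. Pairs with a saturated p-distance (>= 3/4) are
#' excluded with a warning and counted in `$dropped`.
#'
#' @param path FASTA file (gzip accepted). Either a single file with the
#'   `locus<i>_A` / `locus<i>_B` naming convention, or the "A" file of a
#'   record-by-record pair of files.
#' @param path_b Optional second FASTA; when given, records are paired
#'   record-by-record between the two files.
#' @param mu_per_gen Optional rate tag carried into the result.
#' @return A [ks_distribution()] with `source = "fasta"`.
#' @export
read_fasta_pairs <- function(path, path_b = NULL, mu_per_gen = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop(sprintf("no FASTA records in '%s'", path))
  if (is.null(path_b)) {
    idx <- .match_pair_names(names(seqs))
    set_a <- seqs[idx$a]
    set_b <- seqs[idx$b]
  } else {
    set_a <- seqs
    set_b <- Biostrings::readDNAStringSet(path_b)
    if (length(set_b) == 0) stop(sprintf("no FASTA records in '%s'", path_b))
    if (length(set_a) != length(set_b))
      stop(sprintf("paired files differ in record count (%d vs %d)",
                   length(set_a), length(set_b)))
  }
  chr_a <- as.character(set_a)
  chr_b <- as.character(set_b)
  p <- vapply(seq_along(chr_a),
              function(i) pairwise_p_distance(chr_a[i], chr_b[i])$p_dist,
              numeric(1))
  saturated <- p >= 0.75
  if (any(saturated))
    warning(sprintf("%d pair(s) with saturated p-distance excluded",
                    sum(saturated)))
  if (sum(!saturated) < 2) stop("fewer than 2 usable pairs")
  ks_distribution(correct_multiple_hits(p[!saturated]),
                  mu_per_gen = mu_per_gen, source = "fasta",
                  dropped = sum(saturated))
}

#' Write a Ks distribution as TSV plus a JSON summary
#'
#' @param ks A [ks_distribution()].
#' @param tsv_path Path for the per-locus TSV (`locus, ks`); NULL to skip.
#' @param json_path Path for the JSON summary
#'   (`{n_loci, mean_ks, var_ks, dropped}`); NULL to skip.
#' @return Invisibly, the paths written.
#' @export
write_ks_distribution <- function(ks, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(ks, "ks_dist"))
  if (!is.null(tsv_path))
    utils::write.table(data.frame(locus = seq_along(ks$values), ks = ks$values),
                       tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(n_loci = ks$n_loci, mean_ks = ks$mean_ks,
                              var_ks = ks$var_ks, dropped = ks$dropped),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv_path, json_path))
}
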