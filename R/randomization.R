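#' Randomize genes by shuffling codons
#'
#' Two null models that destroy, in different ways, any coupling
#' between codon choice and position while conserving each gene's
#' codon multiset exactly:
#'
#' * `shuffle_synonymous()`: within each gene, the codons encoding
#'   each amino acid are randomly permuted among that amino acid's
#'   positions.  Codon usage and the amino-acid sequence are
#'   maintained; only the synonymous codon ordering is lost.
#' * `shuffle_codons()`: within each gene, all codon positions are
#'   permuted uniformly at random.  Codon usage is maintained but the
#'   amino-acid sequence changes (amino acid shuffling).
#'
#' Both operate on the sequences as given (normally trimmed, since all
#' statistics are computed on trimmed sequences).  Genes are processed
#' in sorted-id order from the current RNG state, so results are
#' reproducible with `set.seed()` and independent of input order.
#'
#' @param x a `cds_set`.
#' @return A `cds_set` with shuffled sequences (same ids, same trim
#'   state).
#' @export
shuffle_synonymous <- function(x) {
  stopifnot(inherits(x, "cds_set"))
  ord <- order(x$id)
  seqs <- x$seq
  for (i in ord) {
    cods <- codons_of(seqs[i])
    aa <- translate_codons(cods)
    for (idx in split(seq_along(cods), aa)) {
      if (length(idx) > 1L)
        cods[idx] <- cods[idx][sample.int(length(idx))]
    }
    seqs[i] <- paste(cods, collapse = "")
  }
  cds_set(x$id, seqs, trimmed = x$trimmed, offset_nt = x$offset_nt)
}

#' @rdname shuffle_synonymous
#' @export
shuffle_codons <- function(x) {
  stopifnot(inherits(x, "cds_set"))
  ord <- order(x$id)
  seqs <- x$seq
  for (i in ord) {
    cods <- codons_of(seqs[i])
    if (length(cods) > 1L)
      cods <- cods[sample.int(length(cods))]
    seqs[i] <- paste(cods, collapse = "")
  }
  cds_set(x$id, seqs, trimmed = x$trimmed, offset_nt = x$offset_nt)
}

#' Null distribution of the trade-off score
#'
#' Generates `n_genomes` randomized genomes under the chosen shuffling
#' method, recomputes the structure profile of every shuffled gene
#' with the same folding engine, window and thresholds as the observed
#' analysis, and records the genome-wide trade-off score of each
#' replicate.  Only predicted (MFE) structure can be recomputed for
#' shuffled sequences, so `rule$kind` must be `"mfe"`: experimental
#' PARS scores belong to the original sequences.
#'
#' @param x a trimmed `cds_set` (the observed genome).
#' @param table a `time_table`.
#' @param rule an MFE [threshold_rule()].
#' @param method `"synonymous_shuffle"` or `"codon_shuffle"`.
#' @param n_genomes number of randomized genomes (default 100).
#' @param seed integer seed; the whole run is reproducible given it.
#' @param engine folding engine, see [mfe_engine()].
#' @param window_nt sliding window width.
#' @param pool pooling mode passed to [genome_tradeoff()].
#' @return An object of class `null_distribution`: list with `method`,
#'   `values` (one trade-off score per replicate; `NA` when a
#'   randomized genome has no region of one class, which happens
#'   routinely under codon shuffling when structure is carried by
#'   amino-acid placement), `n_genomes`, `seed`.
#' @export
null_distribution <- function(x, table, rule,
                              method = c("synonymous_shuffle", "codon_shuffle"),
                              n_genomes = 100L, seed = 1L,
                              engine = mfe_engine(), window_nt = 101L,
                              pool = "codon") {
  method <- match.arg(method)
  if (rule$kind != "mfe")
    stop("null models need recomputable structure: use an MFE rule ",
         "(experimental PARS scores cannot be recomputed for shuffled sequences)")
  shuffler <- switch(method, synonymous_shuffle = shuffle_synonymous,
                     codon_shuffle = shuffle_codons)
  values <- numeric(n_genomes)
  if (n_genomes > 0L) {
    set.seed(seed)
    for (r in seq_len(n_genomes)) {
      xs <- shuffler(x)
      profs <- sliding_window_mfe(xs, window_nt = window_nt, engine = engine)
      res <- genome_tradeoff(xs, profs, table, rule, pool = pool)
      values[r] <- res$tradeoff_score
    }
  }
  structure(list(method = method, values = values,
                 n_genomes = as.integer(n_genomes), seed = as.integer(seed)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution (%s): %d genomes, seed %d\n",
              x$method, x$n_genomes, x$seed))
  ok <- x$values[!is.na(x$values)]
  if (length(ok))
    cat(sprintf("  trade-off score median %.2f [%.2f, %.2f] a.u. (%d/%d defined)\n",
                stats::median(ok),
                stats::quantile(ok, 0.025, names = FALSE),
                stats::quantile(ok, 0.975, names = FALSE),
                length(ok), x$n_genomes))
  else if (x$n_genomes > 0)
    cat("  no replicate retained both structure classes (all scores NA)\n")
  invisible(x)
}

#' Compare an observed trade-off score with a null distribution
#'
#' One-sample Wilcoxon signed-rank test of the null replicate scores
#' against the observed score as hypothesized center, two-sided.  If
#' every null value equals the observed score the test is degenerate
#' and an error of class `"degenerate_test"` is signalled.
#'
#' @param observed observed trade-off score (a.u.).
#' @param null a `null_distribution`.
#' @return A list with `p_value`, `observed`, `null_median`,
#'   `null_ci` (2.5 and 97.5 percentiles of the null), and the number
#'   of replicates with absolute score below the observed magnitude.
#' @export
compare_to_null <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"), null$n_genomes > 0L)
  vals <- null$values[!is.na(null$values)]
  if (!length(vals))
    stop("no null replicate retained both structure classes")
  if (length(vals) < null$n_genomes)
    message(null$n_genomes - length(vals),
            " null replicate(s) without both structure classes dropped")
  ts <- signed_rank_test(vals, mu = observed)
  list(p_value = ts$p_value,
       observed = observed,
       null_median = stats::median(vals),
       null_ci = stats::quantile(vals, c(0.025, 0.975), names = FALSE),
       n_reduced = sum(abs(vals) < abs(observed)),
       n_defined = length(vals),
       n_genomes = null$n_genomes)
}

#' Compare two null distributions
#'
#' Two-sided Mann-Whitney test between the replicate score lists of
#' two randomization methods.
#'
#' @param null_a,null_b `null_distribution` objects.
#' @return The p-value.
#' @export
compare_methods <- function(null_a, null_b) {
  stopifnot(inherits(null_a, "null_distribution"),
            inherits(null_b, "null_distribution"))
  a <- null_a$values[!is.na(null_a$values)]
  b <- null_b$values[!is.na(null_b$values)]
  if (!length(a) || !length(b))
    stop("a null distribution has no defined replicate scores")
  mann_whitney_test(a, b)$p_value
}

#' Export a null distribution as TSV
#'
#' Columns: replicate, method, tradeoff_score, seed.
#'
#' @param null a `null_distribution`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_null_distribution <- function(null, path) {
  utils::write.table(
    data.frame(replicate = seq_len(null$n_genomes),
               method = null$method,
               tradeoff_score = null$values,
               seed = null$seed),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
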