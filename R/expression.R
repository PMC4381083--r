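#' Per-gene trade-off score
#'
#' Computes the trade-off score (`median_high - median_low`, more
#' negative = stronger trade-off) for one gene independently: its
#' structure profile is either supplied or predicted with the folding
#' engine, regions are extracted, and the gene's own high/low codon
#' pools are compared.  Genes lacking one region class get `NA` (the
#' difference of medians is undefined without both classes).
#'
#' @param seq nucleotide sequence of the gene (trimmed if trimming is
#'   wanted; the function uses the sequence as given).
#' @param table a `time_table`.
#' @param rule a [threshold_rule()].
#' @param profile optional precomputed `structure_profile`; when
#'   `NULL` an MFE profile is computed with `engine`.
#' @param engine folding engine used when `profile` is `NULL`.
#' @param window_nt sliding window width for prediction.
#' @param gene_id identifier for messages.
#' @return The trade-off score (a.u.), or `NA` if a region class is
#'   missing.
#' @export
per_gene_tradeoff <- function(seq, table, rule, profile = NULL,
                              engine = mfe_engine(), window_nt = 101L,
                              gene_id = "gene") {
  if (is.null(profile)) {
    if (rule$kind != "mfe")
      stop("a PARS rule needs an experimental profile; none supplied")
    xs <- cds_set(gene_id, seq)
    profile <- sliding_window_mfe(xs, window_nt = window_nt,
                                  engine = engine)[[1]]
  }
  sp <- codon_time_profile(seq, table, gene_id = gene_id)
  if (is.null(sp)) return(NA_real_)
  regions <- extract_regions(profile, rule)
  asg <- assign_codons(regions, length(sp$codon_times))
  if (length(asg$high) == 0L || length(asg$low) == 0L) return(NA_real_)
  stats::median(sp$codon_times[asg$high + 1L]) -
    stats::median(sp$codon_times[asg$low + 1L])
}

#' Codon adaptation index weights
#'
#' Relative adaptiveness of each codon computed from a reference set
#' of (highly expressed) genes: within each amino acid,
#' `w = count / count of the most frequent synonymous codon`, so the
#' preferred codon has weight 1.  Synonymous codons never observed in
#' the reference receive a small positive floor (half the weight of
#' the least frequent observed synonymous codon) to keep the geometric
#' mean defined; amino acids entirely absent from the reference give
#' all their codons weight 1 (uninformative) with a warning.
#'
#' @param reference a `cds_set` of reference genes.
#' @return A named numeric vector of class `cai_weights` over the 61
#'   sense codons, values in (0, 1].
#' @export
cai_weights <- function(reference) {
  stopifnot(inherits(reference, "cds_set"), length(reference) > 0L)
  cods <- unlist(lapply(reference$seq, codons_of), use.names = FALSE)
  cods <- cods[cods %in% sense_codons()]
  cnt <- stats::setNames(numeric(61), sense_codons())
  tb <- table(cods)
  cnt[names(tb)] <- as.numeric(tb)
  aa <- translate_codons(sense_codons())
  w <- cnt
  absent <- character(0)
  for (a in unique(aa)) {
    idx <- which(aa == a)
    if (max(cnt[idx]) == 0) {
      w[idx] <- 1
      absent <- c(absent, a)
      next
    }
    w[idx] <- cnt[idx] / max(cnt[idx])
    zero <- idx[cnt[idx] == 0]
    if (length(zero)) {
      floor_w <- 0.5 * min(w[idx][cnt[idx] > 0])
      w[zero] <- floor_w
    }
  }
  if (length(absent))
    warning("amino acid(s) absent from reference, codons weighted 1: ",
            paste(absent, collapse = ", "))
  structure(w, class = "cai_weights")
}

#' Codon adaptation index
#'
#' Geometric mean of the relative-adaptiveness weights over a gene's
#' codons.  Codons of the single-codon amino acids (Met, Trp) and stop
#' codons are excluded from the mean, as they offer no synonymous
#' choice.  Values range from 0 to 1; 1 means every codon is the
#' preferred one.
#'
#' @param seq nucleotide sequence of the gene.
#' @param weights a [cai_weights()] vector.
#' @return CAI value in (0, 1].
#' @export
cai <- function(seq, weights) {
  stopifnot(inherits(weights, "cai_weights"))
  cods <- codons_of(seq)
  aa <- genetic_code()[cods]
  keep <- !is.na(aa) & !(aa %in% c("*", "M", "W"))
  cods <- cods[keep]
  if (!length(cods)) stop("no codons eligible for CAI in this gene")
  exp(mean(log(unclass(weights)[cods])))
}

#' Read a synonymous-variant library
#'
#' A variant library is a FASTA file of variant coding sequences plus
#' a TSV (columns `variant_id`, `expression`) of measured absolute
#' expression.  Only variants present in both files and with positive
#' expression are returned: variants without measurable expression are
#' excluded from analysis.
#'
#' @param fasta_path variant FASTA path.
#' @param expression_path expression TSV path.
#' @return A list with `cds` (a `cds_set`) and `expression` (named
#'   numeric vector aligned to the set's ids).
#' @export
read_variant_library <- function(fasta_path, expression_path) {
  x <- read_cds(fasta_path, "fasta")
  tab <- utils::read.delim(expression_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("variant_id", "expression") %in% names(tab)))
    stop("expression table must have columns variant_id, expression")
  tab <- tab[tab$variant_id %in% x$id & is.finite(tab$expression) &
               tab$expression > 0, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no variants with measurable expression")
  x <- x[tab$variant_id]
  list(cds = x, expression = stats::setNames(tab$expression, tab$variant_id))
}

#' Correlate per-variant trade-off scores with expression
#'
#' Pearson correlation (two-sided p) between trade-off scores and
#' absolute expression, together with the ordinary least-squares slope
#' of expression on score.  Variants with undefined score (`NA`) are
#' dropped with a message.
#'
#' @param scores named numeric vector of per-variant trade-off scores.
#' @param expression named numeric vector of absolute expression,
#'   matched by name.
#' @return A list with `r`, `p_value`, `slope`, `intercept`, `n`.
#' @export
correlate_expression <- function(scores, expression) {
  ids <- intersect(names(scores), names(expression))
  s <- scores[ids]; e <- expression[ids]
  drop <- !is.finite(s) | !is.finite(e)
  if (any(drop))
    message(sum(drop), " variant(s) without defined score dropped")
  s <- s[!drop]; e <- e[!drop]
  if (length(s) < 3L) stop("need at least 3 variants with defined scores")
  if (stats::sd(s) == 0 || stats::sd(e) == 0)
    stop("zero variance in scores or expression: correlation undefined")
  ct <- stats::cor.test(s, e, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(e ~ s)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_ci = unname(stats::confint(fit)[2, ]),
       n = length(s))
}

#' Score a whole variant library
#'
#' Convenience wrapper: per-variant trade-off scores, CAI against a
#' reference set, and the expression correlation.
#'
#' @param library list from [read_variant_library()] (elements `cds`,
#'   `expression`), or an equivalent list.
#' @param table a `time_table`.
#' @param rule a [threshold_rule()].
#' @param profiles optional named list of precomputed structure
#'   profiles (one per variant); otherwise MFE profiles are computed
#'   with `engine`.
#' @param cai_reference optional `cds_set` used to derive CAI weights
#'   (defaults to the library itself).
#' @inheritParams per_gene_tradeoff
#' @return A list with `table` (data.frame variant_id, tradeoff_score,
#'   cai, expression) and `correlation` (see
#'   [correlate_expression()]).
#' @export
score_variant_library <- function(library, table, rule, profiles = NULL,
                                  engine = mfe_engine(), window_nt = 101L,
                                  cai_reference = NULL) {
  x <- library$cds
  scores <- vapply(seq_along(x$id), function(i)
    per_gene_tradeoff(x$seq[i], table, rule,
                      profile = profiles[[x$id[i]]],
                      engine = engine, window_nt = window_nt,
                      gene_id = x$id[i]),
    numeric(1))
  names(scores) <- x$id
  w <- cai_weights(if (is.null(cai_reference)) x else cai_reference)
  cais <- vapply(x$seq, cai, numeric(1), weights = w, USE.NAMES = FALSE)
  tab <- data.frame(variant_id = x$id, tradeoff_score = unname(scores),
                    cai = cais,
                    expression = unname(library$expression[x$id]),
                    stringsAsFactors = FALSE)
  list(table = tab,
       correlation = correlate_expression(scores, library$expression))
}
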