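#' Specification of a synthetic genome
#'
#' Describes a multi-gene synthetic genome in which structure and
#' synonymous codon choice are coupled with known, tunable strength,
#' so that every pipeline stage can be validated against planted
#' ground truth.  Genes are a sequence of alternating high/low
#' structural blocks; within high blocks each amino acid's codon is
#' drawn with probability mass shifted toward its fastest synonymous
#' codon by `beta` (`beta = 1`: always the fastest; `beta = 0`:
#' uniform, i.e. no coupling), and low blocks mirror toward the
#' slowest codon.
#'
#' Two structure channels exist:
#' * `mode = "pars"` (default): amino acids are uniform over all 20
#'   and the structure truth is emitted as PARS-like per-nucleotide
#'   scores, block mean +1 (high) or -1 (low) plus Gaussian noise of
#'   sd `pars_noise_sd`.  Structure truth is independent of sequence
#'   content, so planted effects are exact.
#' * `mode = "mfe"`: structure is written into the sequence itself so
#'   the folding pipeline can recover it.  A fraction
#'   `1 - shared_frac` of codons are "skeleton" positions: high
#'   blocks use G/C-only codons (Ala GCC/GCG, Pro CCC/CCG, Gly
#'   GGC/GGG) that pair strongly, low blocks use purine-only codons
#'   (Lys AAA/AAG, Glu GAA/GAG, Arg AGA/AGG) that barely pair.  The
#'   remaining `shared_frac` of codons carry the beta coupling and use
#'   amino acids occurring in both block classes, which is what
#'   synonymous shuffling later destroys.
#'
#' @param n_genes number of genes.
#' @param gene_len_codons codons per gene; a single value or a
#'   `c(min, max)` range sampled uniformly.
#' @param block_len_nt structural block length in nucleotides (a
#'   multiple of 3; should be at least the minimum region length used
#'   in analysis, and at least the folding window in `"mfe"` mode).
#' @param beta coupling strength in `[0, 1]`.
#' @param pars_noise_sd sd of the Gaussian noise on PARS block means.
#' @param table a `time_table` providing the fast/slow ranking (also
#'   used by the analysis, so truth and analysis share one source).
#' @param mode `"pars"` or `"mfe"`.
#' @param shared_frac fraction of coupled (non-skeleton) codons in
#'   `"mfe"` mode.
#' @param seed integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200L, gene_len_codons = 300L,
                           block_len_nt = 60L, beta = 0.5,
                           pars_noise_sd = 0.3,
                           table = synthetic_time_table(),
                           mode = c("pars", "mfe"), shared_frac = 0.25,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (block_len_nt %% 3L != 0L) stop("block_len_nt must be a multiple of 3")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (pars_noise_sd < 0) stop("pars_noise_sd must be >= 0")
  if (n_genes < 1L) stop("need at least one gene")
  stopifnot(inherits(table, "time_table"))
  structure(list(n_genes = as.integer(n_genes),
                 gene_len_codons = as.integer(gene_len_codons),
                 block_len_nt = as.integer(block_len_nt),
                 beta = beta, pars_noise_sd = pars_noise_sd,
                 table = table, mode = mode, shared_frac = shared_frac,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# skeleton codon subsets for the "mfe" mode
mfe_skeleton <- list(
  high = list(A = c("GCC", "GCG"), P = c("CCC", "CCG"), G = c("GGC", "GGG")),
  low  = list(K = c("AAA", "AAG"), E = c("GAA", "GAG"), R = c("AGA", "AGG"))
)

# synonymous codons of one amino acid, fastest first under `table`
codons_by_speed <- function(aa, table) {
  cods <- sense_codons()[translate_codons(sense_codons()) == aa]
  cods[order(unclass(table)[cods], cods)]
}

# codon-choice probabilities for one amino acid under the beta rule
beta_probs <- function(k, beta, klass) {
  p <- rep((1 - beta) / k, k)
  if (klass == "high") p[1] <- p[1] + beta else p[k] <- p[k] + beta
  p
}

#' Generate a synthetic genome
#'
#' Draws the genome described by a [synthetic_spec()]: gene sequences,
#' the PARS-style score table (in `"pars"` mode), and per-codon truth
#' labels.  Deterministic given the spec's seed.
#'
#' @param spec a `synthetic_spec`.
#' @return A list with `genes` (an untrimmed, analysis-ready
#'   `cds_set`), `scores` (data.frame `gene_id`, `position`, `score`;
#'   `NULL` in `"mfe"` mode) and `truth` (list with per-gene codon
#'   block classes and the spec).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  aas <- sort(unique(translate_codons(sense_codons())))
  shared_aas <- if (spec$mode == "mfe")
    setdiff(aas, c(names(mfe_skeleton$high), names(mfe_skeleton$low)))
  else aas
  # per-aa codon lists (fastest first) and per-class choice probabilities
  cod_sets <- lapply(stats::setNames(nm = aas), codons_by_speed,
                     table = spec$table)
  probs <- lapply(c(high = "high", low = "low"), function(kl)
    lapply(cod_sets, function(cs) beta_probs(length(cs), spec$beta, kl)))

  block_codons <- spec$block_len_nt %/% 3L
  ids <- sprintf("synth_%04d", seq_len(spec$n_genes))
  seqs <- character(spec$n_genes)
  truth_class <- vector("list", spec$n_genes)
  names(truth_class) <- ids
  score_rows <- vector("list", spec$n_genes)

  for (g in seq_len(spec$n_genes)) {
    n <- if (length(spec$gene_len_codons) == 2L)
      sample(spec$gene_len_codons[1]:spec$gene_len_codons[2], 1L)
    else spec$gene_len_codons
    klass <- rep(c("high", "low"),
                 length.out = ceiling(n / block_codons))
    klass <- rep(klass, each = block_codons)[seq_len(n)]
    cods <- character(n)
    if (spec$mode == "mfe") {
      is_shared <- stats::runif(n) < spec$shared_frac
      aa <- character(n)
      aa[is_shared] <- sample(shared_aas, sum(is_shared), replace = TRUE)
      for (kl in c("high", "low")) {
        sk <- !is_shared & klass == kl
        if (any(sk)) {
          ska <- sample(names(mfe_skeleton[[kl]]), sum(sk), replace = TRUE)
          aa[sk] <- ska
          for (a in names(mfe_skeleton[[kl]])) {
            pos <- sk & aa == a
            if (any(pos))
              cods[pos] <- sample(mfe_skeleton[[kl]][[a]], sum(pos),
                                  replace = TRUE)
          }
        }
      }
    } else {
      is_shared <- rep(TRUE, n)
      aa <- sample(shared_aas, n, replace = TRUE)
    }
    for (kl in c("high", "low")) {
      for (a in unique(aa[is_shared & klass == kl])) {
        pos <- is_shared & klass == kl & aa == a
        cs <- cod_sets[[a]]
        cods[pos] <- if (length(cs) == 1L) cs else
          sample(cs, sum(pos), replace = TRUE, prob = probs[[kl]][[a]])
      }
    }
    seqs[g] <- paste(cods, collapse = "")
    truth_class[[g]] <- klass
    if (spec$mode == "pars") {
      nt_class <- rep(klass, each = 3L)
      score <- ifelse(nt_class == "high", 1, -1) +
        stats::rnorm(3L * n, sd = spec$pars_noise_sd)
      score_rows[[g]] <- data.frame(gene_id = ids[g],
                                    position = seq_len(3L * n) - 1L,
                                    score = score,
                                    stringsAsFactors = FALSE)
    }
  }
  scores <- if (spec$mode == "pars")
    do.call(rbind, c(score_rows, list(make.row.names = FALSE))) else NULL
  list(genes = cds_set(ids, seqs),
       scores = scores,
       truth = list(codon_class = truth_class, spec = spec))
}

# population median of a discrete distribution (support, prob)
discrete_median <- function(support, prob) {
  o <- order(support)
  support <- support[o]
  cum <- cumsum(prob[o])
  i <- which(cum >= 0.5 - 1e-12)[1]
  if (abs(cum[i] - 0.5) < 1e-12 && i < length(support))
    (support[i] + support[i + 1]) / 2
  else support[i]
}

#' Analytic expectation of the planted time difference
#'
#' Computes, exactly from the finite support of the codon-time
#' mixture, the population value of `delta_t = median_low -
#' median_high` implied by a spec's amino-acid and codon-choice
#' distributions.  In `"pars"` mode amino acids are uniform over the
#' 20; in `"mfe"` mode the skeleton/shared mixture is used.
#'
#' @param spec a `synthetic_spec`.
#' @return The expected `delta_t` (a.u.); 0 when `beta = 0`.
#' @export
expected_delta_t <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  meds <- vapply(c("high", "low"), function(kl) {
    mix <- class_time_mixture(spec, kl)
    discrete_median(mix$support, mix$prob)
  }, numeric(1))
  unname(meds["low"] - meds["high"])
}

# time distribution of codons in one block class under the spec
class_time_mixture <- function(spec, klass) {
  aas <- sort(unique(translate_codons(sense_codons())))
  support <- numeric(0); prob <- numeric(0)
  add <- function(cods, p_aa, pr) {
    support <<- c(support, unclass(spec$table)[cods])
    prob <<- c(prob, p_aa * pr)
  }
  if (spec$mode == "pars") {
    for (a in aas) {
      cs <- codons_by_speed(a, spec$table)
      add(cs, 1 / length(aas), beta_probs(length(cs), spec$beta, klass))
    }
  } else {
    shared_aas <- setdiff(aas, c(names(mfe_skeleton$high),
                                 names(mfe_skeleton$low)))
    skel <- mfe_skeleton[[klass]]
    for (a in names(skel))
      add(skel[[a]], (1 - spec$shared_frac) / length(skel),
          rep(0.5, 2))
    for (a in shared_aas) {
      cs <- codons_by_speed(a, spec$table)
      add(cs, spec$shared_frac / length(shared_aas),
          beta_probs(length(cs), spec$beta, klass))
    }
  }
  # collapse duplicated support values
  agg <- tapply(prob, support, sum)
  list(support = as.numeric(names(agg)), prob = as.numeric(agg))
}

#' Generate a synonymous-variant expression library
#'
#' Builds one random protein and recodes it `n_variants` times with
#' coupling strengths spanning `beta_range`; the structural blocks and
#' the PARS-style scores are shared by all variants, only synonymous
#' codon choice differs.  Measured expression is simulated as
#' `intercept + slope * planted_score + noise`, where the planted
#' trade-off score of a variant is the analytic
#' `-expected_delta_t(beta)` (median_high - median_low convention:
#' more negative = stronger trade-off).
#'
#' @param base_protein_len protein length in codons.
#' @param n_variants number of variants (>= 3).
#' @param beta_range `c(min, max)` coupling range spanned evenly.
#' @param slope linear effect of the planted score on expression.
#' @param noise_sd sd of the Gaussian expression noise.
#' @param intercept baseline expression.
#' @param block_len_nt structural block length (multiple of 3).
#' @param pars_noise_sd sd of the PARS score noise.
#' @param table a `time_table`.
#' @param seed integer seed.
#' @return A list with `library` (elements `cds`, `expression`, ready
#'   for [score_variant_library()]), `scores` (PARS score data.frame
#'   for all variants) and `truth` (data.frame `variant_id`, `beta`,
#'   `planted_score`, `expression`).
#' @export
generate_variant_library <- function(base_protein_len = 300L,
                                     n_variants = 30L,
                                     beta_range = c(0, 1),
                                     slope = -0.09, noise_sd = 0.3,
                                     intercept = 1,
                                     block_len_nt = 60L,
                                     pars_noise_sd = 0.3,
                                     table = synthetic_time_table(),
                                     seed = 1L) {
  if (n_variants < 3L) stop("need at least 3 variants")
  set.seed(seed)
  aas <- sort(unique(translate_codons(sense_codons())))
  protein <- sample(aas, base_protein_len, replace = TRUE)
  block_codons <- block_len_nt %/% 3L
  klass <- rep(rep(c("high", "low"),
                   length.out = ceiling(base_protein_len / block_codons)),
               each = block_codons)[seq_len(base_protein_len)]
  betas <- seq(beta_range[1], beta_range[2], length.out = n_variants)
  ids <- sprintf("variant_%02d", seq_len(n_variants))

  cod_sets <- lapply(stats::setNames(nm = aas), codons_by_speed,
                     table = table)
  seqs <- character(n_variants)
  planted <- numeric(n_variants)
  score_rows <- vector("list", n_variants)
  nt_class <- rep(klass, each = 3L)
  for (v in seq_len(n_variants)) {
    cods <- character(base_protein_len)
    for (kl in c("high", "low")) {
      for (a in unique(protein[klass == kl])) {
        pos <- klass == kl & protein == a
        cs <- cod_sets[[a]]
        cods[pos] <- if (length(cs) == 1L) cs else
          sample(cs, sum(pos), replace = TRUE,
                 prob = beta_probs(length(cs), betas[v], kl))
      }
    }
    seqs[v] <- paste(cods, collapse = "")
    sp <- synthetic_spec(n_genes = 1L, gene_len_codons = base_protein_len,
                         block_len_nt = block_len_nt, beta = betas[v],
                         table = table, mode = "pars")
    planted[v] <- -expected_delta_t(sp)
    score_rows[[v]] <- data.frame(gene_id = ids[v],
                                  position = seq_len(3L * base_protein_len) - 1L,
                                  score = ifelse(nt_class == "high", 1, -1) +
                                    stats::rnorm(3L * base_protein_len,
                                                 sd = pars_noise_sd),
                                  stringsAsFactors = FALSE)
  }
  expression <- intercept + slope * planted +
    stats::rnorm(n_variants, sd = noise_sd)
  list(library = list(cds = cds_set(ids, seqs),
                      expression = stats::setNames(expression, ids)),
       scores = do.call(rbind, c(score_rows, list(make.row.names = FALSE))),
       truth = data.frame(variant_id = ids, beta = betas,
                          planted_score = planted,
                          expression = expression,
                          stringsAsFactors = FALSE))
}

#' Write a synthetic data set to disk
#'
#' Emits the generator output in the package's interchange formats:
#' gene FASTA, structure-score TSV (if present) and truth JSON.
#'
#' @param gen output of [generate_genome()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cds_fasta(gen$genes, file.path(dir, "genes.fasta"))
  if (!is.null(gen$scores))
    utils::write.table(gen$scores, file.path(dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(codon_class = gen$truth$codon_class,
                beta = gen$truth$spec$beta,
                mode = gen$truth$spec$mode,
                seed = gen$truth$spec$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
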