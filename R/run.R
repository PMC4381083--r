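#' Read a run configuration
#'
#' Analyses can be driven by a YAML configuration file.  Recognized
#' keys (all optional unless a command needs them):
#'
#' * `genome`: `path`, `format` (`fasta`/`genbank`)
#' * `scores`: path to a PARS-style score TSV (its presence selects
#'   the experimental structure channel)
#' * `times`: path to a codon-time TSV (defaults to the packaged
#'   synthetic table)
#' * `trim_nt`: terminal trim (default 51)
#' * `structure`: `kind`, `window_nt` (101), `high_cut`, `low_cut`,
#'   `min_len_nt` (20), `r_l` (list, default 10/20/30), `engine`
#'   (`fallback`/`vienna`)
#' * `randomization`: `methods`, `n_genomes` (100), `seed`
#' * `expression`: `fasta`, `expression`, `scores`
#' * `subsets`: named id-list file paths and/or length-bin names
#' * `out_dir`, `seed`
#'
#' @param path YAML file path.
#' @return A config list of class `run_config`.
#' @export
run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(trim_nt = 51L,
                   structure = list(window_nt = 101L, min_len_nt = 20L,
                                    r_l = c(10L, 20L, 30L),
                                    engine = "fallback"),
                   randomization = list(methods = c("synonymous_shuffle",
                                                    "codon_shuffle"),
                                        n_genomes = 100L, seed = 1L),
                   seed = 1L, out_dir = ".")
  cfg <- utils::modifyList(defaults, cfg)
  structure(cfg, class = "run_config")
}

cfg_engine <- function(cfg) mfe_engine(cfg$structure$engine)

cfg_table <- function(cfg) {
  if (!is.null(cfg$times)) read_time_table(cfg$times) else synthetic_time_table()
}

# load genome, trim, and build structure profiles per config
cfg_pipeline <- function(cfg) {
  genome <- read_cds(cfg$genome$path,
                     if (is.null(cfg$genome$format)) "fasta" else cfg$genome$format)
  trimmed <- if (cfg$trim_nt > 0L) trim_cds(genome, cfg$trim_nt) else genome
  if (!is.null(cfg$scores)) {
    kind <- "pars"
    profiles <- read_pars_scores(cfg$scores, trimmed)
  } else {
    kind <- "mfe"
    profiles <- sliding_window_mfe(trimmed, cfg$structure$window_nt,
                                   cfg_engine(cfg))
  }
  subsets <- NULL
  if (!is.null(cfg$subsets)) {
    subsets <- lapply(names(cfg$subsets), function(nm) {
      v <- cfg$subsets[[nm]]
      if (v %in% c("short", "medium", "long"))
        select_subset(genome, bin = v, name = nm)
      else select_subset(genome, ids = read_id_list(v), name = nm)
    })
    names(subsets) <- names(cfg$subsets)
  }
  list(genome = genome, trimmed = trimmed, profiles = profiles,
       kind = kind, subsets = subsets, table = cfg_table(cfg))
}

write_manifest <- function(cfg, out_dir, command) {
  man <- list(command = command,
              package_version = as.character(utils::packageVersion("codontrade")),
              config = unclass(cfg))
  jsonlite::write_json(man, file.path(out_dir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Region-length trade-off report
#'
#' Runs the genome-wide trade-off analysis for every configured
#' minimum region length (and subset) and writes a report TSV plus a
#' parameter manifest, mirroring a region-length results table.
#'
#' @param cfg a [run_config()] (or equivalent list).
#' @param out_dir output directory (defaults to the config's).
#' @return The report data.frame, invisibly; side effect: writes
#'   `table1.tsv` and `table1_manifest.json`.
#' @export
run_table1 <- function(cfg, out_dir = cfg$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pp <- cfg_pipeline(cfg)
  tab <- tradeoff_table(pp$trimmed, pp$profiles, pp$table,
                        r_l = unlist(cfg$structure$r_l), kind = pp$kind,
                        high_cut = cfg$structure$high_cut,
                        low_cut = cfg$structure$low_cut,
                        subsets = pp$subsets)
  utils::write.table(tab, file.path(out_dir, "table1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(cfg, out_dir, "table1")
  invisible(tab)
}

#' Randomized-genome null-model report
#'
#' Computes the observed genome-wide trade-off score and, for each
#' configured shuffling method, the null distribution over randomized
#' genomes (structure recomputed with the configured engine), with
#' one-sample Wilcoxon comparisons and the between-method
#' Mann-Whitney test.
#'
#' @inheritParams run_table1
#' @return A list with `observed`, `nulls`, `comparisons`,
#'   `method_p`; side effect: writes `null_<method>.tsv` and
#'   `randomize_manifest.json`.
#' @export
run_randomize <- function(cfg, out_dir = cfg$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pp <- cfg_pipeline(cfg)
  if (pp$kind != "mfe")
    stop("randomization requires predicted (MFE) structure")
  rule <- threshold_rule("mfe", cfg$structure$high_cut,
                         cfg$structure$low_cut, cfg$structure$min_len_nt)
  obs <- genome_tradeoff(pp$trimmed, pp$profiles, pp$table, rule)
  nulls <- list(); comparisons <- list()
  for (m in cfg$randomization$methods) {
    nd <- null_distribution(pp$trimmed, pp$table, rule, method = m,
                            n_genomes = cfg$randomization$n_genomes,
                            seed = cfg$randomization$seed,
                            engine = cfg_engine(cfg),
                            window_nt = cfg$structure$window_nt)
    write_null_distribution(nd, file.path(out_dir, paste0("null_", m, ".tsv")))
    nulls[[m]] <- nd
    comparisons[[m]] <- compare_to_null(obs$tradeoff_score, nd)
  }
  method_p <- if (length(nulls) == 2L)
    compare_methods(nulls[[1]], nulls[[2]]) else NA_real_
  write_manifest(cfg, out_dir, "randomize")
  list(observed = obs, nulls = nulls, comparisons = comparisons,
       method_p = method_p)
}

#' Variant-library expression report
#'
#' Scores a synonymous-variant library (per-variant trade-off score
#' and CAI), correlates the scores with measured expression, and
#' writes the per-variant table plus a JSON summary (R, p, slope).
#'
#' @inheritParams run_table1
#' @return The [score_variant_library()] result, invisibly; side
#'   effect: writes `variants.tsv`, `expression_summary.json` and the
#'   manifest.
#' @export
run_expression <- function(cfg, out_dir = cfg$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lib <- read_variant_library(cfg$expression$fasta, cfg$expression$expression)
  if (!is.null(cfg$expression$scores)) {
    profiles <- read_pars_scores(cfg$expression$scores, lib$cds,
                                 offset_nt = 0L)
    rule <- threshold_rule("pars", min_len_nt = cfg$structure$min_len_nt)
  } else {
    profiles <- NULL
    rule <- threshold_rule("mfe", cfg$structure$high_cut,
                           cfg$structure$low_cut, cfg$structure$min_len_nt)
  }
  res <- score_variant_library(lib, cfg_table(cfg), rule,
                               profiles = profiles,
                               engine = cfg_engine(cfg),
                               window_nt = cfg$structure$window_nt)
  utils::write.table(res$table, file.path(out_dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$correlation,
                       file.path(out_dir, "expression_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, out_dir, "expression")
  invisible(res)
}

#' Generate and write a synthetic data set
#'
#' @inheritParams run_table1
#' @param spec optional [synthetic_spec()]; when `NULL`, spec fields
#'   are taken from `cfg$synth`.
#' @return The generator output, invisibly; side effect: files under
#'   `out_dir` (see [write_synthetic()]).
#' @export
run_synth <- function(cfg, out_dir = cfg$out_dir, spec = NULL) {
  if (is.null(spec)) {
    args <- cfg$synth
    args$table <- cfg_table(cfg)
    if (is.null(args$seed)) args$seed <- cfg$seed
    spec <- do.call(synthetic_spec, args)
  }
  gen <- generate_genome(spec)
  write_synthetic(gen, out_dir)
  write_manifest(cfg, out_dir, "synth")
  invisible(gen)
}
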