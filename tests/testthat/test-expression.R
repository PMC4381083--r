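test_that("a gene with identical pools in both classes scores zero", {
  x_seq <- strrep("GCT", 40)
  profile <- make_profile(c(rep(1, 60), rep(-1, 60)))
  score <- per_gene_tradeoff(x_seq, synthetic_time_table(),
                             threshold_rule("pars", min_len_nt = 20),
                             profile = profile)
  expect_equal(score, 0)
})

test_that("swapping the class labels negates the per-gene score", {
  set.seed(70)
  s <- random_cds(60)
  vals <- rep(c(1, -1), each = 90)
  rule <- threshold_rule("pars", min_len_nt = 20)
  tab <- synthetic_time_table()
  a <- per_gene_tradeoff(s, tab, rule, profile = make_profile(vals))
  b <- per_gene_tradeoff(s, tab, rule, profile = make_profile(-vals))
  expect_equal(a, -b)
})

test_that("genes missing a structure class score NA", {
  s <- strrep("GCT", 40)
  rule <- threshold_rule("pars", min_len_nt = 20)
  tab <- synthetic_time_table()
  expect_true(is.na(per_gene_tradeoff(s, tab, rule,
                                      profile = make_profile(rep(1, 120)))))
  expect_error(per_gene_tradeoff(s, tab, rule), "experimental")
})

test_that("CAI weights are relative adaptiveness with a zero-count floor", {
  # reference: 30 GAA vs 10 GAG; lysine only AAA (AAG unobserved)
  ref <- cds_set("ref", paste0(strrep("GAA", 30), strrep("GAG", 10),
                               strrep("AAA", 5)))
  expect_warning(w <- cai_weights(ref), "weighted 1")
  expect_equal(unclass(w)[["GAA"]], 1)
  expect_equal(unclass(w)[["GAG"]], 1 / 3)
  expect_equal(unclass(w)[["AAA"]], 1)
  expect_equal(unclass(w)[["AAG"]], 0.5)  # half the minimum observed weight
  # absent amino acids get uninformative weight 1
  expect_equal(unclass(w)[["TTT"]], 1)
  # brute-force count oracle on a random reference
  set.seed(71)
  ref2 <- cds_set(c("a", "b"), c(random_cds(300), random_cds(300)))
  w2 <- suppressWarnings(cai_weights(ref2))
  cods <- unlist(lapply(ref2$seq, codontrade:::codons_of))
  gaa <- sum(cods == "GAA"); gag <- sum(cods == "GAG")
  if (gaa > 0 && gag > 0)
    expect_equal(unclass(w2)[["GAG"]] / unclass(w2)[["GAA"]],
                 (gag / max(gag, gaa)) / (gaa / max(gag, gaa)))
})

test_that("CAI is a geometric mean excluding Met, Trp and stops", {
  ref <- cds_set("ref", paste0(strrep("GAA", 4), "GAG"))
  w <- suppressWarnings(cai_weights(ref))
  # gene of only weight-1 codons
  expect_equal(cai(strrep("GAA", 10), w), 1)
  # two codons with weights 0.25 and 1 -> sqrt(0.25)
  expect_equal(cai("GAGGAA", w), sqrt(0.25 * 1))
  # ATG and TGG are excluded from the mean
  expect_equal(cai("ATGGAGGAATGG", w), sqrt(0.25 * 1))
  # independent log-sum oracle on a random gene
  set.seed(72)
  s <- random_cds(100)
  cods <- codontrade:::codons_of(s)
  aa <- codontrade:::translate_codons(cods)
  keep <- !(aa %in% c("M", "W"))
  expect_equal(cai(s, w),
               exp(sum(log(unclass(w)[cods[keep]])) / sum(keep)))
  # invariance under codon permutation
  expect_equal(cai(paste(sample(cods), collapse = ""), w), cai(s, w))
})

test_that("expression correlation recovers a perfect linear relation", {
  scores <- stats::setNames(c(-5, -3, -1, 0, 2), paste0("v", 1:5))
  expr <- -2 * scores
  r <- suppressWarnings(correlate_expression(scores, expr))
  expect_equal(r$r, -1)
  expect_equal(r$slope, -2)
  expect_equal(r$n, 5L)
  expect_error(correlate_expression(stats::setNames(rep(1, 5), paste0("v", 1:5)),
                                    expr), "variance")
  expect_error(correlate_expression(scores[1:2], expr[1:2]), "at least 3")
})

test_that("Pearson R is invariant under affine rescaling of expression", {
  set.seed(73)
  scores <- stats::setNames(rnorm(20), paste0("v", 1:20))
  expr <- stats::setNames(3 - 0.5 * scores + rnorm(20, sd = 0.2),
                          paste0("v", 1:20))
  a <- correlate_expression(scores, expr)
  b <- correlate_expression(scores, 10 * expr + 4)
  expect_equal(a$r, b$r)
  expect_equal(a$p_value, b$p_value)
  expect_equal(10 * a$slope, b$slope)
})

test_that("variants with undefined scores are dropped from the correlation", {
  scores <- stats::setNames(c(NA, -3, -1, 0, 2), paste0("v", 1:5))
  expr <- stats::setNames(1:5, paste0("v", 1:5))
  expect_message(r <- correlate_expression(scores, expr), "dropped")
  expect_equal(r$n, 4L)
})

test_that("a synthetic variant library recovers the planted relationship", {
  lib <- generate_variant_library(base_protein_len = 200, n_variants = 24,
                                  slope = -0.09, noise_sd = 0.2, seed = 74)
  f <- write_scores_tsv(lib$scores)
  profiles <- read_pars_scores(f, lib$library$cds, offset_nt = 0L)
  unlink(f)
  res <- score_variant_library(lib$library, synthetic_time_table(),
                               threshold_rule("pars", min_len_nt = 20),
                               profiles = profiles)
  expect_lt(res$correlation$r, 0)
  expect_lt(res$correlation$p_value, 0.01)
  # planted slope inside the fitted 95% CI
  expect_gt(-0.09, res$correlation$slope_ci[1])
  expect_lt(-0.09, res$correlation$slope_ci[2])
  # measured per-variant scores track the planted ones
  expect_gt(stats::cor(res$table$tradeoff_score, lib$truth$planted_score),
            0.95)
  # CAI stays on its defined scale
  expect_true(all(res$table$cai > 0 & res$table$cai <= 1))
})

test_that("variant libraries read back only variants with measurable expression", {
  lib <- generate_variant_library(base_protein_len = 60, n_variants = 6,
                                  noise_sd = 0, seed = 75)
  dir <- tempfile(); dir.create(dir)
  write_cds_fasta(lib$library$cds, file.path(dir, "variants.fasta"))
  expr <- data.frame(variant_id = names(lib$library$expression),
                     expression = unname(lib$library$expression))
  expr$expression[1] <- -1  # unmeasurable
  utils::write.table(expr, file.path(dir, "expr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  got <- read_variant_library(file.path(dir, "variants.fasta"),
                              file.path(dir, "expr.tsv"))
  expect_length(got$cds, 5)
  expect_false(expr$variant_id[1] %in% got$cds$id)
})
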