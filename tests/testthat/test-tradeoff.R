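test_that("codon assignment requires full containment in a region", {
  regs <- data.frame(gene_id = "g", start = 0L, end = 25L, klass = "high",
                     length = 25L, stringsAsFactors = FALSE)
  asg <- assign_codons(regs, n_codons = 20)
  expect_equal(asg$high, 0:7)  # codon 8 spans nt 24-26 and is excluded
  expect_length(asg$low, 0)
  # enumeration oracle over random intervals
  set.seed(40)
  for (i in 1:25) {
    s <- sample(0:40, 1); e <- s + sample(3:30, 1)
    rr <- data.frame(gene_id = "g", start = s, end = e, klass = "low",
                     length = e - s, stringsAsFactors = FALSE)
    got <- assign_codons(rr, n_codons = 30)$low
    want <- Filter(function(k) 3 * k >= s && 3 * k + 3 <= e, 0:29)
    expect_equal(got, as.integer(want))
  }
})

test_that("majority assignment admits boundary codons with two nucleotides inside", {
  rr <- data.frame(gene_id = "g", start = 2L, end = 25L, klass = "high",
                   length = 23L, stringsAsFactors = FALSE)
  maj <- assign_codons(rr, n_codons = 20, mode = "majority")$high
  want <- Filter(function(k)
    sum((3 * k):(3 * k + 2) >= 2 & (3 * k):(3 * k + 2) < 25) >= 2, 0:19)
  expect_equal(maj, as.integer(want))
})

test_that("degenerate and invalid region sets are handled", {
  expect_equal(assign_codons(NULL, 10), list(high = integer(0), low = integer(0)))
  one <- data.frame(gene_id = "g", start = 0L, end = 3L, klass = "high",
                    length = 3L, stringsAsFactors = FALSE)
  expect_equal(assign_codons(one, 10)$high, 0L)
  overlap <- data.frame(gene_id = "g", start = c(0L, 10L), end = c(12L, 20L),
                        klass = "high", length = c(12L, 10L),
                        stringsAsFactors = FALSE)
  expect_error(assign_codons(overlap, 10), "overlapping")
})

test_that("the trade-off statistic reports medians, IQR, delta_t and exact p", {
  r <- tradeoff_statistic(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$delta_t, 3)
  expect_equal(r$tradeoff_score, -3)
  expect_equal(r$p_value, 0.1)  # complete separation, n=m=3
  expect_equal(r$median_high, 2)
  expect_equal(r$iqr_low, quantile(c(4, 5, 6), c(0.25, 0.75), names = FALSE))
  same <- tradeoff_statistic(c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$delta_t, 0)
  # delta_t and tradeoff_score are exact negatives
  set.seed(41)
  h <- runif(30); l <- runif(25)
  rr <- tradeoff_statistic(h, l)
  expect_equal(rr$delta_t, -rr$tradeoff_score)
  expect_true(rr$iqr_high[1] <= rr$median_high &&
                rr$median_high <= rr$iqr_high[2])
})

test_that("an empty pool yields an NA result carrying the counts", {
  r <- tradeoff_statistic(numeric(0), c(1, 2), n_regions_high = 0L,
                          n_regions_low = 1L)
  expect_true(is.na(r$delta_t))
  expect_true(is.na(r$p_value))
  expect_equal(r$n_codons_low, 2L)
  expect_output(print(r), "empty")
})

test_that("swapping pools negates delta_t and keeps the p-value", {
  set.seed(42)
  for (i in 1:10) {
    h <- sample(1:9, sample(3:12, 1), replace = TRUE)
    l <- sample(1:9, sample(3:12, 1), replace = TRUE)
    a <- tradeoff_statistic(h, l)
    b <- tradeoff_statistic(l, h)
    expect_equal(a$delta_t, -b$delta_t)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("genome-wide pooling is invariant to gene order and bounded by codon counts", {
  spec <- synthetic_spec(n_genes = 6, gene_len_codons = 60, beta = 0.6,
                         seed = 43)
  gen <- generate_genome(spec)
  profs <- pars_profiles_from_scores(gen)
  tab <- synthetic_time_table()
  rule <- threshold_rule("pars", min_len_nt = 20)
  r1 <- genome_tradeoff(gen$genes, profs, tab, rule)
  perm <- sample(length(gen$genes))
  r2 <- genome_tradeoff(gen$genes[perm], profs[perm], tab, rule)
  expect_equal(summary(r1), summary(r2))
  total_codons <- sum(nchar(gen$genes$seq)) / 3
  expect_lte(r1$n_codons_high + r1$n_codons_low, total_codons)
  expect_gt(r1$n_regions_high, 0)
})

test_that("subsets restrict pooling to member genes", {
  spec <- synthetic_spec(n_genes = 6, gene_len_codons = 60, beta = 0.6,
                         seed = 44)
  gen <- generate_genome(spec)
  profs <- pars_profiles_from_scores(gen)
  tab <- synthetic_time_table()
  rule <- threshold_rule("pars", min_len_nt = 20)
  sub <- select_subset(gen$genes, ids = gen$genes$id[1:2])
  r_sub <- genome_tradeoff(gen$genes, profs, tab, rule, subset = sub)
  r_direct <- genome_tradeoff(gen$genes[1:2], profs[1:2], tab, rule)
  expect_equal(r_sub$n_codons_high, r_direct$n_codons_high)
  expect_equal(r_sub$median_low, r_direct$median_low)
})

test_that("a genome without one region class reports NA with counts", {
  x <- cds_set("g", strrep("GCT", 40), trimmed = TRUE, offset_nt = 0L)
  profs <- list(g = make_profile(rep(1, 120)))  # all high
  r <- genome_tradeoff(x, profs, synthetic_time_table(),
                       threshold_rule("pars", min_len_nt = 20))
  expect_true(is.na(r$delta_t))
  expect_equal(r$n_regions_low, 0L)
  expect_gt(r$n_codons_high, 0L)
})

test_that("codon usage fractions count assigned codons and normalize per class", {
  x <- cds_set("g", "GCTGCTAAACCC", trimmed = TRUE, offset_nt = 0L)
  profs <- list(g = make_profile(c(rep(1, 9), rep(-1, 3))))
  tab <- synthetic_time_table()
  usage <- codon_usage_by_region(x, profs, tab,
                                 threshold_rule("pars", min_len_nt = 3))
  high <- usage[usage$klass == "high", ]
  expect_equal(high$fraction[high$codon == "GCT"], 2 / 3)
  expect_equal(high$fraction[high$codon == "AAA"], 1 / 3)
  low <- usage[usage$klass == "low", ]
  expect_equal(low$fraction[low$codon == "CCC"], 1)
  expect_equal(sum(high$fraction), 1)
  expect_equal(sum(low$fraction), 1)
  # speed ranks order synonymous codons fastest-first under the table
  ala <- high[high$amino_acid == "A", ]
  expect_equal(ala$codon[order(ala$rank_by_speed)],
               codontrade:::codons_by_speed("A", tab))
})

test_that("amino-acid composition aggregates codons and sums to one", {
  x <- cds_set("g", "GCTGCAGCGGCC", trimmed = TRUE, offset_nt = 0L)
  profs <- list(g = make_profile(rep(1, 12)))
  comp <- aa_composition_by_region(x, profs,
                                   threshold_rule("pars", min_len_nt = 3))
  expect_equal(comp$fraction[comp$klass == "high" & comp$amino_acid == "A"], 1)
  spec <- synthetic_spec(n_genes = 4, gene_len_codons = 50, seed = 45)
  gen <- generate_genome(spec)
  profs2 <- pars_profiles_from_scores(gen)
  comp2 <- aa_composition_by_region(gen$genes, profs2,
                                    threshold_rule("pars", min_len_nt = 20))
  for (kl in unique(comp2$klass))
    expect_equal(sum(comp2$fraction[comp2$klass == kl]), 1)
})

test_that("the region-length report has one row per subset and R_l", {
  spec <- synthetic_spec(n_genes = 4, gene_len_codons = 60, seed = 46)
  gen <- generate_genome(spec)
  profs <- pars_profiles_from_scores(gen)
  tab <- tradeoff_table(gen$genes, profs, synthetic_time_table(),
                        r_l = c(10, 20, 30), kind = "pars")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$r_l, c(10, 20, 30))
  expect_true(all(tab$n_regions_high[1] >= tab$n_regions_high[2:3]))
})
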