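test_that("poly-A windows cannot pair and fold to 0 kcal/mol", {
  x <- cds_set("pa", strrep("AAA", 67))  # 201 nt
  p <- sliding_window_mfe(x, 101, mfe_engine())[[1]]
  expect_equal(p$kind, "mfe")
  expect_length(p$values, 201)
  expect_true(all(is.na(p$values[1:50])))
  expect_true(all(is.na(p$values[152:201])))
  expect_true(all(p$values[51:151] == 0))
})

test_that("window geometry leaves half-window ends undefined", {
  set.seed(10)
  x <- cds_set("g", random_cds(60))  # 180 nt
  p <- sliding_window_mfe(x, 101, mfe_engine())[[1]]
  def <- which(!is.na(p$values))
  expect_equal(def, 51:130)
  # shorter than the window: all undefined
  y <- cds_set("s", random_cds(30))
  ps <- sliding_window_mfe(y, 101, mfe_engine())[[1]]
  expect_true(all(is.na(ps$values)))
  expect_error(sliding_window_mfe(x, 100), "odd")
})

test_that("a designed hairpin scores exactly minus one per stem pair", {
  # 48 G, 5-nt loop, 48 C: max pairing is bounded by the 48 C's and the
  # full stem achieves it, so the fallback engine must give -48 exactly
  hp <- paste0(strrep("G", 48), strrep("A", 5), strrep("C", 48))
  x <- cds_set("hp", paste0(hp, "A"))  # 102 nt, frame-valid
  p <- sliding_window_mfe(x, 101, mfe_engine())[[1]]
  expect_equal(p$values[51], -48)
  # energy scale multiplies pair counts
  p2 <- sliding_window_mfe(x, 101, mfe_engine(scale = 0.5))[[1]]
  expect_equal(p2$values[51], -24)
})

test_that("fallback engine is deterministic and permutation-sensitive", {
  set.seed(11)
  s <- random_cds(67)
  x <- cds_set("g", s)
  p1 <- sliding_window_mfe(x, 101, mfe_engine())[[1]]
  p2 <- sliding_window_mfe(x, 101, mfe_engine())[[1]]
  expect_identical(p1$values, p2$values)
  cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
  sh <- paste(sample(cods), collapse = "")
  p3 <- sliding_window_mfe(cds_set("g", sh), 101, mfe_engine())[[1]]
  expect_false(identical(p1$values, p3$values))
})

test_that("RNAfold backend folds windows with plausible energies", {
  x <- cds_set("pa", strrep("AAA", 41))  # 123 nt
  p <- sliding_window_mfe(x, 101, mfe_engine("vienna"))[[1]]
  expect_true(all(p$values[51:73] == 0))
  hp <- cds_set("hp", paste0(strrep("GCA", 20), strrep("TGC", 20)))
  ph <- sliding_window_mfe(hp, 101, mfe_engine("vienna"))[[1]]
  expect_true(all(ph$values[!is.na(ph$values)] < -20))
})

test_that("PARS region extraction matches the worked example", {
  vals <- c(rep(1, 25), rep(-1, 10), rep(1, 5))
  p <- make_profile(vals)
  regs <- extract_regions(p, threshold_rule("pars", min_len_nt = 20))
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$start, 0L)
  expect_equal(regs$end, 25L)
  expect_equal(regs$klass, "high")
  expect_equal(regs$length, 25L)
})

test_that("undefined and mid-band profiles yield no regions", {
  p <- make_profile(rep(NA_real_, 100))
  expect_equal(nrow(extract_regions(p, threshold_rule("pars"))), 0L)
  # MFE values between the cut-offs are unclassified
  pm <- make_profile(rep(-25, 100), kind = "mfe")
  expect_equal(nrow(extract_regions(pm, threshold_rule("mfe"))), 0L)
  # kind mismatch is an error
  expect_error(extract_regions(pm, threshold_rule("pars")), "match")
})

test_that("PARS score of exactly zero classifies as low structure", {
  p <- make_profile(rep(0, 30))
  regs <- extract_regions(p, threshold_rule("pars", min_len_nt = 20))
  expect_equal(regs$klass, "low")
})

test_that("region extraction equals exhaustive maximal-run enumeration", {
  set.seed(12)
  rules <- list(threshold_rule("pars", min_len_nt = 5),
                threshold_rule("mfe", min_len_nt = 5))
  for (i in 1:100) {
    rule <- rules[[1 + i %% 2]]
    n <- sample(1:200, 1)
    vals <- if (rule$kind == "pars")
      sample(c(NA, -2, -1, 0, 1, 2), n, replace = TRUE)
    else sample(c(NA, -50, -40, -25, -10, 0), n, replace = TRUE)
    got <- extract_regions(make_profile(vals, kind = rule$kind), rule)
    want <- oracle_regions(vals, rule)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$klass, want$klass)
  }
})

test_that("raising the minimum region length only removes regions", {
  set.seed(13)
  for (i in 1:20) {
    vals <- sample(c(NA, -1, 1), 150, replace = TRUE)
    p <- make_profile(vals)
    key <- function(r) paste(r$start, r$end, r$klass)
    r10 <- key(extract_regions(p, threshold_rule("pars", min_len_nt = 10)))
    r20 <- key(extract_regions(p, threshold_rule("pars", min_len_nt = 20)))
    r30 <- key(extract_regions(p, threshold_rule("pars", min_len_nt = 30)))
    expect_true(all(r30 %in% r20))
    expect_true(all(r20 %in% r10))
  }
})

test_that("PARS regions of the two classes never overlap", {
  set.seed(14)
  vals <- rnorm(300)
  regs <- extract_regions(make_profile(vals),
                          threshold_rule("pars", min_len_nt = 3))
  cover <- rep(0L, 300)
  for (i in seq_len(nrow(regs)))
    cover[(regs$start[i] + 1):regs$end[i]] <- cover[(regs$start[i] + 1):regs$end[i]] + 1L
  expect_true(all(cover <= 1L))
})

test_that("experimental scores re-align to trimmed coordinates", {
  x <- cds_set("geneX", strrep("ACG", 10), trimmed = TRUE, offset_nt = 51L)
  f <- write_scores_tsv(data.frame(gene_id = "geneX",
                                   position = c(51, 10, 55, 81),
                                   score = c(1.7, 9, -2, 0.4)))
  profs <- read_pars_scores(f, x)
  v <- profs[["geneX"]]$values
  expect_equal(v[1], 1.7)      # untrimmed 51 -> trimmed 0
  expect_equal(v[5], -2)       # untrimmed 55 -> trimmed 4
  expect_true(all(is.na(v[-c(1, 5)])))  # pos 10 (trimmed away) and 81 (past end) dropped
})

test_that("score files for unknown genes warn and malformed rows error", {
  x <- cds_set("geneX", strrep("ACG", 10), trimmed = TRUE, offset_nt = 0L)
  f <- write_scores_tsv(data.frame(gene_id = c("geneX", "ghost"),
                                   position = c(0, 1), score = c(1, 2)))
  expect_warning(profs <- read_pars_scores(f, x), "absent from genome")
  expect_equal(profs[["geneX"]]$values[1], 1)
  f2 <- write_scores_tsv(data.frame(gene_id = "geneX",
                                    position = c(0, NA), score = c(1, 2)))
  expect_error(read_pars_scores(f2, x), "malformed")
})

test_that("generator scores round-trip into profiles defined exactly where scored", {
  spec <- synthetic_spec(n_genes = 2, gene_len_codons = 40, seed = 5)
  gen <- generate_genome(spec)
  profs <- pars_profiles_from_scores(gen)
  for (id in gen$genes$id) {
    v <- profs[[id]]$values
    expect_length(v, nchar(gen$genes$seq[gen$genes$id == id]))
    expect_false(anyNA(v))  # generator scores every nucleotide
  }
})

test_that("MFE profiles reject positive energies", {
  expect_error(make_profile(c(-1, 2), kind = "mfe"), "positive")
})
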