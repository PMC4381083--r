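# In-code fixtures: everything is generated at test time.

random_cds <- function(n_codons, rng_seedless = TRUE) {
  cods <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                         names(which(Biostrings::GENETIC_CODE == "*"))),
                 n_codons, replace = TRUE)
  paste(cods, collapse = "")
}

make_profile <- function(values, gene_id = "g1", kind = "pars") {
  codontrade:::structure_profile(gene_id, kind, values)
}

write_scores_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pars_profiles_from_scores <- function(gen) {
  f <- write_scores_tsv(gen$scores)
  on.exit(unlink(f))
  read_pars_scores(f, gen$genes)
}

# small GenBank flat file with forward, reverse-complement and join CDS
write_genbank_fixture <- function(path = tempfile(fileext = ".gb")) {
  set.seed(404)
  genome <- paste(sample(c("a", "c", "g", "t"), 120, replace = TRUE),
                  collapse = "")
  # forward CDS 1..30; reverse complement(61..90); join(91..99,103..111)
  lines <- c(
    "LOCUS       TESTREC               120 bp    DNA     linear   BCT",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "                     /organism=\"synthetic\"",
    "     CDS             1..30",
    "                     /locus_tag=\"geneA\"",
    "     CDS             complement(61..90)",
    "                     /locus_tag=\"geneB\"",
    "     CDS             join(91..99,",
    "                     103..111)",
    "                     /locus_tag=\"geneC\"",
    "     CDS             5..10",
    "                     /locus_tag=\"ps1\"",
    "                     /pseudo",
    "ORIGIN",
    paste0("        1 ", paste(substring(genome,
                                         seq(1, 60, 10),
                                         seq(10, 60, 10)), collapse = " ")),
    paste0("       61 ", paste(substring(genome,
                                         seq(61, 120, 10),
                                         seq(70, 120, 10)), collapse = " ")),
    "//")
  writeLines(lines, path)
  g <- toupper(genome)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  list(path = path,
       expected = list(geneA = substr(g, 1, 30),
                       geneB = rc(substr(g, 61, 90)),
                       geneC = paste0(substr(g, 91, 99), substr(g, 103, 111))))
}
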