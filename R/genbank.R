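# Minimal GenBank flat-file CDS extraction.  Handles single- and
# multi-record files, location forms <start..end>, join(...),
# complement(...) and complement(join(...)); partial-location markers
# (< and >) are tolerated.  Features flagged as pseudo are skipped, as
# are any whose location refers to another accession.

read_genbank_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path)
  rec_starts <- grep("^LOCUS", lines)
  if (!length(rec_starts)) stop("not a GenBank flat file (no LOCUS line): ", path)
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  ids <- character(0); seqs <- character(0)
  for (r in seq_along(rec_starts)) {
    rec <- lines[rec_starts[r]:rec_ends[r]]
    parsed <- parse_genbank_record(rec)
    ids <- c(ids, parsed$id)
    seqs <- c(seqs, parsed$seq)
  }
  list(id = ids, seq = seqs)
}

parse_genbank_record <- function(rec) {
  ori <- grep("^ORIGIN", rec)
  if (!length(ori)) stop("GenBank record without ORIGIN section")
  seq_lines <- rec[(ori[1] + 1L):length(rec)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat <- grep("^FEATURES", rec)
  if (!length(feat)) return(list(id = character(0), seq = character(0)))
  flines <- rec[(feat[1] + 1L):(ori[1] - 1L)]

  # group feature blocks: a new feature starts with a key at column 6
  is_key <- grepl("^     \\S", flines)
  grp <- cumsum(is_key)
  ids <- character(0); seqs <- character(0)
  for (g in unique(grp[grp > 0])) {
    block <- flines[grp == g]
    key <- sub("^\\s*(\\S+).*", "\\1", block[1])
    if (key != "CDS") next
    # location may wrap over continuation lines until first qualifier (/)
    qual_start <- grep("^\\s{10,}/", block)
    loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
    loc <- paste(sub("^\\s*CDS\\s*", "", block[1]),
                 paste(gsub("\\s", "", block[seq_len(loc_end)[-1]]), collapse = ""),
                 sep = "")
    loc <- gsub("\\s", "", loc)
    if (any(grepl("^\\s{10,}/pseudo\\s*$", block))) next
    if (grepl(":", loc)) next  # remote reference
    s <- extract_location(loc, genome)
    if (is.null(s)) next
    id <- genbank_feature_id(block, length(ids) + 1L)
    ids <- c(ids, id)
    seqs <- c(seqs, s)
  }
  list(id = ids, seq = seqs)
}

genbank_feature_id <- function(block, idx) {
  for (q in c("locus_tag", "gene", "protein_id")) {
    m <- grep(sprintf('/%s="?([^"]+)"?', q), block, value = TRUE)
    if (length(m))
      return(sub(sprintf('.*/%s="?([^"]*)"?.*', q), "\\1", m[1]))
  }
  sprintf("CDS_%04d", idx)
}

extract_location <- function(loc, genome) {
  strand <- 1L
  while (TRUE) {
    if (grepl("^complement\\(", loc)) {
      strand <- -strand
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    } else if (grepl("^join\\(", loc)) {
      loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    } else break
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  segs <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("complement", p)) {  # per-segment complement: unsupported mix
      return(NULL)
    }
    nums <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (any(is.na(nums))) return(NULL)
    if (length(nums) == 1L) nums <- c(nums, nums)
    nums
  })
  if (any(vapply(segs, is.null, logical(1)))) return(NULL)
  pieces <- vapply(segs, function(se) substr(genome, se[1], se[2]), character(1))
  s <- paste(pieces, collapse = "")
  if (strand < 0L) s <- revcomp(s)
  s
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}
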