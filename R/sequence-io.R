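#' Load coding sequences
#'
#' Reads protein-coding sequences from a multi-record FASTA file or from
#' the CDS features of a GenBank flat file (join() locations are
#' concatenated, reverse-strand features reverse-complemented).
#' Records whose length is not a multiple of 3 or that contain
#' characters outside A/C/G/T (ambiguity codes included) are excluded
#' with a warning: codon-time lookup and folding are undefined on
#' ambiguous bases.  Internal stop codons do not cause exclusion here.
#'
#' @param path file path.
#' @param format `"fasta"` or `"genbank"`.
#' @return An untrimmed `cds_set`.
#' @export
read_cds <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    id <- sub("\\s.*$", "", names(ss))
    seq <- toupper(as.character(ss))
  } else {
    gb <- read_genbank_cds(path)
    id <- gb$id
    seq <- toupper(gb$seq)
  }
  bad <- nchar(seq) %% 3L != 0L | grepl("[^ACGT]", seq)
  if (any(bad))
    warning(sprintf("excluded %d record(s) with frame or alphabet violations: %s",
                    sum(bad), paste(utils::head(id[bad], 5), collapse = ", ")))
  id <- id[!bad]; seq <- seq[!bad]
  if (!length(id)) stop("no valid coding sequences in ", path)
  cds_set(id, seq)
}

#' Write coding sequences as FASTA
#'
#' @param x a `cds_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(x, path) {
  stopifnot(inherits(x, "cds_set"))
  ss <- Biostrings::DNAStringSet(x$seq)
  names(ss) <- x$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a gene id list (one id per line)
#'
#' @param path file path; blank lines and lines starting with `#` are
#'   ignored.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
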