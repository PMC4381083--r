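#' Coding-sequence sets
#'
#' A `cds_set` holds the protein-coding sequences of one genome (or one
#' variant library): gene identifiers, nucleotide sequences over A/C/G/T,
#' and the trim state shared by the whole set.  All downstream profiles
#' (structure, translation speed) are computed over these sequences, and
#' all coordinates in the package are 0-based, half-open.
#'
#' @param id character vector of gene identifiers (unique).
#' @param seq character vector of nucleotide sequences, same length as
#'   `id`; each must use only A/C/G/T and have length a multiple of 3.
#' @param trimmed logical flag: have terminal regions been removed?
#' @param offset_nt integer, number of nucleotides removed from the 5'
#'   end of every sequence (0 when untrimmed, typically 51 when trimmed).
#' @return An object of class `cds_set`.
#' @export
cds_set <- function(id, seq, trimmed = FALSE, offset_nt = 0L) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  stopifnot(length(id) == length(seq))
  if (anyDuplicated(id))
    stop("duplicate gene ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  bad_frame <- nchar(seq) %% 3L != 0L
  bad_alpha <- grepl("[^ACGT]", seq)
  if (any(bad_frame) || any(bad_alpha))
    stop("invalid coding sequences (frame or alphabet): ",
         paste(id[bad_frame | bad_alpha], collapse = ", "))
  structure(list(id = id, seq = seq, trimmed = isTRUE(trimmed),
                 offset_nt = as.integer(offset_nt)),
            class = "cds_set")
}

#' @export
length.cds_set <- function(x) length(x$id)

#' @export
`[.cds_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  cds_set(x$id[i], x$seq[i], trimmed = x$trimmed, offset_nt = x$offset_nt)
}

#' @export
print.cds_set <- function(x, ...) {
  cat(sprintf("cds_set: %d coding sequences (%s, 5' offset %d nt)\n",
              length(x), if (x$trimmed) "trimmed" else "untrimmed",
              x$offset_nt))
  cat(sprintf("  total length %d nt, GC %.3f\n",
              sum(nchar(x$seq)), gc_content(x)))
  invisible(x)
}

# codon strings of gene i, in order
codons_of <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# genetic code, DNA alphabet, from Biostrings
genetic_code <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  gc <- genetic_code()
  sort(names(gc)[gc != "*"])
}

translate_codons <- function(codons) {
  unname(genetic_code()[codons])
}

#' Pooled G/C content
#'
#' Fraction of G and C nucleotides pooled over all sequences of the set
#' (not a per-gene average), as used when comparing genome-wide
#' composition between organisms.
#'
#' @param x a `cds_set`.
#' @return A single number in `[0, 1]`.
#' @export
gc_content <- function(x) {
  stopifnot(inherits(x, "cds_set"))
  if (length(x) == 0L || sum(nchar(x$seq)) == 0L)
    stop("gc_content: empty input")
  all_nt <- paste(x$seq, collapse = "")
  n_gc <- nchar(gsub("[AT]", "", all_nt))
  n_gc / nchar(all_nt)
}

#' Remove terminal coding regions
#'
#' Removes `n_nt` nucleotides (default 51 nt = 17 codons) from both ends
#' of every sequence, excluding translation-initiation and -termination
#' effects from downstream analyses.  Genes too short to retain any
#' sequence (length <= 2 * n_nt) are excluded and reported via the
#' `"excluded"` attribute and a warning; they are not silently dropped.
#'
#' @param x a `cds_set` (untrimmed).
#' @param n_nt nucleotides to remove from each end; must be a multiple
#'   of 3.
#' @return A trimmed `cds_set` with attribute `"excluded"` naming the
#'   genes removed because they were too short.
#' @export
trim_cds <- function(x, n_nt = 51L) {
  stopifnot(inherits(x, "cds_set"))
  n_nt <- as.integer(n_nt)
  if (n_nt %% 3L != 0L) stop("n_nt must be a multiple of 3")
  if (x$trimmed) stop("cds_set is already trimmed")
  len <- nchar(x$seq)
  keep <- len > 2L * n_nt
  if (!all(keep))
    warning(sprintf("%d gene(s) shorter than 2*%d nt excluded: %s",
                    sum(!keep), n_nt,
                    paste(utils::head(x$id[!keep], 5), collapse = ", ")))
  seq <- substring(x$seq[keep], n_nt + 1L, len[keep] - n_nt)
  out <- cds_set(x$id[keep], seq, trimmed = TRUE, offset_nt = n_nt)
  if (length(out) == 0L) stop("no gene survives trimming")
  attr(out, "excluded") <- x$id[!keep]
  out
}

#' Select a gene subset
#'
#' Builds a named subset of a genome either from an explicit id list
#' (e.g. highly expressed genes) or from untrimmed CDS length bins.
#' The standard bins are short (< 500 bp), medium (500-1500 bp,
#' boundaries inclusive) and long (> 1500 bp).
#'
#' @param x a `cds_set`.  Length bins refer to untrimmed lengths, so
#'   pass the untrimmed set when using `bin`.
#' @param ids character vector of member ids (ids absent from the
#'   genome are dropped with a warning), or `NULL`.
#' @param bin one of `"short"`, `"medium"`, `"long"`, or `NULL`.
#' @param name label for the subset; defaults to the rule used.
#' @return A list of class `gene_subset` with elements `name` and
#'   `member_ids`.
#' @export
select_subset <- function(x, ids = NULL, bin = NULL, name = NULL) {
  stopifnot(inherits(x, "cds_set"))
  if (!is.null(ids) && !is.null(bin)) stop("give either ids or bin, not both")
  if (is.null(ids) && is.null(bin)) stop("no subset rule given")
  if (!is.null(ids)) {
    missing <- setdiff(ids, x$id)
    if (length(missing))
      warning(sprintf("%d id(s) not in genome: %s", length(missing),
                      paste(utils::head(missing, 5), collapse = ", ")))
    member <- intersect(ids, x$id)
    if (is.null(name)) name <- "id_list"
  } else {
    bin <- match.arg(bin, c("short", "medium", "long"))
    len <- nchar(x$seq)
    member <- switch(bin,
      short  = x$id[len < 500L],
      medium = x$id[len >= 500L & len <= 1500L],
      long   = x$id[len > 1500L])
    if (is.null(name)) name <- bin
  }
  structure(list(name = name, member_ids = member), class = "gene_subset")
}

#' @export
print.gene_subset <- function(x, ...) {
  cat(sprintf("gene_subset '%s': %d genes\n", x$name, length(x$member_ids)))
  invisible(x)
}
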