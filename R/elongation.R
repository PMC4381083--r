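#' Codon translation-time tables
#'
#' A translation-time table maps each of the 61 sense codons to a
#' predicted translation time in arbitrary units (a.u.), derived from
#' the abundance of the cognate aminoacyl-tRNA pool: the elongation
#' speed of a codon is taken as proportional to the concentration of
#' its cognate aa-tRNA, so scarcer tRNAs mean longer times.  Stop
#' codons are excluded.
#'
#' `read_time_table()` reads a TSV with columns `codon` and `time_au`
#' (an optional `source` column is carried along);
#' `synthetic_time_table()` returns the table packaged for simulation
#' and testing, in which each amino acid's synonymous codons span a
#' wide 25-125 a.u. band while "structure-extreme" codons (only G/C or
#' only A/G letters) sit in a 60-100 a.u. mid-band so that planted
#' structure and planted speed can be varied independently.
#'
#' @param path TSV file path.
#' @return A named numeric vector of class `time_table` (names are
#'   codons, values times in a.u.) with attribute `"source"`.
#' @export
read_time_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("codon", "time_au") %in% names(tab)))
    stop("time table must have columns codon, time_au")
  time_table(stats::setNames(tab$time_au, toupper(tab$codon)),
             source = if ("source" %in% names(tab)) tab$source[1] else
               basename(path))
}

#' @rdname read_time_table
#' @param times named numeric vector codon -> time (a.u.).
#' @param source free-text provenance label.
#' @export
time_table <- function(times, source = "user") {
  codons <- names(times)
  if (anyDuplicated(codons))
    stop("duplicate codon(s): ",
         paste(unique(codons[duplicated(codons)]), collapse = ", "))
  missing <- setdiff(sense_codons(), codons)
  if (length(missing))
    stop("missing sense codon(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(codons, sense_codons())
  if (length(extra))
    stop("non-sense codon(s) in table: ", paste(extra, collapse = ", "))
  if (any(!is.finite(times)) || any(times <= 0))
    stop("non-positive time for codon(s): ",
         paste(codons[!is.finite(times) | times <= 0], collapse = ", "))
  structure(as.numeric(times)[match(sense_codons(), codons)],
            names = sense_codons(), source = source, class = "time_table")
}

#' @rdname read_time_table
#' @export
synthetic_time_table <- function() {
  read_time_table(system.file("extdata", "times_synthetic.tsv",
                              package = "codontrade", mustWork = TRUE))
}

#' @export
print.time_table <- function(x, ...) {
  cat(sprintf("time_table (%d sense codons, source '%s'): %.1f-%.1f a.u.\n",
              length(x), attr(x, "source"), min(x), max(x)))
  invisible(x)
}

#' Per-codon translation-time profile
#'
#' Looks up the instantaneous translation time of every codon of a
#' coding sequence.  Genes containing internal stop codons cannot be
#' profiled and yield `NULL` with a warning (skip-with-warning), since
#' stop codons carry no tRNA-abundance time.
#'
#' @param seq one nucleotide sequence (length a multiple of 3).
#' @param table a `time_table`.
#' @param gene_id identifier used in messages and the result.
#' @return A list of class `speed_profile` with elements `gene_id`,
#'   `codon_times` (a.u., one per codon) and `smoothed_times`
#'   (`NULL` until [smooth_profile()] is applied), or `NULL` if the
#'   gene contains a stop codon.
#' @export
codon_time_profile <- function(seq, table, gene_id = "gene") {
  stopifnot(inherits(table, "time_table"))
  cods <- codons_of(seq)
  hit <- match(cods, names(table))
  if (anyNA(hit)) {
    warning("gene ", gene_id, " contains stop or unknown codon(s); skipped")
    return(NULL)
  }
  structure(list(gene_id = gene_id, codon_times = unname(table[hit]),
                 smoothed_times = NULL),
            class = "speed_profile")
}

#' Speed profiles for a genome
#'
#' @param x a `cds_set` (normally trimmed).
#' @param table a `time_table`.
#' @return Named list of `speed_profile` objects; genes with internal
#'   stops are dropped (with a warning from [codon_time_profile()]).
#' @export
speed_profiles <- function(x, table) {
  stopifnot(inherits(x, "cds_set"))
  out <- mapply(codon_time_profile, x$seq, gene_id = x$id,
                MoreArgs = list(table = table), SIMPLIFY = FALSE)
  names(out) <- x$id
  out[!vapply(out, is.null, logical(1))]
}

#' Smooth a speed profile over the ribosome footprint
#'
#' Smooths instantaneous codon times with a centered sliding window of
#' `window_nt` nucleotides (default 27 nt = 9 codons, the approximate
#' ribosome footprint), so that clusters of slow codons show up as
#' local slowdowns.  At the profile ends the window is truncated to
#' the available codons (the mean is over fewer codons) so every codon
#' retains a smoothed value.
#'
#' @param profile a `speed_profile`.
#' @param window_nt window width in nucleotides; must be a positive
#'   multiple of 3 with an odd number of codons.
#' @return The profile with `smoothed_times` filled.
#' @export
smooth_profile <- function(profile, window_nt = 27L) {
  stopifnot(inherits(profile, "speed_profile"))
  window_nt <- as.integer(window_nt)
  if (window_nt <= 0L || window_nt %% 3L != 0L)
    stop("window_nt must be a positive multiple of 3")
  wc <- window_nt %/% 3L
  if (wc %% 2L == 0L) stop("window must span an odd number of codons")
  h <- (wc - 1L) %/% 2L
  v <- profile$codon_times
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  profile$smoothed_times <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  profile$window_nt <- window_nt
  profile
}

#' @export
print.speed_profile <- function(x, ...) {
  cat(sprintf("speed_profile '%s': %d codons, mean time %.1f a.u.%s\n",
              x$gene_id, length(x$codon_times), mean(x$codon_times),
              if (is.null(x$smoothed_times)) "" else
                sprintf(", smoothed (%d nt)", x$window_nt)))
  invisible(x)
}

#' Export speed profiles as TSV
#'
#' Columns: gene_id, codon_index (0-based), codon, time_au,
#' smoothed_time_au (NA when not smoothed).
#'
#' @param profiles named list of `speed_profile` objects.
#' @param x the `cds_set` the profiles were computed from (for codon
#'   strings).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_speed_profiles <- function(profiles, x, path) {
  rows <- lapply(profiles, function(p) {
    cods <- codons_of(x$seq[match(p$gene_id, x$id)])
    data.frame(gene_id = p$gene_id,
               codon_index = seq_along(p$codon_times) - 1L,
               codon = cods,
               time_au = p$codon_times,
               smoothed_time_au = if (is.null(p$smoothed_times)) NA_real_
                                  else p$smoothed_times,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
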