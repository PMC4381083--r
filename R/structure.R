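#' Structure classification thresholds
#'
#' Encodes the rule that classifies each nucleotide as part of high or
#' low secondary structure.  For experimental PARS-style scores the
#' split is at 0 (high: score > 0, low: score <= 0).  For predicted
#' window MFE the defaults are high: MFE < -35 kcal/mol and low:
#' MFE > -20 kcal/mol, leaving values in between unclassified.  A
#' minimum region length (`min_len_nt`, default 20 nt) is required for
#' a run of uniformly classified nucleotides to count as a region.
#'
#' @param kind `"pars"` or `"mfe"`.
#' @param high_cut,low_cut classification cut-offs; defaults depend on
#'   `kind` (PARS: 0 and 0; MFE: -35 and -20 kcal/mol).
#' @param min_len_nt minimum region length in nucleotides.
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(kind = c("pars", "mfe"), high_cut = NULL,
                           low_cut = NULL, min_len_nt = 20L) {
  kind <- match.arg(kind)
  if (is.null(high_cut)) high_cut <- if (kind == "pars") 0 else -35
  if (is.null(low_cut)) low_cut <- if (kind == "pars") 0 else -20
  if (kind == "mfe" && !(high_cut < low_cut))
    stop("for kind='mfe', high_cut must be below low_cut")
  if (kind == "pars" && high_cut < low_cut)
    stop("for kind='pars', high_cut must be >= low_cut")
  stopifnot(min_len_nt >= 1)
  structure(list(kind = kind, high_cut = high_cut, low_cut = low_cut,
                 min_len_nt = as.integer(min_len_nt)),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("threshold_rule (%s): high %s %g, low %s %g, min length %d nt\n",
              x$kind,
              if (x$kind == "pars") ">" else "<", x$high_cut,
              if (x$kind == "pars") "<=" else ">", x$low_cut,
              x$min_len_nt))
  invisible(x)
}

structure_profile <- function(gene_id, kind, values) {
  stopifnot(kind %in% c("pars", "mfe"))
  if (kind == "mfe" && any(values > 0, na.rm = TRUE))
    stop("MFE profile contains positive values (gene ", gene_id, ")")
  structure(list(gene_id = gene_id, kind = kind,
                 values = as.numeric(values)),
            class = "structure_profile")
}

#' @export
print.structure_profile <- function(x, ...) {
  nd <- sum(!is.na(x$values))
  cat(sprintf("structure_profile '%s' (%s): %d nt, %d defined\n",
              x$gene_id, x$kind, length(x$values), nd))
  invisible(x)
}

#' Sliding-window minimum free energy profiles
#'
#' Computes per-nucleotide structure profiles by folding a centered
#' sliding window (default 101 nt, step 1) around every position of
#' every sequence.  The window MFE is assigned to the center
#' nucleotide; positions within half a window of either end are
#' undefined (`NA`) rather than computed with truncated windows, which
#' would bias MFE upward.  Sequences shorter than the window yield
#' all-undefined profiles.
#'
#' @param x a `cds_set` (normally trimmed).
#' @param window_nt odd window width in nucleotides.
#' @param engine an [mfe_engine()].
#' @return A named list of `structure_profile` objects (kind `"mfe"`),
#'   one per gene.
#' @export
sliding_window_mfe <- function(x, window_nt = 101L, engine = mfe_engine()) {
  stopifnot(inherits(x, "cds_set"), inherits(engine, "mfe_engine"))
  window_nt <- as.integer(window_nt)
  if (window_nt %% 2L == 0L) stop("window_nt must be odd")
  out <- vector("list", length(x))
  names(out) <- x$id
  for (i in seq_along(x$id)) {
    vals <- tryCatch(engine$fold_windows(x$seq[i], window_nt),
                     error = function(e)
                       stop("folding failed for gene ", x$id[i], ": ",
                            conditionMessage(e)))
    out[[i]] <- structure_profile(x$id[i], "mfe", vals)
  }
  out
}

#' Load experimental per-nucleotide structure scores
#'
#' Reads a PARS-style score table (TSV with header columns `gene_id`,
#' `position`, `score`; positions 0-based on the untrimmed CDS) and
#' aligns the scores to the trimmed coordinates of the given genes by
#' subtracting `offset_nt`.  Positions falling outside the trimmed
#' range are dropped; unscored positions are undefined.
#'
#' @param path score file path.
#' @param x a `cds_set` giving the (trimmed) sequences the profiles
#'   must align to.
#' @param offset_nt nucleotides trimmed from the 5' end (defaults to
#'   the set's own offset).
#' @return A named list of `structure_profile` objects (kind `"pars"`),
#'   one per gene of `x`.
#' @export
read_pars_scores <- function(path, x, offset_nt = x$offset_nt) {
  stopifnot(inherits(x, "cds_set"))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "position", "score")
  if (!all(need %in% names(tab)))
    stop("score file must have columns gene_id, position, score")
  bad <- !is.finite(tab$position) | !is.finite(tab$score)
  if (any(bad))
    stop("malformed score row(s) at line(s): ",
         paste(utils::head(which(bad) + 1L, 5), collapse = ", "))
  unknown <- setdiff(unique(tab$gene_id), x$id)
  if (length(unknown)) {
    warning(sprintf("%d gene(s) in score file absent from genome, skipped: %s",
                    length(unknown),
                    paste(utils::head(unknown, 5), collapse = ", ")))
    tab <- tab[tab$gene_id %in% x$id, , drop = FALSE]
  }
  out <- vector("list", length(x))
  names(out) <- x$id
  idx <- split(seq_len(nrow(tab)), tab$gene_id)
  for (i in seq_along(x$id)) {
    n <- nchar(x$seq[i])
    vals <- rep(NA_real_, n)
    rows <- idx[[x$id[i]]]
    if (!is.null(rows)) {
      pos <- tab$position[rows] - offset_nt  # to trimmed 0-based
      ok <- pos >= 0L & pos < n
      vals[pos[ok] + 1L] <- tab$score[rows][ok]
    }
    out[[i]] <- structure_profile(x$id[i], "pars", vals)
  }
  out
}

classify_positions <- function(values, rule) {
  cls <- rep(NA_character_, length(values))
  def <- !is.na(values)
  if (rule$kind == "pars") {
    cls[def & values > rule$high_cut] <- "high"
    cls[def & values <= rule$low_cut] <- "low"
  } else {
    cls[def & values < rule$high_cut] <- "high"
    cls[def & values > rule$low_cut] <- "low"
  }
  cls
}

#' Extract maximal high/low-structure regions
#'
#' Finds all maximal runs of consecutive defined positions uniformly
#' classified as high (or low) structure under the rule, and keeps
#' those of at least `rule$min_len_nt` nucleotides.  Undefined
#' positions and (for MFE rules) positions in the unclassified band
#' between the two cut-offs break runs.  Coordinates are 0-based,
#' half-open, on the profile's (trimmed) sequence.
#'
#' @param profile a `structure_profile`.
#' @param rule a [threshold_rule()] of matching kind.
#' @return A data.frame with columns `gene_id`, `start`, `end`,
#'   `klass`, `length` ordered by `start` (possibly zero rows).
#' @export
extract_regions <- function(profile, rule) {
  stopifnot(inherits(profile, "structure_profile"),
            inherits(rule, "threshold_rule"))
  if (profile$kind != rule$kind)
    stop("profile kind '", profile$kind, "' does not match rule kind '",
         rule$kind, "'")
  cls <- classify_positions(profile$values, rule)
  empty <- data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), klass = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (!length(cls)) return(empty)
  r <- rle(ifelse(is.na(cls), "none", cls))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  keep <- r$values %in% c("high", "low") & r$lengths >= rule$min_len_nt
  if (!any(keep)) return(empty)
  out <- data.frame(gene_id = profile$gene_id,
                    start = starts[keep], end = ends[keep],
                    klass = r$values[keep],
                    length = r$lengths[keep],
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Extract regions for a list of profiles
#'
#' @param profiles named list of `structure_profile` objects.
#' @param rule a [threshold_rule()].
#' @return One data.frame binding the per-gene region tables.
#' @export
extract_all_regions <- function(profiles, rule) {
  do.call(rbind, c(lapply(profiles, extract_regions, rule = rule),
                   list(make.row.names = FALSE)))
}

#' Write regions as BED-like TSV
#'
#' Columns: gene_id, start, end, class, length (0-based half-open).
#'
#' @param regions region data.frame from [extract_all_regions()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
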