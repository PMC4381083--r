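#' Assign codons to structure regions
#'
#' A codon k occupies nucleotides `[3k, 3k+3)` of the trimmed
#' sequence.  Under the default `"contain"` mode it is assigned to a
#' region's class only when all three nucleotides lie inside the
#' region; codons straddling a region boundary stay unassigned.  The
#' `"majority"` mode (>= 2 nt inside) is available for sensitivity
#' analysis.
#'
#' @param regions region data.frame for one gene (see
#'   [extract_regions()]).
#' @param n_codons number of codons in the gene's trimmed sequence.
#' @param mode `"contain"` or `"majority"`.
#' @return A list with elements `high` and `low`: 0-based codon
#'   indices.
#' @export
assign_codons <- function(regions, n_codons, mode = c("contain", "majority")) {
  mode <- match.arg(mode)
  out <- list(high = integer(0), low = integer(0))
  if (is.null(regions) || nrow(regions) == 0L) return(out)
  for (kl in c("high", "low")) {
    rr <- regions[regions$klass == kl, , drop = FALSE]
    if (nrow(rr) > 1L) {
      o <- order(rr$start)
      if (any(rr$start[o][-1] < rr$end[o][-nrow(rr)]))
        stop("overlapping ", kl, " regions in gene ", rr$gene_id[1])
    }
    idx <- integer(0)
    for (i in seq_len(nrow(rr))) {
      if (mode == "contain") {
        k0 <- ceiling(rr$start[i] / 3)           # first codon fully inside
        k1 <- floor(rr$end[i] / 3) - 1L          # last codon fully inside
      } else {
        # majority: at least 2 of the 3 nt inside [start, end)
        k0 <- ceiling((rr$start[i] - 1L) / 3)
        k1 <- floor((rr$end[i] + 1L) / 3) - 1L
      }
      k1 <- min(k1, n_codons - 1L)
      k0 <- max(k0, 0L)
      if (k1 >= k0) idx <- c(idx, k0:k1)
    }
    out[[kl]] <- sort(unique(idx))
  }
  out
}

#' Trade-off statistic for two codon-time pools
#'
#' Summarizes the codon translation times found in high- versus
#' low-structure regions: medians, interquartile ranges (quartiles by
#' linear interpolation), the time difference
#' `delta_t = median_low - median_high` (positive when a trade-off is
#' present), the complementary sign convention
#' `tradeoff_score = median_high - median_low` (more negative =
#' stronger trade-off), and a two-sided Mann-Whitney p-value.
#'
#' If either pool is empty the result is an NA row carrying the
#' counts.
#'
#' @param times_high,times_low codon translation times (a.u.) pooled
#'   from high- and low-structure regions.
#' @param label free-text label (organism / subset / R_l).
#' @param n_regions_high,n_regions_low region counts to report.
#' @return An object of class `tradeoff_result`.
#' @export
tradeoff_statistic <- function(times_high, times_low, label = "",
                               n_regions_high = NA_integer_,
                               n_regions_low = NA_integer_) {
  nh <- length(times_high); nl <- length(times_low)
  if (nh == 0L || nl == 0L) {
    res <- list(label = label, n_regions_high = n_regions_high,
                n_regions_low = n_regions_low,
                n_codons_high = nh, n_codons_low = nl,
                median_high = NA_real_, median_low = NA_real_,
                iqr_high = c(NA_real_, NA_real_),
                iqr_low = c(NA_real_, NA_real_),
                delta_t = NA_real_, tradeoff_score = NA_real_,
                p_value = NA_real_)
    return(structure(res, class = "tradeoff_result"))
  }
  mh <- stats::median(times_high)
  ml <- stats::median(times_low)
  qh <- stats::quantile(times_high, c(0.25, 0.75), names = FALSE, type = 7)
  ql <- stats::quantile(times_low, c(0.25, 0.75), names = FALSE, type = 7)
  mw <- mann_whitney_test(times_high, times_low)
  structure(list(label = label,
                 n_regions_high = n_regions_high,
                 n_regions_low = n_regions_low,
                 n_codons_high = nh, n_codons_low = nl,
                 median_high = mh, median_low = ml,
                 iqr_high = qh, iqr_low = ql,
                 delta_t = ml - mh, tradeoff_score = mh - ml,
                 p_value = mw$p_value),
            class = "tradeoff_result")
}

#' @export
print.tradeoff_result <- function(x, ...) {
  cat("codon translation-time trade-off",
      if (nzchar(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat(sprintf("  regions: %s high, %s low; codons: %d high, %d low\n",
              format(x$n_regions_high), format(x$n_regions_low),
              x$n_codons_high, x$n_codons_low))
  if (is.na(x$median_high) || is.na(x$median_low)) {
    cat("  one structure class is empty: statistics undefined (NA)\n")
    return(invisible(x))
  }
  cat(sprintf("  median time high %.1f (%.1f, %.1f), low %.1f (%.1f, %.1f) a.u.\n",
              x$median_high, x$iqr_high[1], x$iqr_high[2],
              x$median_low, x$iqr_low[1], x$iqr_low[2]))
  cat(sprintf("  delta_t = %.2f a.u. (trade-off score %.2f), Mann-Whitney p = %.3g\n",
              x$delta_t, x$tradeoff_score, x$p_value))
  invisible(x)
}

#' @export
summary.tradeoff_result <- function(object, ...) {
  data.frame(label = object$label,
             n_regions_high = object$n_regions_high,
             n_regions_low = object$n_regions_low,
             n_codons_high = object$n_codons_high,
             n_codons_low = object$n_codons_low,
             median_high = object$median_high,
             q1_high = object$iqr_high[1], q3_high = object$iqr_high[2],
             median_low = object$median_low,
             q1_low = object$iqr_low[1], q3_low = object$iqr_low[2],
             delta_t = object$delta_t,
             tradeoff_score = object$tradeoff_score,
             p_value = object$p_value,
             stringsAsFactors = FALSE)
}

# pool codon times (or per-region mean times) by structure class
pool_times <- function(x, profiles, table, rule, subset = NULL,
                       pool = c("codon", "region"), mode = "contain") {
  pool <- match.arg(pool)
  ids <- x$id
  if (!is.null(subset)) {
    if (inherits(subset, "gene_subset")) subset <- subset$member_ids
    ids <- intersect(ids, subset)
  }
  ids <- sort(ids)  # order-independence
  high <- list(); low <- list()
  n_reg <- c(high = 0L, low = 0L)
  for (id in ids) {
    p <- profiles[[id]]
    if (is.null(p)) next
    seq <- x$seq[match(id, x$id)]
    sp <- codon_time_profile(seq, table, gene_id = id)
    if (is.null(sp)) next
    regions <- extract_regions(p, rule)
    n_reg["high"] <- n_reg["high"] + sum(regions$klass == "high")
    n_reg["low"] <- n_reg["low"] + sum(regions$klass == "low")
    asg <- assign_codons(regions, length(sp$codon_times), mode = mode)
    if (pool == "codon") {
      high[[id]] <- sp$codon_times[asg$high + 1L]
      low[[id]] <- sp$codon_times[asg$low + 1L]
    } else {
      rr <- regions[regions$length >= rule$min_len_nt, , drop = FALSE]
      hm <- c(); lm <- c()
      for (i in seq_len(nrow(rr))) {
        a <- assign_codons(rr[i, , drop = FALSE], length(sp$codon_times),
                           mode = mode)
        kl <- rr$klass[i]
        ks <- a[[kl]]
        if (length(ks))
          if (kl == "high") hm <- c(hm, mean(sp$codon_times[ks + 1L]))
          else lm <- c(lm, mean(sp$codon_times[ks + 1L]))
      }
      high[[id]] <- hm; low[[id]] <- lm
    }
  }
  list(high = unlist(high, use.names = FALSE),
       low = unlist(low, use.names = FALSE),
       n_regions = n_reg)
}

#' Genome-wide trade-off between codon speed and mRNA structure
#'
#' Pools codon translation times across all genes of a subset into a
#' high-structure pool and a low-structure pool (or, with
#' `pool = "region"`, pools per-region mean times), then computes the
#' trade-off statistic.  Deterministic given its inputs and invariant
#' to gene input order.
#'
#' @param x a trimmed `cds_set`.
#' @param profiles named list of `structure_profile` objects aligned to
#'   `x`.
#' @param table a `time_table`.
#' @param rule a [threshold_rule()].
#' @param subset optional `gene_subset` (or character vector of ids).
#' @param pool `"codon"` (default: pool individual codon times, as for
#'   a genome-wide region-length table) or `"region"` (pool per-region
#'   average times, as for region-distribution comparisons).
#' @param mode codon-assignment mode, see [assign_codons()].
#' @param label label stored in the result.
#' @return A `tradeoff_result`.
#' @export
genome_tradeoff <- function(x, profiles, table, rule, subset = NULL,
                            pool = c("codon", "region"), mode = "contain",
                            label = "") {
  stopifnot(inherits(x, "cds_set"))
  pools <- pool_times(x, profiles, table, rule, subset, pool, mode)
  tradeoff_statistic(pools$high, pools$low, label = label,
                     n_regions_high = unname(pools$n_regions["high"]),
                     n_regions_low = unname(pools$n_regions["low"]))
}

#' Codon usage by structure class
#'
#' Counts codon occurrences over all codons assigned to high- and
#' low-structure regions, normalizes within each class, and groups
#' fractions per amino acid with codons ordered fastest to slowest
#' according to the active time table.
#'
#' @inheritParams genome_tradeoff
#' @return A data.frame with columns `klass`, `amino_acid`, `codon`,
#'   `rank_by_speed`, `count`, `fraction` (fraction of all codons in
#'   the class).
#' @export
codon_usage_by_region <- function(x, profiles, table, rule, subset = NULL,
                                  mode = "contain") {
  stopifnot(inherits(x, "cds_set"))
  ids <- x$id
  if (!is.null(subset)) {
    if (inherits(subset, "gene_subset")) subset <- subset$member_ids
    ids <- intersect(ids, subset)
  }
  counts <- list(high = integer(0), low = integer(0))
  for (id in sort(ids)) {
    p <- profiles[[id]]
    if (is.null(p)) next
    seq <- x$seq[match(id, x$id)]
    cods <- codons_of(seq)
    regions <- extract_regions(p, rule)
    asg <- assign_codons(regions, length(cods), mode = mode)
    for (kl in c("high", "low")) {
      tb <- table(cods[asg[[kl]] + 1L])
      cnt <- counts[[kl]]
      for (cd in names(tb)) cnt[cd] <- (if (cd %in% names(cnt)) cnt[cd] else 0L) + tb[[cd]]
      counts[[kl]] <- cnt
    }
  }
  aa <- translate_codons(sense_codons())
  speed_rank <- stats::ave(unclass(table)[sense_codons()], aa,
                           FUN = function(v) rank(v, ties.method = "first"))
  out <- list()
  for (kl in c("high", "low")) {
    cnt <- counts[[kl]]
    total <- sum(cnt)
    if (total == 0L) next
    full <- stats::setNames(integer(length(sense_codons())), sense_codons())
    full[names(cnt)] <- cnt
    out[[kl]] <- data.frame(klass = kl, amino_acid = aa,
                            codon = sense_codons(),
                            rank_by_speed = as.integer(speed_rank),
                            count = as.integer(full),
                            fraction = as.numeric(full) / total,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res))
    res <- data.frame(klass = character(0), amino_acid = character(0),
                      codon = character(0), rank_by_speed = integer(0),
                      count = integer(0), fraction = numeric(0))
  res[order(res$klass, res$amino_acid, res$rank_by_speed), , drop = FALSE]
}

#' Amino-acid composition by structure class
#'
#' @inheritParams genome_tradeoff
#' @return A data.frame with columns `klass`, `amino_acid`, `fraction`
#'   (fractions sum to 1 within each non-empty class).
#' @export
aa_composition_by_region <- function(x, profiles, rule, subset = NULL,
                                     mode = "contain") {
  usage <- codon_usage_by_region(x, profiles, table = uniform_time_table(),
                                 rule = rule, subset = subset, mode = mode)
  if (nrow(usage) == 0L)
    return(data.frame(klass = character(0), amino_acid = character(0),
                      fraction = numeric(0)))
  agg <- stats::aggregate(cbind(count = usage$count),
                          by = list(klass = usage$klass,
                                    amino_acid = usage$amino_acid),
                          FUN = sum)
  tot <- stats::ave(agg$count, agg$klass, FUN = sum)
  agg$fraction <- agg$count / tot
  agg$count <- NULL
  agg[order(agg$klass, agg$amino_acid), , drop = FALSE]
}

#' Uniform (null) time table
#'
#' All 61 sense codons get time 1 a.u.; useful as a null table and for
#' composition counts where speed is irrelevant.
#'
#' @export
uniform_time_table <- function() {
  time_table(stats::setNames(rep(1, 61), sense_codons()), source = "uniform")
}

#' Region-length trade-off table
#'
#' Runs [genome_tradeoff()] for each minimum region length in `r_l`
#' (and optionally each subset) and assembles a report table with one
#' row per combination.
#'
#' @inheritParams genome_tradeoff
#' @param r_l integer vector of minimum region lengths (nt).
#' @param subsets named list of `gene_subset` objects (or `NULL` for
#'   the whole genome only).
#' @return A data.frame, one row per subset x R_l.
#' @export
tradeoff_table <- function(x, profiles, table, r_l = c(10L, 20L, 30L),
                           kind = c("pars", "mfe"), high_cut = NULL,
                           low_cut = NULL, subsets = NULL,
                           pool = "codon") {
  kind <- match.arg(kind)
  if (is.null(subsets)) subsets <- list(all = NULL)
  rows <- list()
  for (sn in names(subsets)) {
    for (rl in r_l) {
      rule <- threshold_rule(kind, high_cut, low_cut, min_len_nt = rl)
      res <- genome_tradeoff(x, profiles, table, rule,
                             subset = subsets[[sn]], pool = pool,
                             label = sprintf("%s/R_l=%d", sn, rl))
      df <- summary(res)
      df <- cbind(subset = sn, r_l = rl, df)
      rows[[length(rows) + 1L]] <- df
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
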