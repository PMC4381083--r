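# Independent brute-force oracles used across the suite.  These
# deliberately take the slow, obvious route so they share no code with
# the implementation paths they check.

# All maximal runs of uniformly classified positions of length >=
# min_len, by exhaustive scanning of every interval.
oracle_regions <- function(values, rule) {
  n <- length(values)
  klass_of <- function(v) {
    if (is.na(v)) return(NA_character_)
    if (rule$kind == "pars") {
      if (v > rule$high_cut) "high" else "low"
    } else {
      if (v < rule$high_cut) "high"
      else if (v > rule$low_cut) "low"
      else NA_character_
    }
  }
  cls <- vapply(values, klass_of, character(1))
  out <- list()
  for (kl in c("high", "low")) {
    ok <- !is.na(cls) & cls == kl
    for (s in seq_len(n)) {
      if (!ok[s]) next
      if (s > 1 && ok[s - 1]) next         # not a run start
      e <- s
      while (e < n && ok[e + 1L]) e <- e + 1L
      if (e - s + 1L >= rule$min_len_nt)
        out[[length(out) + 1]] <- data.frame(start = s - 1L, end = e,
                                             klass = kl,
                                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      klass = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$klass), , drop = FALSE]
}

# Exact two-sided Mann-Whitney p by enumerating group assignments and
# counting exceeding pairs directly (ties count 1/2).
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  gt <- outer(pool, pool, ">") + 0.5 * outer(pool, pool, "==")
  rowtot <- rowSums(gt)
  u_of <- function(a) sum(rowtot[a]) - sum(gt[a, a])
  u_obs <- u_of(seq_len(n))
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, u_of)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Exact two-sided one-sample Wilcoxon signed-rank p by looping over all
# 2^k sign patterns of the observed absolute-difference ranks.
oracle_signed_rank_p <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  k <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^k)
  for (b in 0:(2^k - 1)) {
    bits <- as.integer(intToBits(b))[seq_len(k)] == 1L
    vs[b + 1] <- sum(r[bits])
  }
  min(1, 2 * min(mean(vs <= v_obs + 1e-9), mean(vs >= v_obs - 1e-9)))
}

# centered windowed mean with truncation at the ends, the slow way
oracle_windowed_mean <- function(v, half) {
  vapply(seq_along(v), function(i) {
    lo <- max(1, i - half); hi <- min(length(v), i + half)
    mean(v[lo:hi])
  }, numeric(1))
}
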