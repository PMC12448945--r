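# Brute-force reference implementations, deliberately independent of the
# package's vectorized/IRanges-backed code paths.

# per-bp membership vector for one chromosome of an interval set
oracle_bp_set <- function(iv, chrom, chrom_len) {
  v <- rep(FALSE, chrom_len)
  sub <- iv[iv$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    if (sub$end[i] > sub$start[i]) v[(sub$start[i] + 1):sub$end[i]] <- TRUE
  }
  v
}

# bp-set -> minimal interval list (0-based half-open)
oracle_set_to_iv <- function(v, chrom) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- which(r$values)
  if (!length(keep)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep])
}

oracle_merge <- function(iv, gap, chroms, chrom_len) {
  out <- list()
  for (ch in chroms) {
    v <- oracle_bp_set(iv, ch, chrom_len)
    if (gap > 0) {
      # close gaps <= gap between covered stretches
      r <- rle(v)
      ends <- cumsum(r$lengths)
      for (k in seq_along(r$values)) {
        if (!r$values[k] && k > 1 && k < length(r$values) && r$lengths[k] <= gap) {
          v[(ends[k] - r$lengths[k] + 1):ends[k]] <- TRUE
        }
      }
    }
    out[[ch]] <- oracle_set_to_iv(v, ch)
  }
  do.call(rbind, out)
}

oracle_intersect <- function(a, b, chroms, chrom_len) {
  out <- list()
  for (ch in chroms) {
    v <- oracle_bp_set(a, ch, chrom_len) & oracle_bp_set(b, ch, chrom_len)
    out[[ch]] <- oracle_set_to_iv(v, ch)
  }
  do.call(rbind, out)
}

random_interval_set <- function(chroms, chrom_len, n) {
  s <- sort(sample.int(chrom_len - 1, n))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = pmin(s + sample.int(500, n), chrom_len))
}

# direct per-site scan of window het/missing counts
oracle_window_counts <- function(sites, windows, absent = "missing") {
  res <- windows[, c("chrom", "start", "end")]
  res$n_het <- 0L
  res$n_missing <- 0L
  for (i in seq_len(nrow(res))) {
    in_w <- sites$chrom == res$chrom[i] &
      sites$pos - 1 >= res$start[i] & sites$pos - 1 < res$end[i]
    gts <- sites$gt[in_w]
    res$n_het[i] <- sum(gts == 1L, na.rm = TRUE)
    res$n_missing[i] <- if (absent == "missing") {
      (res$end[i] - res$start[i]) - sum(!is.na(gts))
    } else sum(is.na(gts))
  }
  res
}

# exhaustive maximal-run scan for ROH calling on one chromosome
oracle_roh_scan <- function(win, threshold, min_windows, min_length, max_miss) {
  ok <- win$het < threshold & win$missing_prop <= max_miss
  segs <- list()
  i <- 1
  while (i <= length(ok)) {
    if (ok[i]) {
      j <- i
      while (j < length(ok) && ok[j + 1]) j <- j + 1
      if ((j - i + 1) >= min_windows && (win$end[j] - win$start[i]) >= min_length) {
        segs[[length(segs) + 1]] <- c(win$start[i], win$end[j], j - i + 1)
      }
      i <- j + 1
    } else i <- i + 1
  }
  segs
}

# upper-tail hypergeometric enumeration for a 2x2 table (a,b,c,d)
oracle_fisher_greater <- function(a, b, c, d) {
  K <- a + c; N <- a + b + c + d; n <- a + b
  ks <- max(a, 0):min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_ranksum_two_sided <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals); nx <- length(x)
  idx <- utils::combn(n, nx)
  stat <- function(ix) sum(rank(vals)[ix])
  obs <- stat(seq_len(nx))
  stats <- apply(idx, 2, stat)
  p_low <- mean(stats <= obs)
  p_high <- mean(stats >= obs)
  min(1, 2 * min(p_low, p_high))
}
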