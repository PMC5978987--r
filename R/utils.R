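# Internal helpers shared across modules.

# GRanges from a data.frame with 0-based half-open chrom/start/end.
.gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

# For each interval of a, whether any interval of b overlaps it (>= 1 bp,
# half-open coordinates). Base-R sorted scan: an interval of b overlaps
# (s, e) iff b$start < e and b$end > s; with b sorted by start, the
# candidates are the first k starts below e, and max(end[1..k]) decides.
.overlaps_any <- function(a, b) {
  out <- logical(nrow(a))
  if (nrow(a) == 0 || is.null(b) || nrow(b) == 0) return(out)
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    if (length(bi) == 0) next
    o <- order(b$start[bi])
    starts <- b$start[bi][o]
    cmax_end <- cummax(b$end[bi][o])
    k <- findInterval(a$end[ai] - 1, starts)
    hit <- k >= 1
    hit[hit] <- cmax_end[k[hit]] > a$start[ai][hit]
    out[ai] <- hit
  }
  out
}

.find_overlaps <- function(a, b) {
  suppressWarnings(GenomicRanges::findOverlaps(.gr(a), .gr(b)))
}

.row_medians <- function(m, na.rm = FALSE) apply(m, 1, stats::median, na.rm = na.rm)

.row_mads <- function(m, center = NULL, na.rm = FALSE) {
  if (is.null(center)) center <- .row_medians(m, na.rm = na.rm)
  apply(abs(m - center), 1, stats::median, na.rm = na.rm) * 1.4826
}

# All overlapping pairs (>= 1 bp) among intervals of one chromosome-less
# set, as index pairs (from < to in start order); simple sweep, O(n log n
# + pairs).
.overlap_pairs <- function(start, end, chrom = NULL) {
  n <- length(start)
  if (is.null(chrom)) chrom <- rep("*", n)
  from <- integer(0); to <- integer(0)
  for (ch in unique(chrom)) {
    ci <- which(chrom == ch)
    o <- ci[order(start[ci])]
    s <- start[o]; e <- end[o]
    m <- length(o)
    for (i in seq_len(max(m - 1, 0))) {
      j <- i + 1
      while (j <= m && s[j] < e[i]) {
        from <- c(from, o[i]); to <- c(to, o[j])
        j <- j + 1
      }
    }
  }
  list(from = from, to = to)
}

# Reciprocal overlap between interval (s1,e1) and (s2,e2), both half-open.
.reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1), ov / (e2 - s2)))
}

# Connected components by union-find over an edge list on 1..n.
.components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Strip a leading "chr" prefix for contig-name harmonization.
.strip_chr <- function(x) sub("^chr", "", x)

# Empirical p-value with the +1 convention.
.perm_p <- function(null, observed, side = c("greater", "two.sided")) {
  side <- match.arg(side)
  if (side == "greater") (1 + sum(null >= observed)) / (length(null) + 1)
  else (1 + sum(abs(null) >= abs(observed))) / (length(null) + 1)
}

# Kolmogorov-Smirnov distance of a numeric vector to N(0,1).
.ks_normal <- function(z) {
  z <- sort(z[is.finite(z)])
  n <- length(z)
  if (n == 0) return(NA_real_)
  ecdf_hi <- seq_len(n) / n
  ecdf_lo <- (seq_len(n) - 1) / n
  p <- stats::pnorm(z)
  max(pmax(abs(ecdf_hi - p), abs(ecdf_lo - p)))
}
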