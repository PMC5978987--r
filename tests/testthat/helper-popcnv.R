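# Shared helpers for the test suite: small fixture builders and
# independent brute-force oracles. Oracles are deliberately naive
# re-implementations used to cross-check the package's vectorized code.

# Reciprocal overlap of two half-open intervals.
ro_pair <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2)
  if (ov <= 0) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

# Recall / precision of calls against a truth table at >= 50% reciprocal
# overlap, per (sample, event).
match_rates <- function(calls, truth, ro = 0.5) {
  hit_truth <- vapply(seq_len(nrow(truth)), function(i) {
    cc <- calls[calls$sample == truth$sample[i] & calls$chrom == truth$chrom[i], ]
    nrow(cc) > 0 && any(vapply(seq_len(nrow(cc)), function(j)
      ro_pair(truth$start[i], truth$end[i], cc$start[j], cc$end[j]),
      numeric(1)) >= ro)
  }, logical(1))
  hit_call <- vapply(seq_len(nrow(calls)), function(j) {
    tt <- truth[truth$sample == calls$sample[j] & truth$chrom == calls$chrom[j], ]
    nrow(tt) > 0 && any(vapply(seq_len(nrow(tt)), function(i)
      ro_pair(tt$start[i], tt$end[i], calls$start[j], calls$end[j]),
      numeric(1)) >= ro)
  }, logical(1))
  list(recall = mean(hit_truth), precision = mean(hit_call))
}

# Random toy call set on a small genome.
toy_calls <- function(n, samples, genome = c(A = 1e6, B = 8e5), seed = NULL,
                      types = c("DEL", "DUP"), size_range = c(5e3, 5e4)) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- sample(names(genome), n, replace = TRUE)
  size <- round(runif(n, size_range[1], size_range[2]))
  start <- vapply(seq_len(n), function(i)
    floor(runif(1, 0, genome[[chrom[i]]] - size[i])), numeric(1))
  data.frame(sample = sample(samples, n, replace = TRUE), chrom = chrom,
             start = start, end = start + size,
             type = sample(types, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Brute-force single-linkage clustering of same-type calls at reciprocal
# overlap >= ro: connected components of the pairwise overlap graph.
oracle_catalog_clusters <- function(calls, ro = 0.5) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && calls$type[i] == calls$type[j] &&
        calls$chrom[i] == calls$chrom[j] &&
        ro_pair(calls$start[i], calls$end[i], calls$start[j], calls$end[j]) >= ro)
      adj[i, j] <- TRUE
  }
  comp <- rep(NA_integer_, n)
  k <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1
    frontier <- i
    while (length(frontier) > 0) {
      comp[frontier] <- k
      frontier <- setdiff(which(apply(adj[frontier, , drop = FALSE], 2, any)),
                          which(!is.na(comp)))
    }
  }
  comp
}

# Brute-force Benjamini-Hochberg: reject the k largest-p hypotheses with
# p_(k) <= k * alpha / m, k maximal.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * alpha / m)
  rejected <- rep(FALSE, m)
  if (length(ok) > 0) rejected[o[seq_len(max(ok))]] <- TRUE
  rejected
}

# Brute-force nearest-exon distance (0 when overlapping), half-open.
oracle_nearest_distance <- function(q, exons) {
  vapply(seq_len(nrow(q)), function(i) {
    e <- exons[exons$chrom == q$chrom[i], ]
    if (nrow(e) == 0) return(NA_real_)
    d <- vapply(seq_len(nrow(e)), function(j) {
      if (q$start[i] < e$end[j] && e$start[j] < q$end[i]) 0
      else if (q$end[i] <= e$start[j]) e$start[j] - q$end[i]
      else q$start[i] - e$end[j]
    }, numeric(1))
    min(d)
  }, numeric(1))
}

# A small simulated cohort shared by several tests (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_bins = 700, n_samples = 30, seed = 401)
      cache <<- simulate_coverage(cfg)
    }
    cache
  }
})

# Bins x samples Z-score matrix aligned on bin index (NA where untested).
zmat <- function(cm, rp) {
  u <- which(rp$usable)
  out <- sapply(samples(cm), function(s) {
    tt <- zscore_bins(cm, rp, s)
    z <- rep(NA_real_, length(u))
    z[match(tt$bin, u)] <- tt$z
    z
  })
  out
}
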