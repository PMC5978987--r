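#' Merge per-sample calls into a cohort CNV catalog
#'
#' Same-type calls are clustered by single linkage: two calls join the
#' same cluster when their reciprocal overlap (the smaller of the two
#' mutual overlap fractions) is at least `ro`. Each cluster becomes one
#' catalog region spanning the union of its calls, carrying the union of
#' carrier samples.
#'
#' @param calls data.frame of calls (`sample`, `chrom`, `start`, `end`,
#'   `type`).
#' @param ro reciprocal-overlap threshold (default 0.5).
#' @param cohort_size number of samples in the cohort, used for
#'   `cohort_freq`; defaults to the number of distinct samples in `calls`.
#' @return data.frame of catalog regions: `chrom`, `start`, `end`, `type`,
#'   `carriers` (comma-separated), `n_carriers`, `cohort_freq`.
#' @export
build_catalog <- function(calls, ro = 0.5, cohort_size = NULL) {
  if (is.null(cohort_size)) cohort_size <- length(unique(calls$sample))
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      type = character(), carriers = character(),
                      n_carriers = integer(), cohort_freq = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  out <- lapply(split(calls, calls$type), function(cc) {
    pr <- .overlap_pairs(cc$start, cc$end, cc$chrom)
    keep <- .reciprocal_overlap(cc$start[pr$from], cc$end[pr$from],
                                cc$start[pr$to], cc$end[pr$to]) >= ro
    comp <- .components(nrow(cc), pr$from[keep], pr$to[keep])
    idx <- split(seq_len(nrow(cc)), comp)
    carriers <- vapply(idx, function(i)
      paste(sort(unique(cc$sample[i])), collapse = ","), character(1))
    n_carr <- vapply(idx, function(i) length(unique(cc$sample[i])), integer(1))
    data.frame(
      chrom = vapply(idx, function(i) cc$chrom[i[1]], character(1)),
      start = vapply(idx, function(i) min(cc$start[i]), numeric(1)),
      end = vapply(idx, function(i) max(cc$end[i]), numeric(1)),
      type = cc$type[1], carriers = carriers, n_carriers = n_carr,
      cohort_freq = n_carr / cohort_size,
      row.names = NULL, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$type), ]
  rownames(res) <- NULL
  res
}

#' Construct an SV database object
#'
#' @param name database label.
#' @param n_samples number of individuals the database was built from.
#' @param variants data.frame with `chrom`, `start`, `end`, `type`,
#'   `n_carriers` (carrier counts must not exceed `n_samples`).
#' @return list of class `sv_database`.
#' @export
sv_database <- function(name, n_samples, variants) {
  stopifnot(all(c("chrom", "start", "end", "n_carriers") %in% names(variants)),
            all(variants$n_carriers <= n_samples))
  structure(list(name = name, n_samples = n_samples, variants = variants),
            class = "sv_database")
}

#' Annotate catalog regions with database frequency and rarity
#'
#' Within each database, a variant supports a region when it covers at
#' least `cov` of the region's length (any variant type counts, because
#' database entries may be large multi-allelic regions); the region's
#' frequency in that database is the largest carrier count among
#' supporting variants divided by the database sample size. `db_freq` is
#' the maximum frequency across databases, and a region is `rare` when
#' `db_freq` is strictly below 1%.
#'
#' @param regions catalog data.frame from [build_catalog()].
#' @param dbs list of [sv_database()] objects.
#' @param cov minimum fraction of the region a database variant must cover
#'   (default 0.5).
#' @return `regions` with `db_freq` and `rare` columns.
#' @export
annotate_frequency <- function(regions, dbs, cov = 0.5) {
  db_freq <- rep(0, nrow(regions))
  if (nrow(regions) > 0) {
    gr <- .gr(regions)
    for (db in dbs) {
      v <- db$variants
      hits <- GenomicRanges::findOverlaps(gr, .gr(v))
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ovl <- pmin(regions$end[qh], v$end[sh]) - pmax(regions$start[qh], v$start[sh])
      frac <- ovl / (regions$end[qh] - regions$start[qh])
      ok <- frac >= cov
      if (any(ok)) {
        f <- tapply(v$n_carriers[sh[ok]] / db$n_samples, qh[ok], max)
        idx <- as.integer(names(f))
        db_freq[idx] <- pmax(db_freq[idx], as.numeric(f))
      }
    }
  }
  regions$db_freq <- db_freq
  regions$rare <- db_freq < 0.01
  regions
}

#' Chi-squared test of the deletion/duplication balance between cohorts
#'
#' Compares the numbers of rare deletion and duplication regions in a case
#' catalog against a control catalog with a Pearson chi-squared test
#' (1 df, no continuity correction). Optionally the control cohort is
#' first downsampled (seeded) to a given sample size, keeping only regions
#' still carried by the subsample.
#'
#' @param catalog_cases,catalog_controls annotated catalogs (need `type`
#'   and `rare`; `carriers` needed when downsampling).
#' @param downsample_to optional number of control samples to retain.
#' @param control_samples character vector of all control sample IDs
#'   (required when downsampling).
#' @param seed seed for the downsampling draw.
#' @return list: `table` (2x2 DEL/DUP x cohort), `statistic`, `p.value`.
#' @export
deldup_test <- function(catalog_cases, catalog_controls, downsample_to = NULL,
                        control_samples = NULL, seed = 1) {
  ctl <- catalog_controls[catalog_controls$rare, ]
  if (!is.null(downsample_to)) {
    if (is.null(control_samples)) stop("control_samples required for downsampling")
    set.seed(seed)
    keep <- sample(control_samples, downsample_to)
    still <- vapply(strsplit(ctl$carriers, ","), function(cc) any(cc %in% keep),
                    logical(1))
    ctl <- ctl[still, ]
  }
  cas <- catalog_cases[catalog_cases$rare, ]
  tab <- rbind(cases = c(DEL = sum(cas$type == "DEL"), DUP = sum(cas$type == "DUP")),
               controls = c(DEL = sum(ctl$type == "DEL"), DUP = sum(ctl$type == "DUP")))
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(table = tab, statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Call-frequency spectrum of an average sample
#'
#' For each sample, the fraction of its calls whose cohort frequency (the
#' frequency of the call's catalog region) falls in each stratum. A
#' caller prone to systematic errors shows a large mass in the top
#' stratum; a well-calibrated caller spreads calls across the spectrum.
#'
#' @param calls per-sample calls data.frame.
#' @param cohort_size total samples in the cohort (default: distinct
#'   samples in `calls`).
#' @param breaks frequency strata boundaries (default `<50%`, `50–95%`,
#'   `>95%`).
#' @param ro reciprocal overlap used to group calls into regions.
#' @return list: `per_sample` (samples x strata proportions) and
#'   `average` (mean over samples).
#' @export
call_frequency_spectrum <- function(calls, cohort_size = NULL,
                                    breaks = c(0, 0.5, 0.95, 1), ro = 0.5) {
  if (is.null(cohort_size)) cohort_size <- length(unique(calls$sample))
  freq <- .call_region_freq(calls, cohort_size, ro)
  strata <- cut(freq, breaks = breaks, include.lowest = TRUE)
  tab <- table(calls$sample, strata)
  per_sample <- sweep(tab, 1, rowSums(tab), `/`)
  list(per_sample = as.matrix(per_sample), average = colMeans(per_sample))
}

# Cohort frequency of each call via its catalog region.
.call_region_freq <- function(calls, cohort_size, ro = 0.5) {
  freq <- numeric(nrow(calls))
  for (ty in unique(calls$type)) {
    i <- which(calls$type == ty)
    cc <- calls[i, ]
    pr <- .overlap_pairs(cc$start, cc$end, cc$chrom)
    keep <- .reciprocal_overlap(cc$start[pr$from], cc$end[pr$from],
                                cc$start[pr$to], cc$end[pr$to]) >= ro
    comp <- .components(nrow(cc), pr$from[keep], pr$to[keep])
    for (g in unique(comp)) {
      j <- which(comp == g)
      freq[i[j]] <- length(unique(cc$sample[j])) / cohort_size
    }
  }
  freq
}

#' Monozygotic-twin replication of CNV calls
#'
#' After removing calls whose cohort frequency exceeds `max_freq` (to keep
#' systematic errors from inflating the estimate), a call replicates when
#' the co-twin carries an overlapping (>= 1 bp) call of the same type.
#'
#' @param calls per-sample calls data.frame.
#' @param pairs data.frame with columns `twin1`, `twin2`.
#' @param cohort_size total number of samples behind `calls` (default:
#'   distinct samples present).
#' @param max_freq maximum cohort frequency retained (default 0.5).
#' @return data.frame per twin sample: `sample`, `n_calls`,
#'   `n_replicated`, `rate`.
#' @export
twin_replication <- function(calls, pairs, cohort_size = NULL, max_freq = 0.5) {
  if (is.null(cohort_size)) cohort_size <- length(unique(calls$sample))
  freq <- .call_region_freq(calls, cohort_size)
  calls <- calls[freq <= max_freq, ]
  partner <- c(stats::setNames(pairs$twin2, pairs$twin1),
               stats::setNames(pairs$twin1, pairs$twin2))
  out <- lapply(names(partner), function(s) {
    own <- calls[calls$sample == s, ]
    other <- calls[calls$sample == partner[[s]], ]
    n_rep <- 0L
    if (nrow(own) > 0 && nrow(other) > 0) {
      hits <- GenomicRanges::findOverlaps(.gr(own), .gr(other))
      same <- own$type[S4Vectors::queryHits(hits)] ==
        other$type[S4Vectors::subjectHits(hits)]
      n_rep <- length(unique(S4Vectors::queryHits(hits)[same]))
    }
    data.frame(sample = s, n_calls = nrow(own), n_replicated = n_rep,
               rate = if (nrow(own) > 0) n_rep / nrow(own) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
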