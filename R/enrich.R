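#' Sample size- and gap-matched control regions
#'
#' Draws `n_sets` sets of control regions with exactly the size
#' distribution of the input regions, placed uniformly over the genome,
#' with the proportion of controls overlapping assembly gaps (centromeres,
#' telomeres, gaps) constrained to match the input proportion within
#' `tol`. Matching is enforced constructively: the number of gap-hitting
#' controls is fixed at the rounded target and each control is rejection-
#' sampled until it satisfies its gap condition.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param gaps data.frame of gap intervals (may have zero rows).
#' @param genome named vector of chromosome lengths.
#' @param n_sets number of control sets (default 10).
#' @param seed RNG seed.
#' @param tol tolerance on the gap-overlap proportion (default 0.02).
#' @return list of `n_sets` data.frames shaped like `regions`.
#' @export
sample_control_regions <- function(regions, gaps, genome, n_sets = 10,
                                   seed = 1, tol = 0.02) {
  set.seed(seed)
  sizes <- regions$end - regions$start
  n <- length(sizes)
  has_gaps <- !is.null(gaps) && nrow(gaps) > 0
  p_gap <- if (has_gaps) mean(.overlaps_any(regions, gaps)) else 0
  n_gap <- round(p_gap * n)

  place_many <- function(sz) {
    ch <- names(genome)[sample.int(length(genome), length(sz), replace = TRUE,
                                   prob = genome)]
    start <- floor(stats::runif(length(sz)) * pmax(genome[ch] - sz, 1))
    data.frame(chrom = ch, start = start, end = start + sz,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  place_one <- function(size, want_gap) {
    for (try in seq_len(10000)) {
      reg <- place_many(size)
      if (any(.overlaps_any(reg, gaps)) == want_gap) return(reg)
    }
    stop("could not place a control region matching the gap constraint")
  }

  lapply(seq_len(n_sets), function(set) {
    if (!has_gaps) return(place_many(sizes))
    want <- rep(FALSE, n)
    if (n_gap > 0) want[sample(n, n_gap)] <- TRUE
    out <- do.call(rbind, lapply(seq_len(n), function(i) place_one(sizes[i], want[i])))
    rownames(out) <- NULL
    out
  })
}

#' Fold-enrichment of regions in an annotation track
#'
#' Ratio of the number of regions overlapping the track (>= 1 bp) to the
#' mean of the same count over the control sets.
#'
#' @param regions data.frame of regions.
#' @param track data.frame of annotation intervals (e.g. exons).
#' @param controls list of control region sets from
#'   [sample_control_regions()].
#' @return numeric fold-enrichment.
#' @export
fold_enrichment <- function(regions, track, controls) {
  n_obs <- sum(.overlaps_any(regions, track))
  n_ctl <- mean(vapply(controls, function(cs)
    sum(.overlaps_any(cs, track)), numeric(1)))
  if (n_obs == 0 && n_ctl == 0) stop("0/0 fold-enrichment is undefined")
  n_obs / n_ctl
}

#' Case/control burden test by catalog subsampling and label permutation
#'
#' The observed statistic is the median, over `n_sub` paired subsampled
#' catalogs (each built from `sub_size` randomly chosen samples per
#' cohort), of the difference in track fold-enrichment between the case
#' and control catalog; the two folds of a pair share the control-region
#' seed so placement noise cancels. The null permutes the cohort labels
#' of the samples: each of the `n_perm` replicates relabels the pooled
#' samples and takes the paired fold difference of one disjoint
#' subsample split. The one-sided permutation p-value uses the +1
#' convention (two-sided by flag).
#'
#' @param case_calls,control_calls per-sample call data.frames.
#' @param track annotation intervals defining the burden (e.g. exons).
#' @param genome named chromosome lengths, for control-region placement.
#' @param gaps gap intervals (may be empty) for control-region matching.
#' @param n_sub number of subsampled catalog pairs (default 100).
#' @param sub_size samples per subsampled catalog (default 150; capped at
#'   each cohort's size).
#' @param n_perm null replicates (default 10000).
#' @param seed RNG seed.
#' @param ro reciprocal overlap for catalog construction.
#' @param n_control_sets control-region sets per fold computation.
#' @param two_sided if TRUE, p is two-sided on the absolute statistic.
#' @return list of class `enrichment_result`: `fold_case`, `fold_control`
#'   (vectors), `statistic`, `null`, `p_perm`, `n_sub`, `n_perm`.
#' @export
burden_permutation <- function(case_calls, control_calls, track, genome,
                               gaps = NULL, n_sub = 100, sub_size = 150,
                               n_perm = 10000, seed = 1, ro = 0.5,
                               n_control_sets = 3, two_sided = FALSE) {
  set.seed(seed)
  case_samples <- unique(case_calls$sample)
  control_samples <- unique(control_calls$sample)
  sub_size <- min(sub_size, length(case_samples), length(control_samples))
  pooled_calls <- rbind(case_calls[, c("sample", "chrom", "start", "end", "type")],
                        control_calls[, c("sample", "chrom", "start", "end", "type")])
  pooled_samples <- c(case_samples, control_samples)

  fold_of <- function(calls, keep, fold_seed) {
    cat_sub <- build_catalog(calls[calls$sample %in% keep, ], ro = ro,
                             cohort_size = length(keep))
    if (nrow(cat_sub) == 0) return(NA_real_)
    ctl <- sample_control_regions(cat_sub, gaps, genome,
                                  n_sets = n_control_sets, seed = fold_seed)
    tryCatch(fold_enrichment(cat_sub, track, ctl),
             error = function(e) NA_real_)   # 0/0: no informative overlap
  }
  # the i-th case and control folds share the control-region seed (paired
  # design): placement noise cancels in the difference
  seeds <- sample.int(2^30, n_sub)
  fold_case <- fold_control <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    fold_case[i] <- fold_of(case_calls, sample(case_samples, sub_size), seeds[i])
    fold_control[i] <- fold_of(control_calls, sample(control_samples, sub_size),
                               seeds[i])
  }
  observed <- stats::median(fold_case - fold_control, na.rm = TRUE)

  # label-permuted null: each replicate relabels the pooled samples and
  # takes the paired fold difference of one disjoint subsample split
  # (placement seed shared within the pair). The single-split replicate
  # carries at least the subsampling noise of the observed median, so the
  # test errs on the conservative side.
  null_seeds <- sample.int(2^30, n_perm)
  null <- vapply(seq_len(n_perm), function(r) {
    both <- sample(pooled_samples, 2 * sub_size)
    fold_of(pooled_calls, both[seq_len(sub_size)], null_seeds[r]) -
      fold_of(pooled_calls, both[sub_size + seq_len(sub_size)], null_seeds[r])
  }, numeric(1))
  null <- null[is.finite(null)]
  p <- .perm_p(null, observed, side = if (two_sided) "two.sided" else "greater")
  structure(list(fold_case = fold_case, fold_control = fold_control,
                 statistic = observed, null = null, p_perm = p,
                 n_sub = n_sub, n_perm = n_perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: statistic %.3f, p_perm %.4g (%d subsamples, %d permutations)\n",
              x$statistic, x$p_perm, x$n_sub, x$n_perm))
  invisible(x)
}

#' Size-matched enrichment of CNV-hit genes in a known-gene list
#'
#' Tests whether the genes hit by CNVs contain more known (e.g.
#' disease-associated) genes than expected for genes of similar size.
#' All genes are stratified into `n_strata` gene-length quantile strata;
#' each null set draws, within every stratum, as many genes as the hit
#' set contains there, and the empirical p-value counts null sets with at
#' least the observed known-gene overlap (+1 convention).
#'
#' @param hit_genes character vector of genes hit by CNVs.
#' @param known_genes character vector of known genes.
#' @param gene_sizes named numeric vector of gene lengths for all genes.
#' @param n_sets number of null gene sets (default 10000).
#' @param seed RNG seed.
#' @param n_strata number of gene-length quantile strata (default 20).
#' @return list: `observed`, `null` (vector), `p`.
#' @export
gene_hit_enrichment <- function(hit_genes, known_genes, gene_sizes,
                                n_sets = 10000, seed = 1, n_strata = 20) {
  set.seed(seed)
  genes <- names(gene_sizes)
  stopifnot(all(hit_genes %in% genes))
  qs <- unique(stats::quantile(gene_sizes, probs = seq(0, 1, length.out = n_strata + 1)))
  stratum <- cut(gene_sizes, breaks = qs, include.lowest = TRUE)
  names(stratum) <- genes
  hit_tab <- table(stratum[hit_genes])
  by_stratum <- split(genes, stratum)
  observed <- length(intersect(hit_genes, known_genes))
  null <- vapply(seq_len(n_sets), function(i) {
    draw <- unlist(lapply(names(hit_tab)[hit_tab > 0], function(st)
      sample(by_stratum[[st]], hit_tab[[st]])))
    length(intersect(draw, known_genes))
  }, numeric(1))
  list(observed = observed, null = null, p = .perm_p(null, observed))
}

#' Proportion of private CNV regions, with downsampled control null
#'
#' A region is private when it is carried by exactly one sample. The
#' control cohort is downsampled `n_down` times to the case sample size
#' and its catalog rebuilt each time, giving a null distribution, a 5-95%
#' interval and an empirical p-value for the case proportion being lower
#' (cases less private, i.e. more recurrent). Also returns the recurrence
#' curve: the fraction of regions seen in at least x samples.
#'
#' @param catalog_case case catalog data.frame (needs `n_carriers`).
#' @param control_calls control per-sample calls.
#' @param case_n case cohort sample size, the downsampling target.
#' @param n_down number of downsamples (default 1000).
#' @param seed RNG seed.
#' @param ro reciprocal overlap for rebuilding control catalogs.
#' @return list: `proportion`, `ci` (5-95% of the null), `p`, `null`,
#'   `curve` (data.frame x, fraction seen in >= x samples).
#' @export
private_proportion <- function(catalog_case, control_calls, case_n,
                               n_down = 1000, seed = 1, ro = 0.5) {
  set.seed(seed)
  prop <- mean(catalog_case$n_carriers == 1)
  control_samples <- unique(control_calls$sample)
  null <- vapply(seq_len(n_down), function(i) {
    keep <- sample(control_samples, min(case_n, length(control_samples)))
    cat_i <- build_catalog(control_calls[control_calls$sample %in% keep, ],
                           ro = ro, cohort_size = length(keep))
    if (nrow(cat_i) == 0) NA_real_ else mean(cat_i$n_carriers == 1)
  }, numeric(1))
  null <- null[!is.na(null)]
  xs <- seq_len(max(catalog_case$n_carriers))
  curve <- data.frame(x = xs,
                      fraction = vapply(xs, function(x)
                        mean(catalog_case$n_carriers >= x), numeric(1)))
  list(proportion = prop,
       ci = stats::quantile(null, c(0.05, 0.95), names = FALSE),
       p = (1 + sum(null <= prop)) / (length(null) + 1),
       null = null, curve = curve)
}

#' Proximity of non-coding CNVs to known-gene exons
#'
#' For each distance threshold d, counts the individuals in each cohort
#' carrying at least one qualifying call (optionally restricted to calls
#' overlapping a functional track) whose distance to the nearest
#' known-gene exon is <= d, and derives the case/control odds ratio
#' (Haldane 0.5 correction when a cell is empty). The control cohort is
#' first downsampled (seeded) to the case sample size. Distances of the
#' per-call distributions are compared with a two-sample
#' Kolmogorov-Smirnov test (per-individual minimum distances by flag).
#'
#' @param case_calls,control_calls non-coding rare call data.frames.
#' @param exons known-gene exon intervals.
#' @param case_n,control_n cohort sizes (individuals, including those
#'   without qualifying calls).
#' @param functional optional functional-region track; calls must overlap
#'   it to qualify.
#' @param dist_grid distance thresholds in bp.
#' @param seed seed for control downsampling.
#' @param per_individual if TRUE, the KS test uses each individual's
#'   minimum distance instead of per-call distances.
#' @return list: `table` (per threshold: exposed counts and odds ratio),
#'   `ks_p`, `case_dist`, `control_dist`.
#' @export
proximity_analysis <- function(case_calls, control_calls, exons,
                               case_n, control_n, functional = NULL,
                               dist_grid = c(5e3, 1e4, 5e4, 1e5, 2e5),
                               seed = 1, per_individual = FALSE) {
  set.seed(seed)
  control_samples <- unique(control_calls$sample)
  if (control_n > case_n && length(control_samples) > 0) {
    keep <- sample(control_samples, round(length(control_samples) * case_n / control_n))
    control_calls <- control_calls[control_calls$sample %in% keep, ]
    control_n <- case_n
  }
  qualify <- function(calls) {
    if (!is.null(functional) && nrow(calls) > 0)
      calls <- calls[.overlaps_any(calls, functional), ]
    calls
  }
  dist_to_exons <- function(calls) {
    if (nrow(calls) == 0) return(numeric(0))
    d <- suppressWarnings(
      GenomicRanges::distanceToNearest(.gr(calls), .gr(exons)))
    out <- rep(NA_real_, nrow(calls))
    out[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
    out
  }
  cas <- qualify(case_calls); ctl <- qualify(control_calls)
  dc <- dist_to_exons(cas); dt <- dist_to_exons(ctl)

  tab <- do.call(rbind, lapply(dist_grid, function(d) {
    n_case <- length(unique(cas$sample[!is.na(dc) & dc <= d]))
    n_ctl <- length(unique(ctl$sample[!is.na(dt) & dt <= d]))
    a <- n_case; b <- case_n - n_case; c <- n_ctl; dd <- control_n - n_ctl
    if (any(c(a, b, c, dd) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; dd <- dd + 0.5 }
    data.frame(dist = d, case_exposed = n_case, control_exposed = n_ctl,
               odds_ratio = (a * dd) / (b * c))
  }))

  if (per_individual) {
    dc_ks <- tapply(dc, cas$sample, min, na.rm = TRUE)
    dt_ks <- tapply(dt, ctl$sample, min, na.rm = TRUE)
  } else {
    dc_ks <- dc[!is.na(dc)]; dt_ks <- dt[!is.na(dt)]
  }
  ks_p <- if (length(dc_ks) > 0 && length(dt_ks) > 0)
    suppressWarnings(stats::ks.test(dc_ks, dt_ks)$p.value) else NA_real_
  list(table = tab, ks_p = ks_p, case_dist = dc, control_dist = dt)
}
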