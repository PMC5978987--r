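#' Configuration for the synthetic coverage simulator
#'
#' The simulator emulates the bias structure seen in whole-genome
#' sequencing read depth: region effects (per-bin lognormal multipliers),
#' sample rank bias (a genome-wide lognormal multiplier per sample, so
#' some samples run consistently high or low), a per-sample unimodal GC
#' response, region-class batch structure (each bin belongs to one of a
#' few latent response classes — think mappability or library-chemistry
#' strata — and every sample carries its own multiplier per class, so a
#' sample can run consistently high over one portion of the genome and
#' low over another), overdispersed counting noise, and spiked CNVs of
#' known copy number and carrier frequency.
#'
#' Expected count for sample s in bin b is
#' `depth_mean * mu_b * L_s * g_s(gc_b) * A_{s, r(b)} * cn_{s,b} / 2`,
#' with `mu_b ~ lognormal(0, bin_effect_sd)`,
#' `L_s ~ lognormal(0, sample_bias_sd)`, `g_s` a Gaussian-bump GC response
#' normalized to mean 1 across bins, `r(b)` the bin's response class and
#' `A ~ lognormal(0, batch_sd)` per sample and class; counts are drawn
#' negative-binomial with the given dispersion (`poisson` and `gaussian`
#' noise arms are available for null comparisons).
#'
#' @param n_bins number of bins (default 2000).
#' @param n_samples number of samples (default 45).
#' @param bin_size bin width in bp (default 5000).
#' @param depth_mean expected reads per diploid bin (default 1600, i.e.
#'   40x coverage with 125 bp reads in a 5 Kbp bin).
#' @param bin_effect_sd lognormal sdlog of per-bin region effects
#'   (default 0.3).
#' @param sample_bias_sd lognormal sdlog of per-sample genome-wide bias
#'   (default 0.05).
#' @param gc_bias whether to apply a per-sample GC response (default TRUE).
#' @param gc_opt_mean,gc_opt_sd mean/SD of each sample's optimal GC
#'   fraction (defaults 0.45, 0.02).
#' @param gc_width width of the GC response bump (default 0.15).
#' @param batch_classes number of latent region response classes
#'   (default 3).
#' @param batch_sd lognormal sdlog of per-sample, per-class response
#'   multipliers (default 0.03, i.e. coherent regional deviations of a
#'   few percent).
#' @param dispersion negative-binomial size parameter (default 800,
#'   i.e. residual variance about 3x Poisson at the default depth — the
#'   structured overdispersion lives in the bias terms).
#' @param noise `"nb"`, `"poisson"` or `"gaussian"`.
#' @param cnv_spikes list of spikes, each
#'   `list(n_events, nbins, cn, carrier_freq)`.
#' @param twin_pairs number of twin pairs among the samples (used by
#'   [simulate_twins()]).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_bins = 2000, n_samples = 45, bin_size = 5000,
                       depth_mean = 1600, bin_effect_sd = 0.3,
                       sample_bias_sd = 0.05, gc_bias = TRUE,
                       gc_opt_mean = 0.45, gc_opt_sd = 0.02, gc_width = 0.15,
                       batch_classes = 3, batch_sd = 0.03,
                       dispersion = 800, noise = c("nb", "poisson", "gaussian"),
                       cnv_spikes = list(), twin_pairs = 0, seed = 1) {
  noise <- match.arg(noise)
  cfg <- structure(mget(names(formals())), class = "sim_config")
  cfg$noise <- noise
  for (sp in cnv_spikes) {
    stopifnot(sp$carrier_freq > 0, sp$carrier_freq <= 1,
              sp$cn %in% c(0, 1, 3, 4, 5, 6), sp$nbins >= 1, sp$n_events >= 1)
  }
  cfg
}

#' Simulate a bin-by-sample coverage matrix with ground truth
#'
#' @param cfg a [sim_config()].
#' @param sample_groups optional list of integer vectors partitioning
#'   samples into carrier groups: members of a group always share spiked
#'   events (used for twin simulation). Default: each sample on its own.
#' @return list: `cm` (raw [cov_matrix] with simulated `gc`), `truth`
#'   (data.frame of spiked events: `event`, `sample`, `chrom`, `start`,
#'   `end`, `nbins`, `cn`), `gc`, `sample_bias`, `bin_effect`,
#'   `gc_response` (bins x samples multiplier matrix), `batch_class`
#'   (per-bin class) and `batch_response` (classes x samples multipliers).
#' @export
simulate_coverage <- function(cfg, sample_groups = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  B <- cfg$n_bins; S <- cfg$n_samples
  sample_ids <- sprintf("s%03d", seq_len(S))
  if (is.null(sample_groups)) sample_groups <- as.list(seq_len(S))

  gc <- stats::rbeta(B, 20, 28)                 # centred near 0.42 like mammalian genomes
  mu_b <- stats::rlnorm(B, 0, cfg$bin_effect_sd)
  L_s <- stats::rlnorm(S, 0, cfg$sample_bias_sd)

  if (cfg$gc_bias) {
    opt <- stats::rnorm(S, cfg$gc_opt_mean, cfg$gc_opt_sd)
    G <- vapply(seq_len(S), function(s) {
      g <- exp(-(gc - opt[s])^2 / (2 * cfg$gc_width^2))
      g / mean(g)
    }, numeric(B))
  } else {
    G <- matrix(1, B, S)
  }

  if (cfg$batch_classes > 1 && cfg$batch_sd > 0) {
    cls <- sample.int(cfg$batch_classes, B, replace = TRUE)
    A <- matrix(stats::rlnorm(S * cfg$batch_classes, 0, cfg$batch_sd),
                cfg$batch_classes, S)
    Amat <- A[cls, , drop = FALSE]
  } else {
    cls <- rep(1L, B)
    A <- matrix(1, 1, S)
    Amat <- matrix(1, B, S)
  }

  # copy-number matrix from spikes; events non-overlapping with a 1-bin buffer
  cn <- matrix(2, B, S)
  occupied <- rep(FALSE, B)
  truth <- list()
  ev <- 0L
  for (sp in cfg$cnv_spikes) {
    for (e in seq_len(sp$n_events)) {
      placed <- FALSE
      for (try in seq_len(5000)) {
        st <- sample.int(B - sp$nbins + 1, 1)
        span <- st:(st + sp$nbins - 1)
        buf <- max(1, st - 1):min(B, st + sp$nbins)
        if (!any(occupied[buf])) { occupied[buf] <- TRUE; placed <- TRUE; break }
      }
      if (!placed) stop("could not place all spiked events; reduce n_events/nbins")
      carrier_groups <- which(stats::rbinom(length(sample_groups), 1,
                                            sp$carrier_freq) == 1)
      carriers <- unlist(sample_groups[carrier_groups])
      ev <- ev + 1L
      for (s in carriers) {
        cn[span, s] <- sp$cn
        truth[[length(truth) + 1]] <- data.frame(
          event = ev, sample = sample_ids[s], chrom = "S1",
          start = (st - 1) * cfg$bin_size, end = (st - 1 + sp$nbins) * cfg$bin_size,
          nbins = sp$nbins, cn = sp$cn, stringsAsFactors = FALSE)
      }
    }
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(event = integer(), sample = character(), chrom = character(),
               start = numeric(), end = numeric(), nbins = integer(),
               cn = numeric(), stringsAsFactors = FALSE)

  m <- cfg$depth_mean * (mu_b * G * Amat) * rep(L_s, each = B) * cn / 2
  counts <- switch(cfg$noise,
    nb = matrix(stats::rnbinom(B * S, mu = m, size = cfg$dispersion), B, S),
    poisson = matrix(stats::rpois(B * S, lambda = m), B, S),
    gaussian = matrix(pmax(0, round(stats::rnorm(B * S, mean = m, sd = sqrt(m)))), B, S))
  colnames(counts) <- sample_ids

  bins <- data.frame(chrom = "S1", start = (seq_len(B) - 1) * cfg$bin_size,
                     end = seq_len(B) * cfg$bin_size, gc = gc, usable = TRUE,
                     stringsAsFactors = FALSE)
  list(cm = cov_matrix(bins, counts, state = "raw"), truth = truth, gc = gc,
       sample_bias = stats::setNames(L_s, sample_ids), bin_effect = mu_b,
       gc_response = G, batch_class = cls, batch_response = A)
}

#' Simulate coverage for a cohort containing monozygotic twin pairs
#'
#' The first `2 * twin_pairs` samples form pairs that share every spiked
#' event (counting noise stays independent); remaining samples are
#' unrelated.
#'
#' @param cfg a [sim_config()] with `twin_pairs >= 1`.
#' @return As [simulate_coverage()], plus `pairs` (data.frame `twin1`,
#'   `twin2`).
#' @export
simulate_twins <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$twin_pairs >= 1,
            2 * cfg$twin_pairs <= cfg$n_samples)
  P <- cfg$twin_pairs
  groups <- c(lapply(seq_len(P), function(i) c(2 * i - 1, 2 * i)),
              as.list(seq(2 * P + 1, length.out = cfg$n_samples - 2 * P)))
  out <- simulate_coverage(cfg, sample_groups = groups)
  ids <- samples(out$cm)
  out$pairs <- data.frame(twin1 = ids[seq(1, 2 * P, by = 2)],
                          twin2 = ids[seq(2, 2 * P, by = 2)],
                          stringsAsFactors = FALSE)
  out
}

#' Simulate a toy annotation set and SV database
#'
#' Generates random multi-exon gene models on a given genome, designates a
#' known-gene subset, assembly-gap intervals covering a configurable
#' genome fraction, an optional functional track (short regulatory
#' intervals near known-gene exons), and an SV database with configurable
#' carrier frequencies.
#'
#' @param genome named vector of chromosome lengths.
#' @param n_genes number of genes (default 100).
#' @param n_known size of the known-gene subset (default 15).
#' @param exons_per_gene mean exons per gene (default 4).
#' @param gap_frac fraction of the genome covered by gaps (default 0.05).
#' @param db_n_samples database sample size (default 200).
#' @param n_db_variants number of random database variants (default 100).
#' @param db_freq_range carrier-frequency range for random variants.
#' @param db_variants optional explicit variants data.frame (`chrom`,
#'   `start`, `end`, `type`, `n_carriers`) overriding random generation.
#' @param functional if TRUE, emit a functional track near known genes.
#' @param seed RNG seed.
#' @return list: `genes` (with `gene`, `size`), `exons` (with `gene`),
#'   `known_genes`, `gaps`, `functional` (or NULL), `database`
#'   (an [sv_database()]).
#' @export
simulate_annotation <- function(genome, n_genes = 100, n_known = 15,
                                exons_per_gene = 4, gap_frac = 0.05,
                                db_n_samples = 200, n_db_variants = 100,
                                db_freq_range = c(0.001, 0.2),
                                db_variants = NULL, functional = FALSE,
                                seed = 1) {
  set.seed(seed)
  n_known <- min(n_known, n_genes)
  chroms <- names(genome)
  pick_interval <- function(size) {
    ch <- sample(chroms, 1, prob = genome)
    start <- floor(stats::runif(1, 0, max(genome[[ch]] - size, 1)))
    data.frame(chrom = ch, start = start, end = start + size,
               stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    span <- round(stats::rlnorm(1, log(3e4), 0.8))
    g <- pick_interval(span)
    g$gene <- sprintf("g%04d", i)
    g
  }))
  genes$size <- genes$end - genes$start
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    g <- genes[i, ]
    k <- max(1, stats::rpois(1, exons_per_gene))
    width <- min(200, floor(g$size / (2 * k)))
    starts <- sort(sample.int(max(g$size - width, 1), k))
    data.frame(chrom = g$chrom, start = g$start + starts - 1,
               end = pmin(g$start + starts - 1 + width, g$end),
               gene = g$gene, stringsAsFactors = FALSE)
  }))
  known_genes <- sample(genes$gene, n_known)

  n_gaps <- max(1, round(gap_frac * sum(genome) / 5e4))
  gaps <- do.call(rbind, lapply(seq_len(n_gaps), function(i) pick_interval(5e4)))

  func <- NULL
  if (functional) {
    ke <- exons[exons$gene %in% known_genes, ]
    off <- sample(c(-1, 1), nrow(ke), replace = TRUE) *
      sample.int(5e4, nrow(ke), replace = TRUE)
    func <- data.frame(chrom = ke$chrom,
                       start = pmax(0, ke$start + off),
                       end = pmax(0, ke$start + off) + 500,
                       gene = ke$gene, stringsAsFactors = FALSE)
  }

  if (is.null(db_variants)) {
    db_variants <- do.call(rbind, lapply(seq_len(n_db_variants), function(i) {
      v <- pick_interval(round(stats::rlnorm(1, log(1e4), 0.6)))
      v$type <- sample(c("DEL", "DUP"), 1)
      v$n_carriers <- max(1, round(stats::runif(1, db_freq_range[1],
                                                db_freq_range[2]) * db_n_samples))
      v
    }))
  }
  db <- sv_database("synthetic-db", db_n_samples, db_variants)
  list(genes = genes, exons = exons, known_genes = known_genes, gaps = gaps,
       functional = func, database = db)
}
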