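# Burden and enrichment statistics: control regions, fold-enrichment,
# permutation tests, private proportions, proximity analysis.

genome2 <- c(A = 2e6, B = 1.5e6)

test_that("control regions preserve sizes and match gap overlap", {
  regions <- data.frame(chrom = "A", start = c(0, 1e5, 2e5),
                        end = c(5000, 1.1e5, 2.2e5))
  gaps <- data.frame(chrom = "A", start = 5e5, end = 6e5)
  ctl <- sample_control_regions(regions, gaps, genome2, n_sets = 5, seed = 3)
  for (cs in ctl) {
    expect_setequal(cs$end - cs$start, c(5000, 10000, 20000))
    # input has 0% gap overlap: controls stay within 2%
    hit <- suppressWarnings(GenomicRanges::countOverlaps(
      GenomicRanges::GRanges(cs$chrom, IRanges::IRanges(cs$start + 1, cs$end)),
      GenomicRanges::GRanges(gaps$chrom, IRanges::IRanges(gaps$start + 1, gaps$end))))
    expect_lte(mean(hit > 0), 0.02)
  }
})

test_that("control placement is uniform over the genome", {
  regions <- data.frame(chrom = "A", start = seq(0, 9e5, 1e5),
                        end = seq(0, 9e5, 1e5) + 1e4)
  ctl <- sample_control_regions(regions, NULL, genome2, n_sets = 300, seed = 4)
  mids <- unlist(lapply(ctl, function(cs) {
    off <- cumsum(c(A = 0, B = genome2[["A"]]))[cs$chrom]
    off + (cs$start + cs$end) / 2
  }))
  gm <- sum(genome2) / 2
  se <- sum(genome2) / sqrt(12) / sqrt(length(mids))
  expect_lt(abs(mean(mids) - gm), 3 * se)
})

test_that("fold_enrichment is the observed/control hit ratio", {
  track <- data.frame(chrom = "A", start = seq(0, 9e5, 1e5),
                      end = seq(0, 9e5, 1e5) + 1000)
  regions <- data.frame(chrom = "A", start = seq(0, 7e5, 1e5),
                        end = seq(0, 7e5, 1e5) + 1500)   # 8 regions, all hit
  controls <- list(
    data.frame(chrom = "A", start = c(1e4, 2e5 + 5e4, 1e5, 3e5),
               end = c(1e4, 2e5 + 5e4, 1e5, 3e5) + 1500))
  # control hits: bins starting exactly at track starts hit; offsets miss
  n_ctl <- sum(suppressWarnings(GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(controls[[1]]$chrom,
      IRanges::IRanges(controls[[1]]$start + 1, controls[[1]]$end)),
    GenomicRanges::GRanges(track$chrom,
      IRanges::IRanges(track$start + 1, track$end)))) > 0)
  expect_equal(fold_enrichment(regions, track, controls), 8 / n_ctl)
  expect_equal(fold_enrichment(regions, track, list(regions)), 1)
  far <- data.frame(chrom = "B", start = 1e6, end = 1e6 + 100)
  expect_error(fold_enrichment(far, track, list(far)), "undefined")

  # invariance to chromosome relabeling
  relabel <- function(df) { df$chrom <- chartr("AB", "XY", df$chrom); df }
  expect_equal(fold_enrichment(relabel(regions), relabel(track),
                               lapply(controls, relabel)),
               fold_enrichment(regions, track, controls))

  # random toys against a naive recount oracle
  set.seed(5)
  for (i in 1:20) {
    rg <- toy_calls(15, "s", genome2, types = "DEL")
    cs <- lapply(1:3, function(j) toy_calls(15, "s", genome2, types = "DEL"))
    naive <- function(q) sum(vapply(seq_len(nrow(q)), function(k)
      any(q$chrom[k] == track$chrom & q$start[k] < track$end &
            track$start < q$end[k]), logical(1)))
    expect_equal(fold_enrichment(rg, track, cs),
                 naive(rg) / mean(vapply(cs, naive, numeric(1))))
  }
})

test_that("burden permutation: identical catalogs give statistic 0 and an
           unremarkable p-value", {
  calls <- toy_calls(150, sprintf("s%02d", 1:30), genome2, seed = 6)
  track <- data.frame(chrom = "A", start = seq(0, 1.9e6, 5e4),
                      end = seq(0, 1.9e6, 5e4) + 2000)
  res <- burden_permutation(calls, calls, track, genome2, n_sub = 10,
                            sub_size = 30, n_perm = 500, seed = 7)
  expect_equal(res$statistic, 0)
  # a calibrated test leaves a zero statistic unremarkable
  expect_gt(res$p_perm, 0.1)
  expect_true(res$p_perm <= 1)
})

test_that("gene_hit_enrichment handles the extreme cases", {
  sizes <- setNames(round(exp(rnorm(200, 10, 1))), sprintf("g%03d", 1:200))
  # every gene known: p = 1
  r1 <- gene_hit_enrichment(names(sizes)[1:30], names(sizes), sizes,
                            n_sets = 100, seed = 8)
  expect_equal(r1$p, 1)
  # hit set = the rare known set itself: p at the floor
  known <- names(sort(sizes))[seq(5, 200, by = 40)]   # spread across strata
  r2 <- gene_hit_enrichment(known, known, sizes, n_sets = 200, seed = 9)
  expect_lt(r2$p, 0.05)
  expect_gte(r2$p, 1 / 201)
})

test_that("private_proportion measures single-carrier regions with a
           downsampled control null", {
  cat_case <- data.frame(chrom = "c1", start = c(0, 1e4, 2e4, 3e4),
                         end = c(5e3, 1.5e4, 2.5e4, 3.5e4), type = "DEL",
                         n_carriers = c(1, 1, 2, 3))
  ctl_calls <- toy_calls(120, sprintf("c%02d", 1:40), genome2, seed = 11)
  res <- private_proportion(cat_case, ctl_calls, case_n = 20, n_down = 50,
                            seed = 12)
  expect_equal(res$proportion, 0.5)
  expect_equal(res$curve$fraction, c(1, 0.5, 0.25))
  expect_length(res$null, 50)
  expect_true(res$p >= 1 / 51 && res$p <= 1)

  all_private <- cat_case; all_private$n_carriers <- 1
  expect_equal(private_proportion(all_private, ctl_calls, 20, n_down = 5,
                                  seed = 1)$proportion, 1)
})

test_that("proximity analysis: distances, odds ratios and KS behave", {
  exons <- data.frame(chrom = c("A", "A", "B"),
                      start = c(1e5, 5e5, 2e5), end = c(1.01e5, 5.02e5, 2.05e5))
  # distance oracle on random toys
  set.seed(13)
  q <- toy_calls(40, "s", genome2)
  d_pkg <- proximity_analysis(q, q, exons, case_n = 1, control_n = 1,
                              dist_grid = 1e5)$case_dist
  expect_equal(d_pkg, oracle_nearest_distance(q, exons))

  # identical cohorts: OR 1 at every threshold
  calls <- toy_calls(60, sprintf("s%02d", 1:15), genome2, seed = 14)
  res <- proximity_analysis(calls, calls, exons, case_n = 15, control_n = 15,
                            dist_grid = c(5e3, 5e4, 2e5))
  expect_true(all(abs(res$table$odds_ratio - 1) < 1e-9))

  # closed-form check of the odds ratio with exposure counts 40/160 vs 20/180
  mk <- function(n_hit, n_tot, pfx) {
    hit <- data.frame(sample = sprintf("%s%03d", pfx, 1:n_hit), chrom = "A",
                      start = 1.2e5, end = 1.3e5, type = "DEL")  # 19 kb away
    far <- data.frame(sample = sprintf("%s%03d", pfx, (n_hit + 1):n_tot),
                      chrom = "B", start = 1e6, end = 1.01e6, type = "DEL")
    rbind(hit, far)
  }
  res2 <- proximity_analysis(mk(40, 200, "p"), mk(20, 200, "c"), exons,
                             case_n = 200, control_n = 200,
                             dist_grid = c(5e4))
  expect_equal(res2$table$odds_ratio, (40 * 180) / (160 * 20))

  # calls overlapping the functional track only
  func <- data.frame(chrom = "A", start = 1.25e5, end = 1.26e5)
  res3 <- proximity_analysis(mk(40, 200, "p"), mk(20, 200, "c"), exons,
                             case_n = 200, control_n = 200, functional = func,
                             dist_grid = c(5e4))
  expect_equal(res3$table$case_exposed, 40)   # hit calls overlap func
  ks <- res3$ks_p
  expect_true(is.na(ks) || (ks >= 0 && ks <= 1))
})

test_that("permutation p-values are reproducible under a fixed seed", {
  calls <- toy_calls(100, sprintf("s%02d", 1:20), genome2, seed = 15)
  track <- data.frame(chrom = "A", start = seq(0, 1.9e6, 1e5),
                      end = seq(0, 1.9e6, 1e5) + 3000)
  r1 <- burden_permutation(calls, toy_calls(100, sprintf("t%02d", 1:20),
                                            genome2, seed = 16),
                           track, genome2, n_sub = 5, sub_size = 20,
                           n_perm = 100, seed = 17)
  r2 <- burden_permutation(calls, toy_calls(100, sprintf("t%02d", 1:20),
                                            genome2, seed = 16),
                           track, genome2, n_sub = 5, sub_size = 20,
                           n_perm = 100, seed = 17)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_identical(r1$statistic, r2$statistic)

  sizes <- setNames(round(exp(rnorm(150, 10, 1))), sprintf("g%03d", 1:150))
  g1 <- gene_hit_enrichment(names(sizes)[1:20], names(sizes)[seq(1, 150, 7)],
                            sizes, n_sets = 200, seed = 18)
  g2 <- gene_hit_enrichment(names(sizes)[1:20], names(sizes)[seq(1, 150, 7)],
                            sizes, n_sets = 200, seed = 18)
  expect_identical(g1$p, g2$p)
})
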