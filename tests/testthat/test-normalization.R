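# Targeted normalization, baseline normalizations and QC diagnostics.

make_gc_corrected <- function(m, gc = NULL) {
  bins <- data.frame(chrom = "c1", start = (seq_len(nrow(m)) - 1) * 5000,
                     end = seq_len(nrow(m)) * 5000,
                     gc = if (is.null(gc)) 0.4 else gc, usable = TRUE)
  cov_matrix(bins, m, state = "gc_corrected")
}

test_that("support sets are scale-invariant, contain the bin, honour K=1", {
  set.seed(5)
  m <- matrix(rpois(200 * 25, 100), 200, 25,
              dimnames = list(NULL, sprintf("r%02d", 1:25)))
  m[2, ] <- 2 * m[1, ]                   # proportional to bin 1
  cm <- make_gc_corrected(m)
  rp <- suppressWarnings(build_reference(cm, K = 2, C = 200, seed = 3))
  expect_equal(sort(rp$support[1, ]), c(1, 2))   # each supports the other
  expect_equal(sort(rp$support[2, ]), c(1, 2))

  rp1 <- suppressWarnings(build_reference(cm, K = 1, C = 200, seed = 3))
  expect_equal(rp1$support[, 1], seq_len(200))   # own bin only

  expect_error(suppressWarnings(build_reference(cm, K = 500, C = 600)),
               "K exceeds")
})

test_that("support sets match an exhaustive nearest-neighbour oracle", {
  set.seed(6)
  m <- matrix(rpois(200 * 25, 150), 200, 25,
              dimnames = list(NULL, sprintf("r%02d", 1:25)))
  cm <- make_gc_corrected(m)
  K <- 8
  rp <- suppressWarnings(build_reference(cm, K = K, C = 200, seed = 9))
  V <- m / rowMeans(m)
  for (b in c(1, 57, 200)) {
    d <- colSums((t(V) - V[b, ])^2)
    d[b] <- Inf
    oracle <- c(b, order(d)[seq_len(K - 1)])
    expect_setequal(rp$support[b, ], oracle)
  }
})

test_that("build_reference is reproducible and flags degenerate bins", {
  set.seed(7)
  m <- matrix(rpois(250 * 25, 80), 250, 25,
              dimnames = list(NULL, sprintf("r%02d", 1:25)))
  m[13, ] <- 0L
  cm <- make_gc_corrected(m)
  rp1 <- suppressWarnings(build_reference(cm, K = 10, C = 100, seed = 21))
  rp2 <- suppressWarnings(build_reference(cm, K = 10, C = 100, seed = 21))
  expect_identical(rp1$support, rp2$support)
  expect_false(rp1$usable[13])           # all-zero reference vector
  expect_warning(build_reference(cm, ref_samples = sprintf("r%02d", 1:15),
                                 K = 10, C = 100), "20 reference")
})

test_that("targeted normalization is the identity on the reference medians
           and absorbs global rescaling exactly", {
  set.seed(8)
  m <- matrix(rpois(300 * 30, 120), 300, 30,
              dimnames = list(NULL, sprintf("r%02d", 1:30)))
  cm <- make_gc_corrected(m)
  rp <- suppressWarnings(build_reference(cm, K = 20, C = 300, seed = 2))

  med <- apply(m, 1, median)
  probe <- cov_matrix(cm$bins, cbind(m, t1 = med, t2 = 1.7 * med),
                      state = "gc_corrected")
  nn <- normalize_targeted(probe, rp)
  expect_equal(nn$counts[, "t1"], unname(med), tolerance = 1e-12)
  expect_equal(nn$counts[, "t2"], unname(med), tolerance = 1e-12)

  # invariance: scaling any sample leaves its normalized column unchanged
  probe2 <- cov_matrix(cm$bins, cbind(m, q = 3.1 * m[, 4]),
                       state = "gc_corrected")
  nn2 <- normalize_targeted(probe2, rp)
  expect_equal(nn2$counts[, "q"], nn2$counts[, 4], tolerance = 1e-12)
})

test_that("a heterozygous deletion normalizes to half the reference level", {
  cfg <- sim_config(n_bins = 700, n_samples = 30, seed = 77,
                    cnv_spikes = list(list(n_events = 6, nbins = 2, cn = 1,
                                           carrier_freq = 0.04)))
  sim <- simulate_coverage(cfg)
  cc <- gc_correct(sim$cm)
  rp <- build_reference(cc, K = 40, C = 700, seed = 5)
  nn <- normalize_targeted(cc, rp)
  tr <- sim$truth
  ratios <- vapply(seq_len(nrow(tr)), function(i) {
    sel <- nn$bins$start >= tr$start[i] & nn$bins$end <= tr$end[i]
    mean(nn$counts[sel, tr$sample[i]] / rp$ref_med[sel])
  }, numeric(1))
  expect_true(all(abs(ratios - 0.5) < 0.1 * 0.5 + 0.05))
  # flanking bins stay at the reference level
  flank <- vapply(seq_len(nrow(tr)), function(i) {
    sel <- which(nn$bins$start >= tr$start[i] & nn$bins$end <= tr$end[i])
    f <- c(min(sel) - 2, max(sel) + 2)
    f <- f[f >= 1 & f <= nrow(nn$bins)]
    mean(nn$counts[f, tr$sample[i]] / rp$ref_med[f])
  }, numeric(1))
  expect_true(all(abs(flank - 1) < 0.1))
})

test_that("sample/bin pairs with mostly-zero support coverage are flagged", {
  set.seed(9)
  m <- matrix(rpois(250 * 25, 90), 250, 25,
              dimnames = list(NULL, sprintf("r%02d", 1:25)))
  cm <- make_gc_corrected(m)
  rp <- suppressWarnings(build_reference(cm, K = 10, C = 250, seed = 4))
  bad <- m[, 1]
  bad[rp$support[40, ]] <- 0L            # zero out bin 40's whole support
  probe <- cov_matrix(cm$bins, cbind(m, z = bad), state = "gc_corrected")
  nn <- normalize_targeted(probe, rp)
  expect_true(is.na(nn$counts[40, "z"]))
  expect_true(attr(nn, "norm_flagged")[40, "z"])
})

test_that("baseline normalizations behave as defined", {
  set.seed(10)
  m <- matrix(rpois(400 * 6, 100) + runif(2400), 400, 6,
              dimnames = list(NULL, sprintf("s%d", 1:6)))
  cm <- make_gc_corrected(m)

  # identical samples unchanged by both
  dup <- make_gc_corrected(matrix(m[, 1], 400, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))))
  expect_equal(normalize_baseline(dup, "median")$counts, dup$counts)
  expect_equal(normalize_baseline(dup, "quantile")$counts, dup$counts)

  med <- normalize_baseline(cm, "median")
  expect_lt(diff(range(apply(med$counts, 2, median))), 1e-9)

  qn <- normalize_baseline(cm, "quantile")
  sorted <- apply(qn$counts, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-9))
})

test_that("qc_bias measures extreme-coverage shares and rank bias", {
  set.seed(12)
  n <- 10
  m <- matrix(rpois(1500 * n, 200), 1500, n,
              dimnames = list(NULL, sprintf("s%02d", 1:n)))
  cm <- make_gc_corrected(m)
  qc <- qc_bias(cm, seed = 1)
  expect_equal(sum(qc$max_share), 1)
  expect_equal(sum(qc$min_share), 1)
  # exchangeable null: every share within 3 binomial SDs of 1/n
  tol <- 3 * sqrt((1 / n) * (1 - 1 / n) / 1500)
  expect_true(all(abs(qc$max_share - 1 / n) < tol))

  # one sample biased x1.3 dominates the maxima
  m2 <- m; m2[, 4] <- round(m2[, 4] * 1.3)
  qc2 <- qc_bias(make_gc_corrected(m2), seed = 1)
  expect_gt(qc2$max_share[4], 0.9)

  # constant matrix: SD distribution degenerate at zero
  qc3 <- qc_bias(make_gc_corrected(matrix(50L, 300, 4,
    dimnames = list(NULL, letters[1:4]))), seed = 1)
  expect_true(all(qc3$bin_sd == 0))
})

test_that("qc_pca separates simulated batches and is stable under duplication", {
  cfg1 <- sim_config(n_bins = 600, n_samples = 12, seed = 31,
                     gc_opt_mean = 0.40, batch_sd = 0)
  cfg2 <- sim_config(n_bins = 600, n_samples = 12, seed = 32,
                     gc_opt_mean = 0.52, batch_sd = 0)
  s1 <- simulate_coverage(cfg1); s2 <- simulate_coverage(cfg2)
  bins <- s1$cm$bins                      # share bin set; gc from batch 1
  joint <- cov_matrix(bins, cbind(s1$cm$counts,
    `colnames<-`(s2$cm$counts, sprintf("t%03d", 1:12))))
  pc <- qc_pca(joint)
  lab <- rep(1:2, each = 12)
  x <- pc$scores[, 1]
  sil <- vapply(seq_along(x), function(i) {
    a <- mean(abs(x[i] - x[lab == lab[i]][-which(which(lab == lab[i]) == i)]))
    b <- mean(abs(x[i] - x[lab != lab[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  # single batch (exchangeable samples): no dominant component
  s0 <- simulate_coverage(sim_config(n_bins = 600, n_samples = 12, seed = 33,
                                     gc_bias = FALSE, batch_sd = 0))
  ve <- qc_pca(s0$cm)$var_explained
  expect_lt(ve[1], 3 * mean(ve[-1]))

  # duplicated samples get identical scores
  dup <- cov_matrix(bins, cbind(s1$cm$counts,
    dup1 = s1$cm$counts[, 1]))
  sc <- qc_pca(dup)$scores
  expect_equal(sc["dup1", ], sc["s001", ], ignore_attr = TRUE)
})

test_that("after targeted normalization the per-bin SD distribution matches
           the Gaussian-noise null arm of the simulator", {
  run_arm <- function(noise, seed) {
    cfg <- sim_config(n_bins = 2000, n_samples = 45, seed = seed, noise = noise)
    sim <- simulate_coverage(cfg)
    cc <- filter_bins(gc_correct(sim$cm))
    rp <- build_reference(cc, seed = seed + 1)
    nn <- normalize_targeted(cc, rp)
    apply(zmat(nn, rp), 1, sd, na.rm = TRUE)
  }
  sd_nb <- run_arm("nb", 23)
  sd_gauss <- run_arm("gaussian", 23)
  ks <- suppressWarnings(stats::ks.test(sd_nb, sd_gauss))
  expect_gt(ks$p.value, 0.01)
})
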