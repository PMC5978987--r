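#' Z-score every bin of a sample against the reference profile
#'
#' For each usable bin, `z = (x - loc) / scale` where `x` is the sample's
#' normalized coverage on the profile's analysis scale (square-root by
#' default, which symmetrizes counting noise) and `loc`/`scale` are the
#' robust per-bin statistics of the reference panel on that same scale.
#' Bins with zero/missing scale or a missing normalized value are
#' excluded and listed in the `excluded` attribute.
#'
#' @param cm a normalized [cov_matrix].
#' @param rp a `ref_profile` (or any list with per-bin `loc` and `scale`,
#'   e.g. [panel_stats()] output, plus the `usable` flag taken from `cm`).
#' @param sample sample ID to test.
#' @return data.frame of class `bin_tests`: `bin` (row index in `cm`),
#'   `chrom`, `start`, `end`, `x`, `z`.
#' @export
zscore_bins <- function(cm, rp, sample) {
  stopifnot(inherits(cm, "cov_matrix"), sample %in% samples(cm))
  if (cm$state != "normalized") stop("zscore_bins expects a normalized matrix")
  usable <- if (!is.null(rp$usable)) rp$usable else cm$bins$usable
  transform <- if (is.null(rp$transform)) "identity" else rp$transform
  x <- cm$counts[, sample]
  ok <- usable & !is.na(x) & !is.na(rp$scale) & rp$scale > 0
  excluded <- which(usable & !ok)
  idx <- which(ok)
  xt <- .apply_transform(x[idx], transform)
  out <- data.frame(bin = idx, cm$bins[idx, c("chrom", "start", "end")],
                    x = x[idx], z = (xt - rp$loc[idx]) / rp$scale[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "sample") <- sample
  class(out) <- c("bin_tests", "data.frame")
  out
}

#' Estimate FDR over a sample's bin Z-scores
#'
#' The null is estimated from the centre of the sample's own Z-score
#' distribution, so that true CNVs in the tails do not inflate it: a
#' scaled-t null whose scale `sigma0` matches the median of `|z|` and
#' whose degrees of freedom match the 95%/50% quantile ratio of `|z|`
#' (a panel of a few dozen samples leaves residual per-bin variance
#' heterogeneity that makes the null mildly heavier-tailed than normal;
#' with normally distributed Z-scores the fit returns the normal).
#' Two-sided p-values are Benjamini-Hochberg adjusted across the sample's
#' tested bins and a bin is marked abnormal when its q-value falls below
#' `fdr_threshold`.
#'
#' @param tests a `bin_tests` data.frame from [zscore_bins()].
#' @param fdr_threshold FDR level for calling a bin abnormal (default 0.05).
#' @return `tests` with columns `p`, `q`, `abnormal`, `direction`
#'   (`loss`/`gain`/`none`); `sigma0`, `df0` and `fdr_threshold` as
#'   attributes.
#' @export
estimate_fdr <- function(tests, fdr_threshold = 0.05) {
  z <- tests$z
  if (length(z) < 500) {
    warning("fewer than 500 tested bins; sigma0 set to 1")
    sigma0 <- 1
    df0 <- Inf
  } else {
    fit <- .fit_t_null(z)
    sigma0 <- fit$sigma0
    df0 <- fit$df0
    if (!is.finite(sigma0) || sigma0 <= 0) { sigma0 <- 1; df0 <- Inf }
  }
  p <- pmin(2 * .pt_null(-abs(z) / sigma0, df0), 1)
  q <- stats::p.adjust(p, method = "BH")
  tests$p <- p
  tests$q <- q
  tests$abnormal <- q < fdr_threshold
  tests$direction <- ifelse(!tests$abnormal, "none", ifelse(z < 0, "loss", "gain"))
  attr(tests, "sigma0") <- sigma0
  attr(tests, "df0") <- df0
  attr(tests, "fdr_threshold") <- fdr_threshold
  tests
}

# Scaled-t null fitted to the centre of the |z| distribution: sigma0 from
# the median, df from the q95/q50 ratio (both quantiles robust to a few
# percent of true CNV bins in the tails). df on a coarse grid; the normal
# is returned when the observed ratio is no heavier than normal.
.fit_t_null <- function(z, df_grid = c(3:30, seq(35, 100, by = 5), Inf)) {
  q50 <- stats::quantile(abs(z), 0.5, names = FALSE)
  q95 <- stats::quantile(abs(z), 0.95, names = FALSE)
  if (!is.finite(q50) || q50 <= 0) return(list(sigma0 = NA_real_, df0 = Inf))
  r_obs <- q95 / q50
  r_t <- vapply(df_grid, function(d) {
    if (is.infinite(d)) stats::qnorm(0.975) / stats::qnorm(0.75)
    else stats::qt(0.975, d) / stats::qt(0.75, d)
  }, numeric(1))
  df0 <- df_grid[which.min(abs(log(r_t) - log(r_obs)))]
  denom <- if (is.infinite(df0)) stats::qnorm(0.75) else stats::qt(0.75, df0)
  list(sigma0 = q50 / denom, df0 = df0)
}

.pt_null <- function(q, df0) {
  if (is.infinite(df0)) stats::pnorm(q) else stats::pt(q, df0)
}

#' Merge abnormal bins into CNV calls
#'
#' `consecutive` mode joins runs of same-direction abnormal bins on a
#' chromosome, tolerating up to `stitch` non-abnormal tested bins inside a
#' run. `cbs` mode segments the Z-score track by recursive binary
#' change-point search with a permutation stopping rule and turns segments
#' whose combined Z meets the sample's abnormality criterion into calls.
#' Region significance is recomputed by Stouffer combination
#' (`z_region = mean(z) * sqrt(nbins)` over the region's bins), converted
#' to p through the sample's `sigma0` and BH-adjusted across the sample's
#' calls against the full number of tested bins (regions were nominated
#' from that many hypotheses). All merged regions are returned;
#' [call_cnvs()] keeps those with `q` below the FDR threshold.
#'
#' @param tests output of [estimate_fdr()].
#' @param stitch number of non-abnormal bins tolerated inside a run
#'   (consecutive mode; default 0).
#' @param segmenter `"consecutive"` or `"cbs"`.
#' @param cbs_alpha permutation significance needed to keep a CBS split
#'   (default 0.01).
#' @param cbs_nperm permutations per CBS split test (default 200).
#' @return data.frame of calls: `sample`, `chrom`, `start`, `end`, `type`
#'   (`DEL`/`DUP`), `nbins`, `z`, `q`.
#' @export
merge_calls <- function(tests, stitch = 0, segmenter = c("consecutive", "cbs"),
                        cbs_alpha = 0.01, cbs_nperm = 200) {
  segmenter <- match.arg(segmenter)
  if (stitch < 0) stop("stitch must be >= 0")
  sigma0 <- attr(tests, "sigma0")
  df0 <- attr(tests, "df0")
  if (is.null(df0)) df0 <- Inf
  fdr <- attr(tests, "fdr_threshold")
  smp <- attr(tests, "sample")
  if (is.null(sigma0)) stop("tests must come from estimate_fdr()")

  regions <- list()
  for (ch in unique(tests$chrom)) {
    tt <- tests[tests$chrom == ch, ]
    tt <- tt[order(tt$start), ]
    if (segmenter == "consecutive") {
      regions <- c(regions, .runs_consecutive(tt, stitch))
    } else {
      regions <- c(regions, .runs_cbs(tt, sigma0, fdr, cbs_alpha, cbs_nperm))
    }
  }
  if (length(regions) == 0)
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(), type = character(),
                      nbins = integer(), z = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  calls <- do.call(rbind, regions)
  calls$sample <- if (!is.null(smp)) smp else NA_character_
  p_region <- pmin(2 * .pt_null(-abs(calls$z) / sigma0, df0), 1)
  # BH across the sample's calls, but against the number of bins that were
  # tested: candidate regions were nominated from that many hypotheses, so
  # per-call multiplicity alone would understate it.
  m <- max(nrow(tests), nrow(calls))
  o <- order(p_region)
  qv <- rev(cummin(rev(p_region[o] * m / seq_along(o))))
  calls$q <- numeric(nrow(calls))
  calls$q[o] <- pmin(qv, 1)
  calls$type <- ifelse(calls$z < 0, "DEL", "DUP")
  calls <- calls[, c("sample", "chrom", "start", "end", "type", "nbins", "z", "q")]
  rownames(calls) <- NULL
  calls
}

# Same-direction runs of abnormal bins, tolerating <= stitch tested
# non-abnormal bins per gap. tt: one chromosome, sorted by start.
.runs_consecutive <- function(tt, stitch) {
  out <- list()
  for (dir in c("loss", "gain")) {
    ab <- which(tt$direction == dir)
    if (length(ab) == 0) next
    gap <- c(Inf, diff(ab) - 1)          # tested bins skipped between hits
    grp <- cumsum(gap > stitch)
    for (g in unique(grp)) {
      i <- ab[grp == g]
      zr <- mean(tt$z[i]) * sqrt(length(i))
      out[[length(out) + 1]] <- data.frame(
        chrom = tt$chrom[1], start = min(tt$start[i]), end = max(tt$end[i]),
        nbins = length(i), z = zr, stringsAsFactors = FALSE)
    }
  }
  out
}

# Recursive change-point segmentation of the z track (circular binary
# segmentation: the candidate change is an interval (i, j], tested
# against the rest of the segment with a permutation stopping rule).
# Kept segments are those whose Stouffer z reaches the FDR-threshold
# quantile with a mean shift beyond the null scale.
.runs_cbs <- function(tt, sigma0, fdr, alpha, nperm) {
  z <- tt$z
  cuts <- c(0, length(z))
  # max two-cut statistic: |mean_in - mean_out| * sqrt(len*(n-len)/n),
  # equal to |centered window sum| * sqrt(n/(len*(n-len))); scanned per
  # window length with cumulative sums
  max_stat <- function(v) {
    n <- length(v)
    cs <- c(0, cumsum(v - mean(v)))
    best <- 0; bi <- 0L; bj <- 0L
    for (l in seq_len(n - 1)) {
      s <- abs(cs[(l + 1):(n + 1)] - cs[seq_len(n + 1 - l)]) *
        sqrt(n / (l * (n - l)))
      k <- which.max(s)
      if (s[k] > best) { best <- s[k]; bi <- k - 1L; bj <- k - 1L + l }
    }
    list(stat = best, i = bi, j = bj)
  }
  segment <- function(lo, hi) {              # (lo, hi]: 0-based cut points
    n <- hi - lo
    if (n < 4) return()
    zz <- z[(lo + 1):hi]
    best <- max_stat(zz)
    null <- vapply(seq_len(nperm), function(i) max_stat(sample(zz))$stat,
                   numeric(1))
    p <- (1 + sum(null >= best$stat)) / (nperm + 1)
    if (p < alpha) {
      new_cuts <- lo + c(best$i, best$j)
      new_cuts <- new_cuts[new_cuts > lo & new_cuts < hi]
      cuts <<- sort(unique(c(cuts, new_cuts)))
      bounds <- sort(unique(c(lo, new_cuts, hi)))
      for (b in seq_len(length(bounds) - 1)) segment(bounds[b], bounds[b + 1])
    }
  }
  segment(0, length(z))
  out <- list()
  zcrit <- stats::qnorm(1 - fdr / 2) * sigma0
  for (i in seq_len(length(cuts) - 1)) {
    idx <- (cuts[i] + 1):cuts[i + 1]
    zr <- mean(z[idx]) * sqrt(length(idx))
    if (abs(zr) >= zcrit && abs(mean(z[idx])) > sigma0) {
      out[[length(out) + 1]] <- data.frame(
        chrom = tt$chrom[1], start = min(tt$start[idx]), end = max(tt$end[idx]),
        nbins = length(idx), z = zr, stringsAsFactors = FALSE)
    }
  }
  out
}

#' Estimate copy number for CNV calls
#'
#' Copy number is twice the ratio of the sample's mean normalized coverage
#' over the call's bins to the mean reference coverage over the same bins.
#'
#' @param calls data.frame of calls from [merge_calls()].
#' @param cm the normalized [cov_matrix] the calls came from.
#' @param rp the `ref_profile` used for normalization.
#' @return `calls` with a numeric `cn` column.
#' @export
estimate_cn <- function(calls, cm, rp) {
  if (nrow(calls) == 0) { calls$cn <- numeric(0); return(calls) }
  cn <- numeric(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    sel <- cm$bins$chrom == calls$chrom[i] &
      cm$bins$start < calls$end[i] & cm$bins$end > calls$start[i] &
      rp$usable
    x <- cm$counts[sel, calls$sample[i]]
    ref <- rp$ref_mean[sel]
    ok <- !is.na(x) & !is.na(ref)
    cn[i] <- if (any(ok)) 2 * mean(x[ok]) / mean(ref[ok]) else NA_real_
  }
  calls$cn <- pmax(cn, 0)
  calls
}

#' Run the per-sample CNV calling pipeline
#'
#' Convenience wrapper: Z-scores, FDR estimation, call merging and copy
#' number estimation for each requested sample of a normalized matrix.
#'
#' @inheritParams zscore_bins
#' @inheritParams estimate_fdr
#' @inheritParams merge_calls
#' @param test_samples samples to call (default all).
#' @return data.frame of calls across samples (possibly zero rows).
#' @export
call_cnvs <- function(cm, rp, test_samples = NULL, fdr_threshold = 0.05,
                      stitch = 0, segmenter = "consecutive") {
  if (is.null(test_samples)) test_samples <- samples(cm)
  out <- lapply(test_samples, function(s) {
    tests <- estimate_fdr(zscore_bins(cm, rp, s), fdr_threshold)
    calls <- merge_calls(tests, stitch = stitch, segmenter = segmenter)
    calls <- calls[calls$q < fdr_threshold, , drop = FALSE]  # confirm regions
    estimate_cn(calls, cm, rp)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
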