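#' Coverage-bias QC diagnostics
#'
#' Quantifies the two technical-bias signatures that motivate panel-based
#' normalization: region effects (the spread of per-bin cross-sample mean
#' and SD coverage, compared to two null distributions) and sample rank
#' bias (the share of the genome in which each sample has the highest, or
#' lowest, coverage — under exchangeability every share is about 1/n).
#'
#' The shuffled null permutes each sample's values across bins (destroying
#' region effects while keeping each sample's marginal distribution); the
#' Gaussian null draws a matrix of independent normals matched to the
#' observed global mean and SD.
#'
#' @param cm a [cov_matrix]; usable bins only are used.
#' @param seed seed for the shuffled and Gaussian nulls.
#' @return list of class `qc_report`: `bin_mean`, `bin_sd`, the same for
#'   `shuffled` and `gaussian` nulls, `max_share`/`min_share` per sample,
#'   and per-sample `z_normality` (KS distance of standardized coverage to
#'   the normal), with `worst_sample` named.
#' @export
qc_bias <- function(cm, seed = 1) {
  stopifnot(inherits(cm, "cov_matrix"))
  m <- cm$counts[cm$bins$usable, , drop = FALSE]
  set.seed(seed)
  shuf <- apply(m, 2, sample)
  gauss <- matrix(stats::rnorm(length(m), mean = mean(m), sd = stats::sd(m)),
                  nrow = nrow(m))
  stat <- function(x) list(mean = rowMeans(x), sd = apply(x, 1, stats::sd))
  obs <- stat(m); sh <- stat(shuf); ga <- stat(gauss)

  imax <- apply(m, 1, which.max)
  imin <- apply(m, 1, which.min)
  max_share <- tabulate(imax, ncol(m)) / nrow(m)
  min_share <- tabulate(imin, ncol(m)) / nrow(m)
  names(max_share) <- names(min_share) <- colnames(m)

  zn <- apply(scale(m), 2, .ks_normal)
  structure(list(bin_mean = obs$mean, bin_sd = obs$sd,
                 shuffled = sh, gaussian = ga,
                 max_share = max_share, min_share = min_share,
                 z_normality = zn,
                 worst_sample = names(which.max(zn))),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d bins, %d samples; worst-normality sample: %s (KS %.3f)\n",
              length(x$bin_mean), length(x$max_share), x$worst_sample,
              max(x$z_normality)))
  cat(sprintf("max-coverage share range: %.3f-%.3f (uniform: %.3f)\n",
              min(x$max_share), max(x$max_share), 1 / length(x$max_share)))
  invisible(x)
}

#' Principal component analysis of bin coverage
#'
#' Decomposes the sample x bin matrix (bins centered) to expose batch
#' effects: samples processed differently separate on the leading
#' components. Samples are first rescaled to a common median so that
#' sequencing depth does not masquerade as the first component.
#' Recommended before choosing a reference panel.
#'
#' @param cm a [cov_matrix]; usable bins only are used.
#' @param n_comp number of component scores to return (default 2).
#' @return list with `scores` (samples x components) and `var_explained`.
#' @export
qc_pca <- function(cm, n_comp = 2) {
  stopifnot(inherits(cm, "cov_matrix"))
  m <- cm$counts[cm$bins$usable, , drop = FALSE]
  meds <- apply(m, 2, stats::median)
  m <- t(sweep(m, 2, stats::median(meds) / meds, `*`))
  pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_comp, ncol(pr$x))
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       var_explained = pr$sdev^2 / sum(pr$sdev^2))
}

#' Per-sample deviation of Z-scores from normality
#'
#' Kolmogorov-Smirnov distance between each sample's Z-scores and the
#' standard normal. The comparison metric used to contrast normalization
#' strategies: good normalization leaves every sample's Z-scores close to
#' N(0,1).
#'
#' @param z matrix of Z-scores, bins x samples (NAs ignored).
#' @return Named numeric vector of KS distances, one per sample.
#' @export
z_normality <- function(z) {
  apply(z, 2, .ks_normal)
}
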