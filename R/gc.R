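#' Correct GC-content bias in raw bin counts
#'
#' Each sample's counts are divided by a smooth per-sample trend of count
#' versus bin GC fraction and rescaled so the sample's genome-wide median
#' is preserved. The trend is a local regression (span `span`) fitted to
#' mean counts over `knots` GC-quantile knots, evaluated at each bin's GC
#' by interpolation. Bins where the fitted trend falls below 1% of the
#' sample median cannot be corrected reliably: their corrected count is set
#' to 0 and they are recorded in the `gc_flagged` attribute.
#'
#' @param cm a [cov_matrix] in state `"raw"` with defined `gc` on its
#'   usable bins.
#' @param span loess span for the GC trend (default 0.3).
#' @param knots number of GC quantile knots (default 100).
#'
#' @return A [cov_matrix] in state `"gc_corrected"`.
#' @export
gc_correct <- function(cm, span = 0.3, knots = 100) {
  stopifnot(inherits(cm, "cov_matrix"))
  if (cm$state != "raw") stop("gc_correct expects a raw coverage matrix")
  usable <- cm$bins$usable & !is.na(cm$bins$gc)
  if (sum(usable) < 200)
    stop("fewer than 200 usable bins with defined GC; trend unidentifiable")

  gc <- cm$bins$gc
  corrected <- cm$counts * 1.0
  flagged <- matrix(FALSE, nrow(cm$counts), ncol(cm$counts),
                    dimnames = dimnames(cm$counts))

  qs <- unique(stats::quantile(gc[usable], probs = seq(0, 1, length.out = knots + 1)))
  knot_bin <- cut(gc, breaks = qs, include.lowest = TRUE)
  knot_gc <- tapply(gc[usable], knot_bin[usable], mean)

  for (s in seq_len(ncol(cm$counts))) {
    x <- cm$counts[usable, s]
    med <- stats::median(x)
    knot_count <- tapply(x, knot_bin[usable], mean)
    ok <- !is.na(knot_gc) & !is.na(knot_count)
    fit <- stats::loess(knot_count[ok] ~ knot_gc[ok], span = span, degree = 2)
    trend <- stats::approx(knot_gc[ok], stats::fitted(fit),
                           xout = gc, rule = 2)$y
    has_gc <- !is.na(gc)
    low <- has_gc & trend < 0.01 * med
    corr <- corrected[, s]
    corr[has_gc] <- cm$counts[has_gc, s] * med / trend[has_gc]
    corr[low] <- 0
    # exact median preservation (the trend division shifts it slightly)
    med_corr <- stats::median(corr[usable])
    if (med_corr > 0) corr[has_gc] <- corr[has_gc] * med / med_corr
    corrected[, s] <- corr
    flagged[low, s] <- TRUE
  }
  out <- cov_matrix(cm$bins, corrected, state = "gc_corrected")
  attr(out, "gc_flagged") <- flagged
  out
}

#' Filter bins with extreme or unstable coverage
#'
#' Marks unusable (reason-logged) any bin whose cross-sample median
#' coverage is below `low_frac` times, or above `high_mult` times, the
#' genome-wide median (median of usable-bin medians), or that has a zero
#' count in more than `max_zero_frac` of samples. Comparisons are strict,
#' so a bin sitting exactly on a threshold is retained.
#'
#' @param cm a [cov_matrix] in state `"raw"` or `"gc_corrected"`.
#' @param low_frac low-coverage fraction of the genome-wide median
#'   (default 0.1).
#' @param high_mult high-coverage multiple of the genome-wide median
#'   (default 3).
#' @param max_zero_frac maximum tolerated fraction of samples with a zero
#'   count (default 0.1).
#'
#' @return The filtered [cov_matrix]; the per-bin reason log (columns
#'   `bin`, `chrom`, `start`, `end`, `reason`) is in the `filter_log`
#'   attribute.
#' @export
filter_bins <- function(cm, low_frac = 0.1, high_mult = 3, max_zero_frac = 0.1) {
  stopifnot(inherits(cm, "cov_matrix"))
  if (!cm$state %in% c("raw", "gc_corrected"))
    stop("filter_bins expects a raw or gc_corrected matrix")
  usable <- cm$bins$usable
  med <- .row_medians(cm$counts)
  gw <- stats::median(med[usable])
  zero_frac <- rowMeans(cm$counts == 0)

  reason <- rep(NA_character_, nrow(cm$bins))
  reason[usable & med < low_frac * gw] <- "low"
  reason[usable & med > high_mult * gw] <- "high"
  reason[usable & is.na(reason) & zero_frac > max_zero_frac] <- "zero"

  drop <- !is.na(reason)
  cm$bins$usable[drop] <- FALSE
  if (!any(cm$bins$usable)) stop("all bins filtered out")
  log <- data.frame(bin = which(drop), cm$bins[drop, c("chrom", "start", "end")],
                    reason = reason[drop], stringsAsFactors = FALSE)
  rownames(log) <- NULL
  attr(cm, "filter_log") <- log
  cm
}
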