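#' Build a targeted-normalization reference profile
#'
#' For every usable bin, finds the K "supporting" bins whose coverage
#' profile across the reference samples is most similar to the bin's own
#' profile. Each bin's reference vector is scaled to mean 1 (so similarity
#' ignores absolute depth) and compared by Euclidean distance to a shared,
#' seeded candidate pool of `C` usable bins; the bin itself always belongs
#' to its support set. The reference samples are then normalized against
#' these supports, and per-bin robust location (median) and scale
#' (1.4826 x MAD, falling back to the SD when the MAD is 0) are stored for
#' downstream Z-score testing.
#'
#' @param cm a [cov_matrix] in state `"gc_corrected"`.
#' @param ref_samples sample IDs to use as the reference panel (default:
#'   all samples). Fewer than 20 reference samples triggers a warning.
#' @param K number of supporting bins per bin, including the bin itself
#'   (default 100).
#' @param C size of the shared candidate pool (default 5000, capped at the
#'   number of usable bins).
#' @param seed integer seed for the candidate-pool draw.
#' @param transform analysis scale for the Z-score statistics: `"sqrt"`
#'   (default) stabilizes the variance of counting noise and removes its
#'   right skew, so the normal null holds out into the tails;
#'   `"identity"` tests the coverage scale directly.
#'
#' @return An object of class `ref_profile`: list with `ref_samples`,
#'   `support` (usable-bins x K matrix of bin indices), `ref_med`, `loc`,
#'   `scale` (on the analysis scale), `ref_mean` (linear scale, for copy
#'   number), `usable`, `K`, `C`, `seed`, `transform` and the bin table.
#' @export
build_reference <- function(cm, ref_samples = NULL, K = 100, C = 5000, seed = 1,
                            transform = c("sqrt", "identity")) {
  transform <- match.arg(transform)
  stopifnot(inherits(cm, "cov_matrix"))
  if (cm$state != "gc_corrected")
    stop("build_reference expects a gc_corrected matrix")
  if (is.null(ref_samples)) ref_samples <- samples(cm)
  stopifnot(all(ref_samples %in% samples(cm)))
  if (length(ref_samples) < 20)
    warning("fewer than 20 reference samples; 20 or more are recommended")

  M <- cm$counts[, ref_samples, drop = FALSE]
  usable <- cm$bins$usable
  usable[usable][rowSums(M[usable, , drop = FALSE]) == 0] <- FALSE  # degenerate all-zero bins
  u <- which(usable)
  nb <- length(u)
  if (K > nb) stop("K exceeds the number of usable bins")
  C <- min(C, nb)
  if (K > C) stop("K must be <= C")

  set.seed(seed)
  pool <- sort(sample(u, C))

  V <- M[u, , drop = FALSE]
  V <- V / rowMeans(V)
  Vp <- M[pool, , drop = FALSE]
  Vp <- Vp / rowMeans(Vp)
  # squared Euclidean distances between scaled vectors, bins x pool
  d2 <- outer(rowSums(V^2), rep(1, C)) + outer(rep(1, nb), rowSums(Vp^2)) -
    2 * tcrossprod(V, Vp)

  support <- matrix(NA_integer_, nrow = nb, ncol = K)
  pool_pos <- match(u, pool)  # position of each usable bin inside the pool, NA if absent
  for (i in seq_len(nb)) {
    d <- d2[i, ]
    if (!is.na(pool_pos[i])) d[pool_pos[i]] <- Inf  # the bin itself enters explicitly
    nn <- pool[order(d, pool)[seq_len(K - 1)]]
    support[i, ] <- c(u[i], nn)
  }

  ref_med <- rep(NA_real_, nrow(cm$bins))
  ref_med[u] <- .row_medians(M[u, , drop = FALSE])

  rp <- structure(list(ref_samples = ref_samples, support = support,
                       usable = usable, ref_med = ref_med,
                       loc = NULL, scale = NULL, ref_mean = NULL,
                       K = K, C = C, seed = seed, transform = transform,
                       bins = cm$bins[, c("chrom", "start", "end")]),
                  class = "ref_profile")

  ref_norm <- normalize_targeted(cm, rp)
  Rn <- ref_norm$counts[u, ref_samples, drop = FALSE]
  st <- .robust_bin_stats(.apply_transform(Rn, transform), length(ref_samples))
  loc <- scl <- mn <- rep(NA_real_, nrow(cm$bins))
  loc[u] <- st$loc; scl[u] <- st$scale; mn[u] <- rowMeans(Rn, na.rm = TRUE)
  rp$loc <- loc; rp$scale <- scl; rp$ref_mean <- mn
  rp
}

.apply_transform <- function(x, transform) {
  if (transform == "sqrt") sqrt(pmax(x, 0)) else x
}

# Robust per-bin location/scale of a panel matrix: median and 1.4826*MAD
# (SD fallback when the MAD is 0), with the per-bin variance empirical-
# Bayes moderated toward a location trend (limma::squeezeVar, robust).
# Residual df are scaled by the MAD's 37% Gaussian efficiency; without
# moderation the scale's sampling error at panel sizes of a few dozen
# leaves bins with badly underestimated scale, which turn into recurrent
# single-bin false positives across all samples.
.robust_bin_stats <- function(M, n_ref) {
  loc <- .row_medians(M, na.rm = TRUE)
  mad <- .row_mads(M, center = loc, na.rm = TRUE)
  sdv <- apply(M, 1, stats::sd, na.rm = TRUE)
  scl <- ifelse(mad > 0, mad, sdv)
  ok <- is.finite(scl) & scl > 0 & is.finite(loc) & loc > 0
  if (sum(ok) >= 50) {
    df <- max(2, round(0.37 * (n_ref - 1)))
    sq <- tryCatch(
      limma::squeezeVar(scl[ok]^2, df = df, covariate = log(loc[ok]),
                        robust = TRUE),
      error = function(e) NULL)
    if (!is.null(sq)) scl[ok] <- sqrt(sq$var.post)
  }
  list(loc = loc, scale = scl)
}

#' @export
print.ref_profile <- function(x, ...) {
  cat(sprintf("ref_profile: %d reference samples, %d usable bins, K=%d, C=%d, seed=%d\n",
              length(x$ref_samples), sum(x$usable), x$K, x$C, x$seed))
  invisible(x)
}

#' Targeted normalization against a reference profile
#'
#' For sample s and bin b the normalization factor is the median over b's
#' supporting bins j of `ref_med[j] / count[s, j]` (zero-count supports are
#' skipped); the normalized value is `count[s, b]` times that factor. A
#' sample whose count is zero in more than half of a bin's supports gets a
#' missing value there (recorded in the `norm_flagged` attribute). Because
#' the factor is a ratio, any global per-sample depth scaling cancels
#' exactly.
#'
#' @param cm a [cov_matrix] in state `"gc_corrected"` with the same bins
#'   as `rp`.
#' @param rp a `ref_profile` from [build_reference()].
#'
#' @return A [cov_matrix] in state `"normalized"`; unusable bins are NA.
#' @export
normalize_targeted <- function(cm, rp) {
  stopifnot(inherits(cm, "cov_matrix"), inherits(rp, "ref_profile"))
  if (nrow(cm$bins) != nrow(rp$bins) ||
      !all(cm$bins$start == rp$bins$start & cm$bins$chrom == rp$bins$chrom))
    stop("bins of cm and rp do not match")
  u <- which(rp$usable)
  K <- ncol(rp$support)
  norm <- matrix(NA_real_, nrow(cm$counts), ncol(cm$counts),
                 dimnames = dimnames(cm$counts))
  flagged <- matrix(FALSE, nrow(cm$counts), ncol(cm$counts),
                    dimnames = dimnames(cm$counts))
  sup <- rp$support
  for (s in seq_len(ncol(cm$counts))) {
    cnt <- cm$counts[, s]
    ratio <- rp$ref_med / cnt
    ratio[cnt == 0] <- NA_real_
    R <- matrix(ratio[sup], nrow = nrow(sup))
    n_ok <- rowSums(!is.na(R))
    f <- apply(R, 1, stats::median, na.rm = TRUE)
    bad <- n_ok < K / 2
    f[bad] <- NA_real_
    flagged[u[bad], s] <- TRUE
    norm[u, s] <- cnt[u] * f
  }
  out <- cov_matrix(cm$bins, norm, state = "normalized")
  out$bins$usable <- rp$usable
  attr(out, "norm_flagged") <- flagged
  out
}

#' Baseline normalizations: global median scaling and quantile
#'
#' The comparison methods for targeted normalization: `"median"` rescales
#' every sample to a common genome-wide median; `"quantile"` applies
#' classic rank-based quantile normalization across samples (ties receive
#' the average rank value).
#'
#' @param cm a [cov_matrix] (raw or gc_corrected).
#' @param method `"median"` or `"quantile"`.
#' @return A [cov_matrix] in state `"normalized"`.
#' @export
normalize_baseline <- function(cm, method = c("median", "quantile")) {
  method <- match.arg(method)
  stopifnot(inherits(cm, "cov_matrix"))
  m <- cm$counts
  if (method == "median") {
    meds <- apply(m, 2, stats::median)
    target <- stats::median(meds)
    m <- sweep(m, 2, target / meds, `*`)
  } else {
    m <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(m) <- dimnames(cm$counts)
  }
  cov_matrix(cm$bins, m, state = "normalized")
}

#' Per-bin location and scale of a normalized panel
#'
#' Robust per-bin statistics (median and moderated 1.4826 x MAD, exactly
#' as [build_reference()] stores for its panel) of a set of samples. Used
#' to Z-score data normalized by a baseline method for comparison with
#' targeted normalization.
#'
#' @param cm a normalized [cov_matrix].
#' @param ref_samples samples defining the panel (default all).
#' @param transform analysis scale, as in [build_reference()].
#' @return list with per-bin `loc`, `scale`, `ref_mean` (NA off usable
#'   bins), `usable` and `transform`.
#' @export
panel_stats <- function(cm, ref_samples = NULL, transform = c("sqrt", "identity")) {
  transform <- match.arg(transform)
  if (is.null(ref_samples)) ref_samples <- samples(cm)
  u <- which(cm$bins$usable)
  M <- cm$counts[u, ref_samples, drop = FALSE]
  st <- .robust_bin_stats(.apply_transform(M, transform), length(ref_samples))
  loc <- scl <- mn <- rep(NA_real_, nrow(cm$bins))
  loc[u] <- st$loc; scl[u] <- st$scale
  mn[u] <- rowMeans(M, na.rm = TRUE)
  list(loc = loc, scale = scl, ref_mean = mn, usable = cm$bins$usable,
       transform = transform)
}
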