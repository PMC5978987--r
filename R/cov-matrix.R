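#' Bin-by-sample coverage matrix
#'
#' The central container of the package: a set of genome bins together with
#' a bins x samples matrix of read counts (or corrected/normalized coverage)
#' and a state flag recording how far along the pipeline the values are.
#'
#' @param bins data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `gc` (fraction in \[0,1\] or `NA`) and `usable` (logical).
#'   Missing `gc`/`usable` columns are added (`gc = NA`, `usable = TRUE`
#'   only when `gc` is defined).
#' @param counts numeric matrix, one row per bin, one named column per
#'   sample. Raw counts must be non-negative integers.
#' @param state one of `"raw"`, `"gc_corrected"`, `"normalized"`.
#'
#' @return An object of class `cov_matrix`: a list with elements `bins`,
#'   `counts` and `state`.
#' @export
cov_matrix <- function(bins, counts, state = c("raw", "gc_corrected", "normalized")) {
  state <- match.arg(state)
  stopifnot(is.data.frame(bins), all(c("chrom", "start", "end") %in% names(bins)))
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(bins))
    stop("counts must have one row per bin")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts must have unique sample names as column names")
  if (state == "raw") {
    v <- counts[!is.na(counts)]
    if (any(v < 0) || any(v != round(v)))
      stop("raw counts must be non-negative integers")
  }
  if (is.null(bins$gc)) bins$gc <- NA_real_
  if (is.null(bins$usable)) bins$usable <- !is.na(bins$gc)
  bins$usable <- bins$usable & !is.na(bins$gc)
  o <- order(bins$chrom, bins$start)
  if (is.unsorted(o)) { bins <- bins[o, , drop = FALSE]; counts <- counts[o, , drop = FALSE] }
  rownames(bins) <- NULL
  structure(list(bins = bins, counts = counts, state = state), class = "cov_matrix")
}

#' @export
print.cov_matrix <- function(x, ...) {
  cat(sprintf("cov_matrix: %d bins x %d samples [%s], %d usable bins\n",
              nrow(x$bins), ncol(x$counts), x$state, sum(x$bins$usable)))
  invisible(x)
}

#' @export
dim.cov_matrix <- function(x) dim(x$counts)

#' Sample names of a coverage matrix
#' @param cm a [cov_matrix].
#' @return Character vector of sample IDs.
#' @export
samples <- function(cm) colnames(cm$counts)

#' Subset a coverage matrix by sample
#' @param cm a [cov_matrix].
#' @param keep character vector of sample IDs to keep.
#' @return A [cov_matrix] restricted to `keep` (bins unchanged).
#' @export
subset_samples <- function(cm, keep) {
  stopifnot(all(keep %in% samples(cm)))
  cm$counts <- cm$counts[, keep, drop = FALSE]
  cm
}

#' Write / read a coverage matrix as TSV
#'
#' The TSV layout is `chrom, start, end, gc, usable` followed by one column
#' per sample; the coverage state is recorded on a `#state=` header line.
#'
#' @param cm a [cov_matrix].
#' @param path file path.
#' @return `write_counts` returns `path` invisibly; `read_counts` returns a
#'   [cov_matrix].
#' @export
write_counts <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#state=%s", cm$state), con)
  df <- cbind(cm$bins[, c("chrom", "start", "end", "gc", "usable")],
              as.data.frame(cm$counts, check.names = FALSE))
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1)
  state <- if (startsWith(first, "#state=")) sub("^#state=", "", first) else "raw"
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("chrom", "start", "end", "gc", "usable")
  bins <- df[, meta]
  bins$gc <- suppressWarnings(as.numeric(bins$gc))
  counts <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  cov_matrix(bins, counts, state = state)
}

#' Write / read CNV calls as TSV
#'
#' Calls use BED-compatible first three columns (`chrom`, `start`, `end`,
#' 0-based half-open) followed by `sample`, `type`, `nbins`, `z`, `q`, `cn`.
#'
#' @param calls data.frame of calls as returned by [merge_calls()] /
#'   [call_cnvs()].
#' @param path file path.
#' @export
write_calls <- function(calls, path) {
  cols <- intersect(c("chrom", "start", "end", "sample", "type", "nbins", "z", "q", "cn"),
                    names(calls))
  df <- calls[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 10, trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
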