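#' Count properly mapped reads per bin from BAM files
#'
#' Counts, for every sample, the reads whose leftmost aligned base falls in
#' each bin. A read qualifies when it is a primary alignment, mapped,
#' not flagged as duplicate, carries the proper-pair flag and has
#' MAPQ >= `min_mapq`. Assignment by the leftmost base puts a read
#' straddling a bin boundary in exactly one bin.
#'
#' @param bam_paths character vector of coordinate-sorted, indexed BAM
#'   files (one per sample).
#' @param bins bin data.frame from [define_bins()].
#' @param min_mapq minimum mapping quality (default 30).
#' @param sample_names sample IDs; defaults to the BAM basenames.
#'
#' @return A [cov_matrix] in state `"raw"`.
#' @export
count_reads <- function(bam_paths, bins, min_mapq = 30, sample_names = NULL) {
  if (is.null(sample_names))
    sample_names <- sub("\\.bam$", "", basename(bam_paths))
  stopifnot(length(sample_names) == length(bam_paths))

  counts <- matrix(0L, nrow = nrow(bins), ncol = length(bam_paths),
                   dimnames = list(NULL, sample_names))
  bin_chr <- .strip_chr(bins$chrom)

  for (i in seq_along(bam_paths)) {
    bam <- bam_paths[i]
    if (!file.exists(paste0(bam, ".bai")) && !file.exists(sub("\\.bam$", ".bai", bam)))
      stop("missing BAM index for ", bam)
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    missing_contigs <- setdiff(unique(bin_chr), .strip_chr(names(hdr)))
    if (length(missing_contigs) > 0)
      stop("contigs in bins absent from ", bam, ": ",
           paste(missing_contigs, collapse = ", "))
    flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                   isUnmappedQuery = FALSE, isDuplicate = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos"),
                                     mapqFilter = min_mapq)
    reads <- Rsamtools::scanBam(bam, param = param)[[1]]
    rchr <- .strip_chr(as.character(reads$rname))
    for (ch in unique(bin_chr)) {
      idx <- which(bin_chr == ch)
      pos0 <- reads$pos[rchr == ch] - 1L   # 0-based leftmost aligned base
      if (length(pos0) == 0) next
      j <- findInterval(pos0, bins$start[idx])
      keep <- j >= 1
      keep[keep] <- pos0[keep] < bins$end[idx][j[keep]]
      tab <- tabulate(j[keep], nbins = length(idx))
      counts[idx, i] <- counts[idx, i] + tab
    }
  }
  cov_matrix(bins, counts, state = "raw")
}
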