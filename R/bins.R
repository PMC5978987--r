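#' Tile a genome into fixed-size bins
#'
#' Fragments each chromosome into consecutive non-overlapping windows of
#' `bin_size` bp (the last bin of a chromosome may be shorter). When a
#' reference FASTA is supplied, each bin is annotated with its GC fraction
#' computed over non-N bases; bins where more than `max_n_frac` of the bases
#' are N get an undefined GC and are flagged unusable.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (default 5000, i.e. 5 Kbp windows).
#' @param fasta optional path to the reference FASTA used for GC content.
#' @param max_n_frac maximum tolerated fraction of N bases in a bin before
#'   its GC content is declared undefined (default 0.2).
#'
#' @return data.frame of bins with columns `chrom`, `start`, `end`
#'   (0-based half-open), `gc` and `usable`.
#' @export
define_bins <- function(chrom_lengths, bin_size = 5000, fasta = NULL, max_n_frac = 0.2) {
  if (bin_size < 100) stop("bin_size must be >= 100 bp")
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome in chrom_lengths")

  bins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts, end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  }))
  bins$gc <- NA_real_

  if (!is.null(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    extra <- setdiff(names(seqs), names(chrom_lengths))
    if (length(extra) > 0)
      warning("FASTA sequences not in chrom_lengths, skipped: ",
              paste(extra, collapse = ", "))
    for (ch in intersect(names(seqs), names(chrom_lengths))) {
      idx <- which(bins$chrom == ch)
      v <- Biostrings::Views(seqs[[ch]],
                             start = bins$start[idx] + 1, end = bins$end[idx])
      freq <- Biostrings::letterFrequency(v, c("G", "C", "N"))
      width <- bins$end[idx] - bins$start[idx]
      n_frac <- freq[, "N"] / width
      gc <- (freq[, "G"] + freq[, "C"]) / (width - freq[, "N"])
      gc[n_frac > max_n_frac | width == freq[, "N"]] <- NA_real_
      bins$gc[idx] <- gc
    }
  }
  bins$usable <- !is.na(bins$gc)
  rownames(bins) <- NULL
  bins
}
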