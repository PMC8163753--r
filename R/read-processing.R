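#' Shift mapped reads to nucleosome dyads
#'
#' Each single-end read is shifted by 73 bp in its 3' direction so that the
#' shifted 5' position marks the nucleosome dyad, then replaced by a fixed
#' 50 bp dyad-centered fragment `[dyad - 25, dyad + 25)`. Plus-strand:
#' `dyad = start + 73`; minus-strand: `dyad = (end - 1) - 73`. Fragments that
#' would extend beyond their chromosome are dropped and counted.
#'
#' @param reads data.frame(chrom, start, end, strand), 0-based half-open.
#' @param genome A [genome_def()].
#' @param fragment_length Width of the dyad-centered fragment (default 50).
#' @return data.frame(chrom, pos, start, end): the dyad position and fragment
#'   interval per retained read; attribute `n_dropped` counts dropped reads.
#' @export
shift_reads_to_dyads <- function(reads, genome, fragment_length = 50) {
  if (!all(reads$strand %in% c("+", "-")))
    stop("reads must have strand '+' or '-'")
  bad <- !reads$chrom %in% genome$chrom_names
  if (any(bad))
    stop("unknown chromosome(s): ", paste(unique(reads$chrom[bad]), collapse = ", "))
  pos <- ifelse(reads$strand == "+", reads$start + 73, (reads$end - 1) - 73)
  fstart <- pos - fragment_length %/% 2
  fend <- fstart + fragment_length
  L <- genome$chrom_lengths[reads$chrom]
  keep <- fstart >= 0 & fend <= L
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " fragment(s) dropped at chromosome boundaries")
  res <- data.frame(chrom = reads$chrom[keep], pos = as.integer(pos[keep]),
                    start = as.integer(fstart[keep]), end = as.integer(fend[keep]),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Per-base genome coverage of dyad fragments
#'
#' Coverage at base b is the number of fragments overlapping b (exact integer
#' counts; summed coverage equals fragment length times the number of
#' fragments).
#'
#' @param fragments data.frame(chrom, start, end), 0-based half-open.
#' @param genome A [genome_def()].
#' @return An object of class `coverage_track`: a named list (one integer
#'   vector per chromosome, element i giving coverage at 0-based position
#'   i - 1) with the genome attached as attribute.
#' @export
compute_coverage <- function(fragments, genome) {
  bad <- !fragments$chrom %in% genome$chrom_names
  if (any(bad))
    stop("unknown chromosome(s): ", paste(unique(fragments$chrom[bad]), collapse = ", "))
  cov <- lapply(genome$chrom_names, function(cn) {
    L <- genome$chrom_lengths[[cn]]
    f <- fragments[fragments$chrom == cn, , drop = FALSE]
    if (nrow(f) == 0) return(integer(L))
    ir <- IRanges::IRanges(start = f$start + 1L, end = f$end)  # to 1-based closed
    as.integer(IRanges::coverage(ir, width = L))
  })
  names(cov) <- genome$chrom_names
  structure(cov, class = "coverage_track", genome = genome)
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- sum(vapply(x, function(v) sum(as.numeric(v)), numeric(1)))
  cat("<coverage_track>", length(x), "chromosome(s), total coverage",
      format(tot, big.mark = ","), "\n")
  invisible(x)
}
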