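#' Read / write UCSC chrom.sizes tables
#'
#' Two-column tab-separated: chromosome name, length.
#'
#' @param path File path.
#' @return [read_chrom_sizes()] returns a [genome_def()].
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           stringsAsFactors = FALSE)
  genome_def(setNames(tab$length, tab$chrom))
}

#' @rdname read_chrom_sizes
#' @param genome A [genome_def()].
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(data.frame(genome$chrom_names,
                                format(genome$chrom_lengths, scientific = FALSE, trim = TRUE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = genome$chrom_names,
                        seqlengths = as.integer(genome$chrom_lengths))
}

#' Read / write barrier sites as BED6
#'
#' The BED name column carries the site kind (GRF, DSB, plus1) and the score
#' column the optional site score. Coordinates are 0-based half-open on disk
#' and in memory.
#'
#' @param path File path.
#' @return [read_sites_bed()] returns a site data.frame (chrom, start, end,
#'   strand, kind, score, site_id, center).
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   kind = if (!is.null(gr$name)) gr$name else NA_character_,
                   score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
                   stringsAsFactors = FALSE)
  df$site_id <- sprintf("site_%04d", seq_len(nrow(df)))
  df$center <- floor((df$start + df$end) / 2)
  df
}

#' @rdname read_sites_bed
#' @param sites Site data.frame.
#' @export
write_sites_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = ifelse(sites$strand == "*", "*", sites$strand),
    name = sites$kind,
    score = ifelse(is.na(sites$score), 0, sites$score))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write mapped reads as BED6
#'
#' @param path File path.
#' @return [read_reads_bed()] returns data.frame(chrom, start, end, strand).
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_reads_bed
#' @param reads data.frame(chrom, start, end, strand).
#' @export
write_reads_bed <- function(reads, path) {
  gr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(start = reads$start + 1L, end = reads$end),
    strand = reads$strand, name = rep(".", nrow(reads)), score = 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Integer counts, run-length compressed, 0-based half-open intervals.
#'
#' @param coverage A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(coverage, path) {
  genome <- attr(coverage, "genome")
  rle <- methods::as(lapply(coverage, S4Vectors::Rle), "SimpleRleList")
  gr <- methods::as(rle, "GRanges")
  names(gr@elementMetadata) <- "score"
  gr <- gr[gr$score != 0]
  GenomeInfoDb::seqlengths(gr) <- as.integer(genome$chrom_lengths[GenomeInfoDb::seqlevels(gr)])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write array features as a tidy TSV
#'
#' One row per (replicate, barrier kind, side, feature, value).
#'
#' @param features An `array_features` or list of them.
#' @param path Output path.
#' @export
write_features_tsv <- function(features, path) {
  if (inherits(features, "array_features")) features <- list(features)
  tab <- do.call(rbind, lapply(features, as.data.frame))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default synthetic-dataset configuration
#'
#' The flat key-value configuration mirroring the generator arguments;
#' values read from a YAML file override these defaults, and function
#' arguments override both.
#'
#' @return Named list of generator settings.
#' @export
default_sim_config <- function() {
  list(n_sites = 300, chrom_length = NULL, site_kind = "GRF",
       min_separation = 3000, phasing_distance = 80, linker = 60,
       n_per_side = 3, jitter_sd = 15, footprint = 147, both_sides = TRUE,
       reads_per_dyad = 100, strand_balance = 0.5, read_length = 50, seed = 1)
}

#' Read a generator configuration file
#'
#' @param path YAML (or flat `key: value`) file; keys as in
#'   [default_sim_config()].
#' @param overrides Named list taking precedence over the file.
#' @return Named list of settings.
#' @export
read_sim_config <- function(path = NULL, overrides = list()) {
  cfg <- default_sim_config()
  if (!is.null(path)) {
    fromfile <- yaml::read_yaml(path)
    unknown <- setdiff(names(fromfile), names(cfg))
    if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(fromfile)] <- fromfile
  }
  cfg[names(overrides)] <- overrides
  cfg
}
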