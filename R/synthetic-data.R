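#' Genome definition
#'
#' A minimal genome: chromosome names and lengths. All coordinates in the
#' package are 0-based, half-open (BED convention).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @return An object of class `genome_def`.
#' @export
genome_def <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chrom_lengths must have unique names")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  structure(
    list(chrom_names = names(chrom_lengths),
         chrom_lengths = setNames(as.numeric(chrom_lengths), names(chrom_lengths))),
    class = "genome_def"
  )
}

#' @export
print.genome_def <- function(x, ...) {
  cat("<genome_def>", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Array geometry parameters for the synthetic generator
#'
#' Defines barrier-anchored phased regular arrays: the first nucleosome sits
#' `phasing_distance` bp (barrier center to proximal nucleosome flank) from the
#' barrier, subsequent nucleosomes follow at constant `linker` spacing
#' (flank-to-flank), with independent Gaussian positional jitter per nucleosome.
#'
#' @param phasing_distance Distance (bp) from barrier center to the proximal
#'   flank of the first nucleosome. Default 80 (the scale of in vitro
#'   remodeler-set phasing distances).
#' @param linker Flank-to-flank distance (bp) between neighboring nucleosomes.
#' @param n_per_side Nucleosomes per array side.
#' @param jitter_sd Gaussian positional jitter SD (bp) applied per nucleosome.
#' @param footprint Nucleosome footprint (bp), default 147.
#' @param both_sides Generate arrays on both sides of the barrier?
#' @param cumulative_jitter If `TRUE`, jitter accumulates outward along the
#'   array (random-register mode) instead of being independent per nucleosome.
#' @return An object of class `array_params`.
#' @export
array_params <- function(phasing_distance = 80, linker = 60, n_per_side = 3,
                         jitter_sd = 15, footprint = 147, both_sides = TRUE,
                         cumulative_jitter = FALSE) {
  stopifnot(phasing_distance >= 0, linker >= 0, n_per_side >= 1,
            jitter_sd >= 0, footprint >= 1)
  structure(list(phasing_distance = phasing_distance, linker = linker,
                 n_per_side = n_per_side, jitter_sd = jitter_sd,
                 footprint = footprint, both_sides = isTRUE(both_sides),
                 cumulative_jitter = isTRUE(cumulative_jitter)),
            class = "array_params")
}

site_width_for_kind <- function(kind) {
  # GRF: Reb1-like 8 bp motif; DSB: BamHI GGATCC (6 bp, palindromic);
  # plus1: a single-bp dyad annotation.
  switch(kind, GRF = 8L, DSB = 6L, plus1 = 1L,
         stop("unknown site kind: ", kind))
}

#' Generate a synthetic genome with barrier sites
#'
#' Places `n_sites` barrier sites uniformly at random on `n_chrom` chromosomes
#' of equal length, keeping every site center at least `min_separation` bp from
#' its neighbors and at least 1000 bp from chromosome ends (so a full 2001 bp
#' alignment window always fits). GRF and plus1 sites get random strands; DSB
#' sites (palindromic cut sites) are unstranded (`*`).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length (bp) of each chromosome.
#' @param n_sites Total number of barrier sites.
#' @param site_kind One of `"GRF"`, `"DSB"`, `"plus1"`.
#' @param min_separation Minimum center-to-center distance between sites (bp).
#' @param seed Integer seed; identical seeds give identical output.
#' @param end_margin Margin (bp) kept free at chromosome ends (default 1000).
#' @return A list with elements `genome` (a [genome_def()]) and `sites`
#'   (a data.frame with columns chrom, start, end, strand, kind, score,
#'   site_id, center; 0-based half-open).
#' @export
make_synthetic_genome <- function(n_chrom = 1, chrom_length = 50000,
                                  n_sites = 10, site_kind = "GRF",
                                  min_separation = 3000, seed = 1,
                                  end_margin = 1000) {
  stopifnot(n_chrom >= 1, chrom_length >= 1, n_sites >= 1, min_separation >= 0)
  site_kind <- match.arg(site_kind, c("GRF", "DSB", "plus1"))
  chrom_names <- sprintf("chrSim%d", seq_len(n_chrom))
  genome <- genome_def(setNames(rep(chrom_length, n_chrom), chrom_names))

  # even split across chromosomes, remainder on the first ones
  n_per <- rep(n_sites %/% n_chrom, n_chrom)
  extra <- n_sites %% n_chrom
  if (extra > 0) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L
  usable <- chrom_length - 2 * end_margin
  span <- usable - (max(n_per) - 1) * min_separation
  if (usable <= 0 || span < 0)
    stop("cannot place sites: ", max(n_per), " site(s) with separation ",
         min_separation, " do not fit in ", chrom_length, " bp")

  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_chrom), function(ci) {
      k <- n_per[ci]
      if (k == 0) return(NULL)
      # order-statistics construction: uniform placement with hard minimum gap
      span_i <- usable - (k - 1) * min_separation
      u <- sort(runif(k, 0, span_i))
      centers <- end_margin + floor(u) + (seq_len(k) - 1) * min_separation
      strand <- if (site_kind == "DSB") rep("*", k) else sample(c("+", "-"), k, replace = TRUE)
      data.frame(chrom = chrom_names[ci], center = centers, strand = strand,
                 stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, rows)
  })
  w <- site_width_for_kind(site_kind)
  sites$start <- sites$center - w %/% 2
  sites$end <- sites$start + w
  sites$center <- floor((sites$start + sites$end) / 2)
  sites$kind <- site_kind
  sites$score <- NA_real_
  sites$site_id <- sprintf("site_%04d", seq_len(nrow(sites)))
  sites <- sites[, c("chrom", "start", "end", "strand", "kind", "score",
                     "site_id", "center")]
  rownames(sites) <- NULL
  list(genome = genome, sites = sites)
}

# Minimal-L2, order-preserving resolution of footprint overlaps: subtract the
# rigid packing offset, fit a nondecreasing sequence (isotonic regression),
# and add it back. Pooled runs end up at exactly `footprint` separation.
resolve_overlaps <- function(pos, footprint) {
  if (length(pos) < 2) return(pos)
  if (all(diff(pos) >= footprint)) return(pos)
  off <- (seq_along(pos) - 1) * footprint
  fit <- isoreg(pos - off)$yf
  round(fit) + off
}

#' Sample ground-truth nucleosome dyads around barrier sites
#'
#' For each site, nucleosome k (k = 1..n_per_side) on the downstream side has
#' mean dyad position
#' `center + phasing_distance + (footprint-1)/2 + (k-1)*(footprint+linker)`,
#' mirrored on the upstream side when `both_sides`. Downstream follows the
#' site strand (rightward for `+`/`*`). Gaussian jitter is added, positions are
#' rounded to integer bp, re-sorted, and footprint overlaps are resolved by the
#' minimal order-preserving displacement. Sites whose array (dyad +/- half
#' footprint) would leave the chromosome are dropped and counted.
#'
#' @param genome A [genome_def()].
#' @param sites Site data.frame as from [make_synthetic_genome()].
#' @param params An [array_params()].
#' @param seed Integer seed.
#' @return data.frame(chrom, pos, site_id) of dyad positions (0-based), with
#'   attribute `n_dropped_sites`.
#' @export
sample_array_dyads <- function(genome, sites, params = array_params(), seed = 1) {
  stopifnot(inherits(params, "array_params"))
  hf <- (params$footprint - 1) / 2
  repeat_len <- params$footprint + params$linker
  k <- seq_len(params$n_per_side)
  mean_down <- params$phasing_distance + hf + (k - 1) * repeat_len

  n_dropped <- 0L
  out <- vector("list", nrow(sites))
  withr::with_seed(seed, {
    for (i in seq_len(nrow(sites))) {
      s <- sites[i, ]
      dir <- if (identical(s$strand, "-")) -1 else 1
      means <- s$center + dir * mean_down
      if (params$both_sides) means <- c(s$center - dir * mean_down, means)
      n <- length(means)
      if (params$jitter_sd > 0) {
        noise <- rnorm(n, sd = params$jitter_sd)
        if (params$cumulative_jitter) {
          # accumulate outward on each side independently
          idx_up <- if (params$both_sides) seq_len(params$n_per_side) else integer(0)
          idx_dn <- setdiff(seq_len(n), idx_up)
          noise[idx_dn] <- cumsum(noise[idx_dn])
          if (length(idx_up)) noise[idx_up] <- rev(cumsum(rev(noise[idx_up])))
        }
        pos <- round(means + noise)
      } else {
        pos <- round(means)
      }
      pos <- resolve_overlaps(sort(pos), params$footprint)
      L <- genome$chrom_lengths[[s$chrom]]
      if (pos[1] - floor(hf) < 0 || pos[length(pos)] + ceiling(hf) > L - 1) {
        n_dropped <- n_dropped + 1L
        next
      }
      out[[i]] <- data.frame(chrom = s$chrom, pos = as.integer(pos),
                             site_id = s$site_id, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), pos = integer(), site_id = character())
  rownames(res) <- NULL
  if (n_dropped > 0)
    warning(n_dropped, " site(s) dropped: array exceeds chromosome")
  attr(res, "n_dropped_sites") <- n_dropped
  res
}

#' Generate MNase-seq-like single-end reads from dyad positions
#'
#' The inverse of the dyad-recovery shift applied in read processing: a
#' plus-strand read's 5' end sits 73 bp upstream of the dyad
#' (`start = pos - 73`), a minus-strand read's 5' end 73 bp downstream
#' (`end = pos + 74`). Strand is drawn Bernoulli(`strand_balance`). Reads
#' extending past a chromosome end are dropped and counted.
#'
#' @param dyads data.frame(chrom, pos, ...) of dyad positions.
#' @param genome A [genome_def()] (for boundary checks).
#' @param reads_per_dyad Reads generated per dyad.
#' @param strand_balance Probability a read is plus-strand.
#' @param read_length Read length in bp (default 50, single-end).
#' @param seed Integer seed.
#' @return data.frame(chrom, start, end, strand) of mapped reads (0-based
#'   half-open), with attribute `n_dropped`.
#' @export
dyads_to_reads <- function(dyads, genome, reads_per_dyad = 100,
                           strand_balance = 0.5, read_length = 50, seed = 1) {
  stopifnot(reads_per_dyad >= 1, strand_balance >= 0, strand_balance <= 1,
            read_length >= 1)
  n <- nrow(dyads) * reads_per_dyad
  chrom <- rep(dyads$chrom, each = reads_per_dyad)
  pos <- rep(dyads$pos, each = reads_per_dyad)
  withr::with_seed(seed, {
    plus <- runif(n) < strand_balance
  })
  start <- ifelse(plus, pos - 73, pos + 74 - read_length)
  end <- start + read_length
  strand <- ifelse(plus, "+", "-")
  L <- genome$chrom_lengths[chrom]
  keep <- start >= 0 & end <= L
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning(n_dropped, " read(s) dropped: extend past chromosome end")
  res <- data.frame(chrom = chrom[keep], start = as.integer(start[keep]),
                    end = as.integer(end[keep]), strand = strand[keep],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Simulate a full barrier-aligned MNase-seq dataset
#'
#' Convenience wrapper chaining [make_synthetic_genome()],
#' [sample_array_dyads()] and [dyads_to_reads()] with one master seed.
#'
#' @inheritParams make_synthetic_genome
#' @inheritParams dyads_to_reads
#' @param params An [array_params()].
#' @return list(genome, sites, dyads, reads).
#' @export
simulate_mnase_dataset <- function(n_sites = 300, chrom_length = NULL,
                                   site_kind = "GRF", params = array_params(),
                                   min_separation = 3000, reads_per_dyad = 100,
                                   strand_balance = 0.5, read_length = 50,
                                   seed = 1) {
  if (is.null(chrom_length))
    chrom_length <- n_sites * min_separation + 4000
  gen <- make_synthetic_genome(n_chrom = 1, chrom_length = chrom_length,
                               n_sites = n_sites, site_kind = site_kind,
                               min_separation = min_separation, seed = seed)
  dyads <- sample_array_dyads(gen$genome, gen$sites, params, seed = seed + 1L)
  reads <- dyads_to_reads(dyads, gen$genome, reads_per_dyad = reads_per_dyad,
                          strand_balance = strand_balance,
                          read_length = read_length, seed = seed + 2L)
  list(genome = gen$genome, sites = gen$sites, dyads = dyads, reads = reads)
}
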