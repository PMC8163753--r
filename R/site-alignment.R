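#' Extract a barrier-aligned coverage matrix
#'
#' One row per site, columns for offsets `-flank..+flank` (2001 columns at the
#' default 1000 bp flank) relative to the site center. Minus-strand sites are
#' orientation-flipped so positive offsets always point downstream of the
#' site. Sites whose full window does not fit their chromosome are excluded
#' and counted.
#'
#' @param coverage A `coverage_track` from [compute_coverage()].
#' @param sites Site data.frame (chrom, center, strand, kind, score, site_id).
#' @param flank Half-window size in bp (default 1000).
#' @return An object of class `aligned_matrix`: list(values, offsets, meta,
#'   n_excluded, normalized).
#' @export
extract_aligned_matrix <- function(coverage, sites, flank = 1000) {
  if (nrow(sites) == 0) stop("empty site list")
  genome <- attr(coverage, "genome")
  L <- genome$chrom_lengths[sites$chrom]
  ok <- sites$center - flank >= 0 & sites$center + flank <= L - 1
  n_excluded <- sum(!ok)
  sites <- sites[ok, , drop = FALSE]
  if (nrow(sites) == 0) stop("no site window fits its chromosome")
  offsets <- -flank:flank
  values <- matrix(0, nrow = nrow(sites), ncol = length(offsets),
                   dimnames = list(sites$site_id, offsets))
  for (i in seq_len(nrow(sites))) {
    v <- coverage[[sites$chrom[i]]][(sites$center[i] - flank):(sites$center[i] + flank) + 1L]
    if (identical(sites$strand[i], "-")) v <- rev(v)
    values[i, ] <- v
  }
  structure(list(values = values, offsets = offsets,
                 meta = sites[, intersect(c("site_id", "chrom", "center", "strand",
                                            "kind", "score"), names(sites)),
                              drop = FALSE],
                 n_excluded = n_excluded, normalized = FALSE),
            class = "aligned_matrix")
}

#' Per-site (per-gene) normalization of an aligned matrix
#'
#' Divides every row by its own mean over the window, so each site contributes
#' equal weight to the composite regardless of local sequencing depth. Rows
#' with zero mean are dropped and counted; idempotent.
#'
#' @param matrix An `aligned_matrix`.
#' @return The normalized `aligned_matrix` (adds `n_zero_dropped`).
#' @export
normalize_per_site <- function(matrix) {
  stopifnot(inherits(matrix, "aligned_matrix"))
  rm <- rowMeans(matrix$values)
  keep <- rm > 0
  if (!any(keep)) stop("all rows have zero coverage")
  matrix$values <- matrix$values[keep, , drop = FALSE] / rm[keep]
  matrix$meta <- matrix$meta[keep, , drop = FALSE]
  matrix$n_zero_dropped <- sum(!keep)
  matrix$normalized <- TRUE
  matrix
}

#' Composite (aggregate) profile of an aligned matrix
#'
#' Column-wise arithmetic mean over sites.
#'
#' @param matrix An `aligned_matrix`.
#' @return A `composite_profile`: data.frame(offset, value) with attribute
#'   `n_sites`.
#' @export
composite_profile <- function(matrix) {
  stopifnot(inherits(matrix, "aligned_matrix"), nrow(matrix$values) >= 1)
  new_composite_profile(matrix$offsets, colMeans(matrix$values),
                        n_sites = nrow(matrix$values))
}

#' Construct a composite profile from offset/value vectors
#'
#' @param offset Integer offsets relative to the alignment point.
#' @param value Mean coverage (or occupancy probability) per offset.
#' @param n_sites Number of sites (or trajectories) averaged.
#' @return A `composite_profile` data.frame.
#' @export
new_composite_profile <- function(offset, value, n_sites = 1L) {
  stopifnot(length(offset) == length(value), n_sites > 0)
  structure(data.frame(offset = as.integer(offset), value = as.numeric(value)),
            n_sites = n_sites,
            class = c("composite_profile", "data.frame"))
}

#' Score sites in a fixed upstream window and select the top fraction
#'
#' Used to rank sites by an external signal (e.g., an anti-GRF ChIP track
#' aligned to the same points): the score is the mean of each row over
#' `[window_start_offset, window_start_offset + window_len)` — by default the
#' 120 bp window 160 bp upstream of the alignment point — and the top
#' `top_fraction` of sites (ceiling) is selected, ties broken by site id.
#'
#' @param matrix An `aligned_matrix` of the score track.
#' @param window_start_offset Window start offset (default -280).
#' @param window_len Window length in bp (default 120).
#' @param top_fraction Fraction of sites selected (default 0.125).
#' @return list(scores = named numeric, selected = character site ids).
#' @export
score_sites_by_window <- function(matrix, window_start_offset = -280,
                                  window_len = 120, top_fraction = 0.125) {
  stopifnot(inherits(matrix, "aligned_matrix"), window_len > 0,
            top_fraction > 0, top_fraction <= 1)
  idx <- matrix$offsets >= window_start_offset &
    matrix$offsets < window_start_offset + window_len
  if (sum(idx) < window_len)
    stop("scoring window outside the aligned matrix")
  scores <- rowMeans(matrix$values[, idx, drop = FALSE])
  names(scores) <- matrix$meta$site_id
  n_sel <- ceiling(top_fraction * length(scores))
  ord <- order(-scores, names(scores))
  list(scores = scores, selected = sort(names(scores)[ord[seq_len(n_sel)]]))
}

#' Group GRF sites by motif orientation relative to downstream genes
#'
#' Considers genes whose TSS lies within `max_upstream` bp downstream of the
#' site (i.e., the site is within `max_upstream` bp upstream of the TSS).
#' Group 1: the motif is on the sense strand of the single downstream gene;
#' group 2: antisense; group 3: the site sits between two divergent genes
#' (a bidirectional promoter); anything else is "other".
#'
#' @param sites Site data.frame (needs chrom, center, strand, site_id).
#' @param genes data.frame(chrom, tss, strand) of gene TSS annotations.
#' @param max_upstream Maximum site-to-TSS distance (default 400 bp).
#' @return data.frame(site_id, group) with group in
#'   `c("group1","group2","group3","other")`.
#' @export
group_sites_by_orientation <- function(sites, genes, max_upstream = 400) {
  grp <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    g <- genes[genes$chrom == s$chrom, , drop = FALSE]
    # site upstream of a + gene: TSS to the right; of a - gene: TSS to the left
    right <- g[g$strand == "+" & g$tss > s$center & g$tss - s$center <= max_upstream, , drop = FALSE]
    left <- g[g$strand == "-" & g$tss < s$center & s$center - g$tss <= max_upstream, , drop = FALSE]
    if (nrow(right) > 0 && nrow(left) > 0) {
      grp[i] <- "group3"
    } else if (nrow(right) + nrow(left) == 1 || xor(nrow(right) > 0, nrow(left) > 0)) {
      gene_strand <- if (nrow(right) > 0) "+" else "-"
      if (!s$strand %in% c("+", "-")) grp[i] <- "other"
      else grp[i] <- if (identical(s$strand, gene_strand)) "group1" else "group2"
    } else {
      grp[i] <- "other"
    }
  }
  data.frame(site_id = sites$site_id, group = grp, stringsAsFactors = FALSE)
}
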