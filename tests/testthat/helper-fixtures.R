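# shared in-code fixtures

# an aligned_matrix built directly from a values matrix (sites x offsets)
fake_aligned_matrix <- function(values, flank = 1000, strand = NULL,
                                kind = "GRF") {
  n <- nrow(values)
  ids <- sprintf("site_%04d", seq_len(n))
  dimnames(values) <- list(ids, -flank:flank)
  structure(list(values = values, offsets = -flank:flank,
                 meta = data.frame(site_id = ids,
                                   strand = strand %||% rep("+", n),
                                   kind = kind, stringsAsFactors = FALSE),
                 n_excluded = 0L, normalized = FALSE),
            class = "aligned_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent windowed-argmax oracle for downstream peak positions on a raw
# (unsmoothed) profile: plain loops, no shared code with the peak caller.
# Tied maxima forming one contiguous plateau resolve to the plateau center.
brute_force_peaks_down <- function(offset, value, min_first = 30,
                                   rep_min = 100, rep_max = 250) {
  peaks <- integer(0)
  lo <- min_first
  hi <- min_first + rep_max
  repeat {
    win <- which(offset >= lo & offset <= hi)
    if (!length(win)) break
    if (max(value[win]) == min(value[win])) break
    tied <- offset[win][value[win] == max(value[win])]
    plateau <- tied[seq_len(match(TRUE, c(diff(tied) != 1, TRUE)))]
    best <- plateau[length(plateau) %/% 2 + 1]
    peaks <- c(peaks, best)
    lo <- best + rep_min
    hi <- best + rep_max
    if (lo > max(offset)) break
  }
  peaks
}
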