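#' Peak-calling parameters for composite profiles
#'
#' The composite is smoothed by a centered moving average, the first
#' downstream peak is the maximum over
#' `[min_first_offset, min_first_offset + search_max_repeat]`, and each
#' subsequent peak is the maximum over
#' `[previous + search_min_repeat, previous + search_max_repeat]` — an
#' outward-seeded windowed argmax. Calling stops when the search window
#' leaves the profile or a candidate falls below
#' `min_prominence_fraction` of the first peak's height. The upstream side is
#' mirrored.
#'
#' @param smooth_window Moving-average window (bp, odd; default 15).
#' @param min_first_offset Smallest |offset| considered for the first peak
#'   (default 30; keeps the barrier's own footprint out of the search).
#' @param search_min_repeat,search_max_repeat Allowed peak-to-peak repeat
#'   range (bp; defaults 100 and 250, bracketing a 147 bp footprint plus
#'   0-100 bp linkers).
#' @param min_prominence_fraction Stop once a candidate peak is below this
#'   fraction of the first peak's smoothed height (default 0.1).
#' @return An object of class `peak_call_params`.
#' @export
peak_call_params <- function(smooth_window = 15, min_first_offset = 30,
                             search_min_repeat = 100, search_max_repeat = 250,
                             min_prominence_fraction = 0.1) {
  stopifnot(smooth_window >= 1, smooth_window %% 2 == 1,
            search_min_repeat > 0, search_max_repeat > search_min_repeat,
            min_prominence_fraction >= 0)
  structure(list(smooth_window = smooth_window,
                 min_first_offset = min_first_offset,
                 search_min_repeat = search_min_repeat,
                 search_max_repeat = search_max_repeat,
                 min_prominence_fraction = min_prominence_fraction),
            class = "peak_call_params")
}

# centered moving average with edge replication
smooth_profile <- function(v, w) {
  if (w <= 1) return(v)
  pad <- (w - 1) %/% 2
  x <- c(rep(v[1], pad), v, rep(v[length(v)], pad))
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))[(pad + 1):(pad + length(v))]
}

# peaks on one side; dist = |offset| ascending, vals = smoothed values
call_peaks_one_side <- function(dist, vals, params) {
  peaks <- integer(0)
  heights <- numeric(0)
  last <- NULL
  repeat {
    if (is.null(last)) {
      win <- which(dist >= params$min_first_offset &
                   dist <= params$min_first_offset + params$search_max_repeat)
    } else {
      if (last + params$search_min_repeat > max(dist)) break  # window leaves profile
      win <- which(dist >= last + params$search_min_repeat &
                   dist <= last + params$search_max_repeat)
    }
    if (length(win) == 0) break
    vw <- vals[win]
    if (max(vw) - min(vw) == 0) break         # flat: no local structure
    # tied maxima: a contiguous plateau resolves to its center (so flat-topped
    # jitter-free peaks land on the dyad); separate tied runs resolve to the
    # run at the smallest |offset|
    cand <- win[vw == max(vw)]
    run_break <- c(FALSE, diff(cand) != 1 | diff(dist[cand]) != 1)
    run <- cand[cumsum(run_break) == 0]
    i <- run[length(run) %/% 2 + 1]
    h <- vals[i]
    if (length(peaks) >= 1 && h < params$min_prominence_fraction * heights[1])
      break
    peaks <- c(peaks, dist[i])
    heights <- c(heights, h)
    last <- dist[i]
  }
  data.frame(dist = peaks, height = heights)
}

#' Call nucleosome peak maxima in a composite profile
#'
#' @param profile A `composite_profile` (offset, value).
#' @param params A [peak_call_params()].
#' @return An object of class `peak_set`: list(down, up) data.frames with
#'   columns offset (signed bp) and height (smoothed), plus the parameters
#'   used. A profile with no structure above the prominence floor yields an
#'   empty peak set (diagnostic in attribute `note`).
#' @export
call_composite_peaks <- function(profile, params = peak_call_params()) {
  stopifnot(inherits(profile, "composite_profile"))
  sm <- smooth_profile(profile$value, params$smooth_window)
  dn_idx <- profile$offset >= 0
  up_idx <- profile$offset <= 0
  down <- if (any(dn_idx)) {
    d <- profile$offset[dn_idx]
    o <- order(d)
    call_peaks_one_side(d[o], sm[dn_idx][o], params)
  } else data.frame(dist = numeric(0), height = numeric(0))
  up <- if (any(up_idx)) {
    d <- -profile$offset[up_idx]
    o <- order(d)
    call_peaks_one_side(d[o], sm[up_idx][o], params)
  } else data.frame(dist = numeric(0), height = numeric(0))
  res <- structure(
    list(down = data.frame(offset = down$dist, height = down$height),
         up = data.frame(offset = -up$dist, height = up$height),
         params = params),
    class = "peak_set")
  if (nrow(down) + nrow(up) == 0)
    attr(res, "note") <- "flat profile: no peaks above prominence floor"
  res
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set>", nrow(x$down), "downstream,", nrow(x$up), "upstream peak(s)\n")
  if (nrow(x$down)) cat("  down offsets:", paste(x$down$offset, collapse = ", "), "\n")
  if (nrow(x$up)) cat("  up offsets:  ", paste(x$up$offset, collapse = ", "), "\n")
  invisible(x)
}

#' Quantify array features from called peaks
#'
#' Per side: `distance_to_barrier = |first peak offset| - half_footprint`
#' (barrier center to the proximal flank of the first nucleosome) and
#' `linker_i = |peak_{i+1} - peak_i| - footprint` (flank-to-flank spacing).
#' The composite peak is read as the nucleosome dyad. Averaged values are the
#' mean over the sides where the feature is defined.
#'
#' @param peaks A `peak_set`.
#' @param barrier_kind One of "GRF", "DSB", "plus1".
#' @param half_footprint Half nucleosome footprint (default 73, i.e., a
#'   147 bp footprint).
#' @param n_sites Number of sites behind the composite (bookkeeping).
#' @param replicate_id Replicate label (bookkeeping).
#' @param max_linkers Number of linkers reported per side (default 3).
#' @return An object of class `array_features`.
#' @export
quantify_array_features <- function(peaks, barrier_kind = "GRF",
                                    half_footprint = 73, n_sites = NA_integer_,
                                    replicate_id = NA_character_,
                                    max_linkers = 3) {
  stopifnot(inherits(peaks, "peak_set"))
  if (nrow(peaks$down) + nrow(peaks$up) == 0)
    stop("no peaks: cannot quantify array features")
  footprint <- 2 * half_footprint + 1
  side_feats <- function(offsets) {
    d <- abs(offsets)
    if (length(d) == 0)
      return(list(distance = NA_real_, linker = rep(NA_real_, max_linkers)))
    lk <- rep(NA_real_, max_linkers)
    if (length(d) > 1) {
      gaps <- diff(d) - footprint
      lk[seq_len(min(max_linkers, length(gaps)))] <-
        gaps[seq_len(min(max_linkers, length(gaps)))]
    }
    list(distance = d[1] - half_footprint, linker = lk)
  }
  dn <- side_feats(peaks$down$offset)
  up <- side_feats(peaks$up$offset)
  avg2 <- function(a, b) {
    v <- c(a, b)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  linker <- lapply(seq_len(max_linkers), function(i)
    c(down = dn$linker[i], up = up$linker[i], avg = avg2(dn$linker[i], up$linker[i])))
  names(linker) <- paste0("linker_", seq_len(max_linkers))
  structure(list(
    distance_to_barrier = c(down = dn$distance, up = up$distance,
                            avg = avg2(dn$distance, up$distance)),
    linker = linker,
    peak_heights = list(down = peaks$down$height, up = peaks$up$height),
    barrier_kind = barrier_kind, n_sites = n_sites,
    replicate_id = replicate_id), class = "array_features")
}

#' @export
print.array_features <- function(x, ...) {
  cat("<array_features>", x$barrier_kind, "barrier\n")
  cat(sprintf("  distance_to_barrier: down %.1f  up %.1f  avg %.1f\n",
              x$distance_to_barrier[["down"]], x$distance_to_barrier[["up"]],
              x$distance_to_barrier[["avg"]]))
  for (nm in names(x$linker))
    cat(sprintf("  %s: down %.1f  up %.1f  avg %.1f\n", nm,
                x$linker[[nm]][["down"]], x$linker[[nm]][["up"]],
                x$linker[[nm]][["avg"]]))
  invisible(x)
}

#' Tidy one-row-per-value view of array features
#'
#' @param x An `array_features` object.
#' @param ... Unused.
#' @return data.frame(replicate_id, barrier_kind, side, feature, value).
#' @export
as.data.frame.array_features <- function(x, ...) {
  rows <- list(data.frame(feature = "distance_to_barrier",
                          side = names(x$distance_to_barrier),
                          value = unname(x$distance_to_barrier)))
  for (nm in names(x$linker))
    rows[[length(rows) + 1]] <- data.frame(feature = nm, side = names(x$linker[[nm]]),
                                           value = unname(x$linker[[nm]]))
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$value), , drop = FALSE]
  data.frame(replicate_id = x$replicate_id, barrier_kind = x$barrier_kind,
             side = out$side, feature = out$feature, value = out$value,
             row.names = NULL)
}

#' Average array features over replicates
#'
#' Arithmetic mean per (feature, side) over replicates, skipping replicates
#' where a feature is missing. All replicates must share the barrier kind.
#'
#' @param features A list of `array_features`.
#' @return An `array_features` with the per-replicate tidy table attached as
#'   attribute `per_replicate`.
#' @export
aggregate_replicates <- function(features) {
  if (length(features) == 0) stop("no replicates to aggregate")
  stopifnot(all(vapply(features, inherits, logical(1), "array_features")))
  kinds <- unique(vapply(features, `[[`, character(1), "barrier_kind"))
  if (length(kinds) != 1) stop("replicates mix barrier kinds: ",
                               paste(kinds, collapse = ", "))
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  sides <- c("down", "up", "avg")
  dist <- vapply(sides, function(s) mean_na(vapply(
    features, function(f) f$distance_to_barrier[[s]], numeric(1))), numeric(1))
  lk_names <- names(features[[1]]$linker)
  linker <- lapply(lk_names, function(nm) vapply(sides, function(s) mean_na(
    vapply(features, function(f) f$linker[[nm]][[s]], numeric(1))), numeric(1)))
  names(linker) <- lk_names
  out <- structure(list(distance_to_barrier = dist, linker = linker,
                        peak_heights = list(down = numeric(0), up = numeric(0)),
                        barrier_kind = kinds, n_sites = NA_integer_,
                        replicate_id = "mean"), class = "array_features")
  attr(out, "per_replicate") <- do.call(rbind, lapply(features, as.data.frame))
  out
}
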