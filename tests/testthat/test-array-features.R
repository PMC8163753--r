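noiseless_composite <- function(seed = 4, n_sites = 200, reads = 20,
                                params = array_params(jitter_sd = 0)) {
  ds <- simulate_mnase_dataset(n_sites = n_sites, params = params,
                               reads_per_dyad = reads, seed = seed)
  cov <- compute_coverage(shift_reads_to_dyads(ds$reads, ds$genome), ds$genome)
  composite_profile(normalize_per_site(extract_aligned_matrix(cov, ds$sites)))
}

test_that("peak maxima of a jitter-free composite match the windowed-argmax oracle", {
  cp <- noiseless_composite()
  pk <- call_composite_peaks(cp, peak_call_params(smooth_window = 1))
  oracle <- brute_force_peaks_down(cp$offset, cp$value)
  expect_equal(pk$down$offset[1:2], c(153, 360))  # 80+73; +(147+60)
  expect_equal(pk$down$offset[seq_along(oracle)], oracle)
  expect_equal(pk$up$offset[1:2], c(-153, -360))
})

test_that("a constant profile yields an empty peak set", {
  cp <- new_composite_profile(-1000:1000, rep(3, 2001), n_sites = 5L)
  pk <- call_composite_peaks(cp)
  expect_equal(nrow(pk$down) + nrow(pk$up), 0)
  expect_match(attr(pk, "note"), "flat")
})

test_that("equal maxima in the first window resolve to the smaller offset", {
  v <- numeric(2001)
  names(v) <- -1000:1000
  v[c("150", "160")] <- 1
  cp <- new_composite_profile(-1000:1000, v, n_sites = 1L)
  pk <- call_composite_peaks(cp, peak_call_params(smooth_window = 1))
  expect_equal(pk$down$offset[1], 150)
})

test_that("prominence floor stops peak calling on decaying arrays", {
  offs <- -1000:1000
  v <- dnorm(offs, 153, 20) + 0.3 * dnorm(offs, 360, 20)
  pk <- call_composite_peaks(new_composite_profile(offs, v, 1L),
                             peak_call_params(min_prominence_fraction = 0.5))
  expect_equal(nrow(pk$down), 1)
  # a laxer floor admits the second peak
  pk2 <- call_composite_peaks(new_composite_profile(offs, v, 1L),
                              peak_call_params(min_prominence_fraction = 0.1))
  expect_equal(nrow(pk2$down), 2)
})

test_that("array features follow the flank/linker conventions", {
  mk_peaks <- function(down, up) {
    structure(list(down = data.frame(offset = down, height = rep(1, length(down))),
                   up = data.frame(offset = up, height = rep(1, length(up))),
                   params = peak_call_params()), class = "peak_set")
  }
  f <- quantify_array_features(mk_peaks(155, -155), "GRF")
  expect_equal(unname(f$distance_to_barrier), c(82, 82, 82))

  f2 <- quantify_array_features(mk_peaks(c(153, 360), numeric(0)), "GRF")
  expect_equal(f2$linker$linker_1[["down"]], 60)  # 360 - 153 - 147
  expect_true(is.na(f2$linker$linker_1[["up"]]))
  expect_equal(f2$linker$linker_1[["avg"]], 60)
  expect_equal(f2$distance_to_barrier[["avg"]], 80)

  f3 <- quantify_array_features(mk_peaks(106, numeric(0)), "DSB")
  expect_equal(f3$distance_to_barrier[["down"]], 33)
  expect_true(all(is.na(unlist(f3$linker))))

  expect_error(quantify_array_features(mk_peaks(numeric(0), numeric(0)), "GRF"),
               "no peaks")
})

test_that("replicate aggregation averages per feature and skips missing values", {
  mk_feat <- function(dist, l2 = NA_real_) {
    structure(list(
      distance_to_barrier = c(down = dist, up = dist, avg = dist),
      linker = list(linker_1 = c(down = 50, up = 50, avg = 50),
                    linker_2 = c(down = l2, up = l2, avg = l2),
                    linker_3 = c(down = NA_real_, up = NA_real_, avg = NA_real_)),
      peak_heights = list(down = 1, up = 1), barrier_kind = "GRF",
      n_sites = 10L, replicate_id = "r"), class = "array_features")
  }
  agg <- aggregate_replicates(list(mk_feat(54, 33), mk_feat(58, NA), mk_feat(58, 35)))
  expect_equal(agg$distance_to_barrier[["avg"]], mean(c(54, 58, 58)))
  expect_equal(agg$linker$linker_2[["avg"]], 34)  # mean over the two present
  expect_true(is.na(agg$linker$linker_3[["avg"]]))
  one <- aggregate_replicates(list(mk_feat(56)))
  expect_equal(one$distance_to_barrier[["avg"]], 56)
  expect_error(aggregate_replicates(list()), "no replicates")
  bad <- mk_feat(56); bad$barrier_kind <- "DSB"
  expect_error(aggregate_replicates(list(mk_feat(1), bad)), "mix")
})

test_that("the tidy view has one row per side and feature", {
  ds <- simulate_mnase_dataset(n_sites = 60, reads_per_dyad = 30, seed = 6)
  q <- quantify_arrays(ds$reads, ds$sites, ds$genome, replicate_id = "rep1")
  tab <- as.data.frame(q$features)
  expect_true(all(c("replicate_id", "barrier_kind", "side", "feature", "value")
                  %in% names(tab)))
  expect_true(all(tab$side %in% c("down", "up", "avg")))
  expect_true("distance_to_barrier" %in% tab$feature)
})

test_that("the pipeline recovers generator phasing and spacing", {
  ds <- simulate_mnase_dataset(n_sites = 200, reads_per_dyad = 50,
                               params = array_params(jitter_sd = 15), seed = 9)
  f <- quantify_arrays(ds$reads, ds$sites, ds$genome)$features
  expect_lte(abs(f$distance_to_barrier[["avg"]] - 80), 2)
  expect_lte(abs(f$linker$linker_1[["avg"]] - 60), 3)
})

test_that("increasing the generator linker shifts the recovered linker by the same amount", {
  recover_l1 <- function(linker) {
    ds <- simulate_mnase_dataset(n_sites = 200, reads_per_dyad = 50,
                                 params = array_params(linker = linker,
                                                       jitter_sd = 15),
                                 seed = 10)
    quantify_arrays(ds$reads, ds$sites, ds$genome)$features$linker$linker_1[["avg"]]
  }
  delta <- recover_l1(75) - recover_l1(60)
  expect_lte(abs(delta - 15), 3)
})

test_that("recovered peaks are stable under the smoothing window", {
  cp <- noiseless_composite(seed = 12)
  offs <- sapply(c(9, 15, 21), function(w)
    call_composite_peaks(cp, peak_call_params(smooth_window = w))$down$offset[1])
  expect_lte(max(offs) - min(offs), 2)
})
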