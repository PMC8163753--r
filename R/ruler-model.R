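#' Remodeler ruler specification
#'
#' Parameterizes the position-dependent sliding-direction bias a remodeler's
#' ruler imposes near a barrier, as two piecewise-constant regions: in region
#' A (gap `0 <= d < reach_a`) sliding toward the barrier is disfavored, in
#' region B (`reach_a <= d < reach_a + reach_b`) it is favored, and beyond the
#' ruler's reach (region C) sliding is an unbiased random walk. The crossing
#' at `d = reach_a` is the self-stabilizing dynamic equilibrium point.
#'
#' @param reach_a Region A length a (bp): gaps shorter than this push the
#'   nucleosome away from the barrier.
#' @param reach_b Region B length b (bp): gaps in `[a, a+b)` pull it toward
#'   the barrier.
#' @param rate Base sliding rate r0 (events per unit time) per direction in
#'   region C.
#' @param beta Bias magnitude in `[0, 1)`: biased rates are `r0*(1±beta)`.
#' @param mode `"reciprocal"` (both directions modulated, total rate constant),
#'   `"asymmetric"` (only the toward-barrier rate modulated), or
#'   `"kinetic_release"` (reciprocal, with both rates additionally scaled by
#'   `1 - release_depth` exactly at `d = reach_a`, making the equilibrium
#'   point a total-rate minimum).
#' @param release_depth Rate-depression depth at `d = reach_a` in
#'   kinetic-release mode (default 0.5).
#' @return An object of class `ruler_spec`.
#' @export
ruler_spec <- function(reach_a = 40, reach_b = 40, rate = 1, beta = 0.5,
                       mode = c("reciprocal", "asymmetric", "kinetic_release"),
                       release_depth = 0.5) {
  mode <- match.arg(mode)
  stopifnot(reach_a >= 0, reach_b > 0, rate > 0, beta >= 0, beta < 1,
            release_depth >= 0, release_depth < 1)
  structure(list(reach_a = reach_a, reach_b = reach_b, rate = rate,
                 beta = beta, mode = mode, release_depth = release_depth),
            class = "ruler_spec")
}

#' Ruler sliding rates at a given gap
#'
#' @param ruler A [ruler_spec()].
#' @param d Gap(s) in bp between the nucleosome flank and the nearest obstacle
#'   edge on one side (`Inf` = no obstacle in reach).
#' @return list(toward, away): sliding rates toward and away from the obstacle.
#' @export
ruler_rates <- function(ruler, d) {
  stopifnot(inherits(ruler, "ruler_spec"))
  if (any(d < 0, na.rm = TRUE)) stop("gap d must be non-negative")
  a <- ruler$reach_a; b <- ruler$reach_b; r0 <- ruler$rate; beta <- ruler$beta
  in_A <- is.finite(d) & d < a
  in_B <- is.finite(d) & d >= a & d < a + b
  toward <- r0 * ifelse(in_A, 1 - beta, ifelse(in_B, 1 + beta, 1))
  away <- if (ruler$mode == "asymmetric") rep(r0, length(d))
          else r0 * ifelse(in_A, 1 + beta, ifelse(in_B, 1 - beta, 1))
  if (ruler$mode == "kinetic_release") {
    s <- ifelse(is.finite(d) & d == a, 1 - ruler$release_depth, 1)
    toward <- toward * s
    away <- away * s
  }
  list(toward = toward, away = away)
}

#' One-dimensional lattice of nucleosomes and barriers
#'
#' A DNA segment `[0, length)` carrying hard-core nucleosomes (each occupying
#' `footprint` bp around its dyad) and fixed barriers. Barriers are given as
#' boundary coordinates; a barrier at coordinate x with footprint `w` occupies
#' `[x - w/2, x + w/2)` (zero-footprint barriers are pure edges, DSB/DNA-end
#' like; a GRF-like barrier gets a positive, even footprint). Domain ends
#' always block sliding; only coordinates listed in `barriers` engage the
#' ruler.
#'
#' @param length Domain length L (bp).
#' @param nucleosomes Integer dyad positions (ascending).
#' @param footprint Nucleosome footprint (odd bp; default 147, reducible for
#'   exact small-system oracles).
#' @param barriers Numeric barrier coordinates in `[0, length]`
#'   (default both DNA ends).
#' @param barrier_footprint Barrier footprint(s), even, recycled (default 0).
#' @return An object of class `lattice_state`.
#' @export
lattice_state <- function(length, nucleosomes, footprint = 147,
                          barriers = c(0, length), barrier_footprint = 0) {
  stopifnot(length >= footprint, footprint %% 2 == 1)
  hw <- (footprint - 1) %/% 2
  nucleosomes <- as.integer(nucleosomes)
  if (is.unsorted(nucleosomes, strictly = TRUE) && length(nucleosomes) > 1)
    stop("nucleosome dyads must be strictly ascending")
  wb <- rep_len(barrier_footprint, base::length(barriers))
  if (any(wb %% 2 != 0)) stop("barrier footprints must be even")
  lo <- barriers - wb / 2
  hi <- barriers + wb / 2
  if (base::length(nucleosomes)) {
    f <- nucleosomes - hw
    g <- nucleosomes + hw + 1
    if (any(f < 0) || any(g > length)) stop("nucleosome extends past the domain")
    if (base::length(nucleosomes) > 1 && any(diff(nucleosomes) < footprint))
      stop("nucleosome footprints overlap")
    for (j in seq_along(barriers))
      if (any(f < hi[j] & g > lo[j])) stop("nucleosome overlaps barrier ", j)
  }
  structure(list(length = length, nucleosomes = nucleosomes,
                 footprint = footprint, hw = hw,
                 barriers = barriers, barrier_lo = lo, barrier_hi = hi),
            class = "lattice_state")
}

# Move rates for nucleosome i of configuration ps on a lattice; mirrors the
# compiled simulator and serves as the independent piece of the exact oracles.
move_rates <- function(lattice, ruler, ps, i) {
  BIG <- 1e18
  hw <- lattice$hw
  f <- ps[i] - hw
  g <- ps[i] + hw + 1
  dL <- if (i > 1) f - (ps[i - 1] + hw + 1) else BIG
  dR <- if (i < length(ps)) (ps[i + 1] - hw) - g else BIG
  for (j in seq_along(lattice$barriers)) {
    if (lattice$barrier_hi[j] <= f) dL <- min(dL, f - lattice$barrier_hi[j])
    if (lattice$barrier_lo[j] >= g) dR <- min(dR, lattice$barrier_lo[j] - g)
  }
  okL <- f >= 1 && (dL >= BIG || dL >= 1)
  okR <- g <= lattice$length - 1 && (dR >= BIG || dR >= 1)
  rl <- ruler_rates(ruler, if (dL >= BIG) Inf else dL)
  rr <- ruler_rates(ruler, if (dR >= BIG) Inf else dR)
  c(left = if (okL) rl$toward * rr$away / ruler$rate else 0,
    right = if (okR) rr$toward * rl$away / ruler$rate else 0)
}

#' Stochastic simulation of ruler-driven nucleosome sliding
#'
#' Continuous-time Markov chain (Gillespie algorithm, compiled inner loop):
#' events are 1 bp sliding moves of single nucleosomes; each nucleosome's
#' left/right move rates follow [ruler_rates()] applied to its left and right
#' gaps (nearest barrier edge or neighbor flank), each side contributing an
#' independent multiplicative factor; moves creating overlap have rate zero.
#' Dyad occupancy is accumulated time-weighted after `burn_in`.
#'
#' @param lattice A [lattice_state()].
#' @param ruler A [ruler_spec()].
#' @param t_max Total simulated time (may be `Inf` if `max_events` is finite).
#' @param seed Integer seed.
#' @param burn_in Time discarded before occupancy accumulation.
#' @param max_events Optional cap on the number of sliding events.
#' @return An object of class `ruler_occupancy`: list(occupancy (numeric,
#'   position 0..L-1, time-weighted probability, sums to the nucleosome
#'   count), n_events, time, final_state, lattice, ruler).
#' @export
simulate_ruler <- function(lattice, ruler, t_max = Inf, seed = 1, burn_in = 0,
                           max_events = Inf) {
  stopifnot(inherits(lattice, "lattice_state"), inherits(ruler, "ruler_spec"))
  if (length(lattice$nucleosomes) == 0) stop("no nucleosomes on the lattice")
  if (is.finite(t_max) && t_max <= burn_in) stop("t_max must exceed burn_in")
  if (!is.finite(t_max) && !is.finite(max_events))
    stop("either t_max or max_events must be finite")
  mode_i <- match(ruler$mode, c("reciprocal", "asymmetric", "kinetic_release")) - 1L
  res <- withr::with_seed(seed,
    ruler_sim_cpp(lattice$length, lattice$hw, lattice$nucleosomes,
                  lattice$barrier_lo, lattice$barrier_hi,
                  ruler$reach_a, ruler$reach_b, ruler$rate, ruler$beta,
                  mode_i, ruler$release_depth, t_max, burn_in, max_events))
  span <- res$t_end - burn_in
  if (span <= 0) stop("no simulated time beyond burn_in")
  occ <- res$occ / span
  names(occ) <- 0:(lattice$length - 1)
  structure(list(occupancy = occ, n_events = res$n_events, time = res$t_end,
                 final_state = res$final_pos, jammed = res$jammed,
                 lattice = lattice, ruler = ruler),
            class = "ruler_occupancy")
}

# segment boundaries of the lattice: barrier edges plus the domain walls,
# with a flag for whether each boundary engages the ruler
lattice_segments <- function(lattice) {
  segs <- list()
  lefts <- sort(unique(c(0, lattice$barrier_hi)))
  rights <- sort(unique(c(lattice$barrier_lo, lattice$length)))
  for (le in lefts) {
    re <- rights[rights > le]
    if (!length(re)) next
    re <- min(re)
    # skip degenerate segments inside a barrier
    inside <- any(lattice$barrier_lo < le + 1e-9 & lattice$barrier_hi > le + 1e-9)
    if (inside) next
    segs[[length(segs) + 1]] <- list(
      left = le, right = re,
      left_barrier = any(abs(lattice$barrier_hi - le) < 1e-9),
      right_barrier = any(abs(lattice$barrier_lo - re) < 1e-9))
  }
  segs
}

# enumerate k-nucleosome configurations on positions p_lo..p_hi with minimum
# dyad spacing w; returns an integer matrix, one configuration per row
enumerate_configs <- function(p_lo, p_hi, k, w) {
  m <- p_hi - (k - 1) * w - p_lo + 1
  if (m <= 0) return(matrix(integer(0), ncol = k))
  n_states <- choose(m + k - 1, k)
  if (n_states > 2e5)
    stop("state space too large (", n_states, " configurations); use simulate_ruler()")
  q <- utils::combn(m + k - 1, k)  # strictly increasing -> nondecreasing shift
  cfg <- t(q - seq_len(k) + 1) + p_lo - 1
  cfg + matrix((seq_len(k) - 1) * w, nrow = nrow(cfg), ncol = k, byrow = TRUE)
}

#' Exact stationary distribution of the ruler chain
#'
#' Barriers split the domain into independent segments, each an irreducible
#' finite chain. Single-nucleosome segments are solved in closed form by
#' detailed balance on the 1D birth-death chain of the dyad position;
#' multi-nucleosome segments by a sparse linear solve of the master-equation
#' generator over all hard-core configurations. Rates are computed by the same
#' gap logic as [simulate_ruler()] but in plain R.
#'
#' @param lattice A [lattice_state()] (initial positions fix each segment's
#'   nucleosome count).
#' @param ruler A [ruler_spec()].
#' @return An object of class `stationary_density`: list(marginal (numeric,
#'   per-dyad-position density summing to the nucleosome count), segments
#'   (per-segment configurations and probabilities)).
#' @export
stationary_exact <- function(lattice, ruler) {
  stopifnot(inherits(lattice, "lattice_state"), inherits(ruler, "ruler_spec"))
  hw <- lattice$hw
  segs <- lattice_segments(lattice)
  marginal <- numeric(lattice$length)
  names(marginal) <- 0:(lattice$length - 1)
  seg_out <- list()
  for (sg in segs) {
    p_lo <- ceiling(sg$left) + hw
    p_hi <- floor(sg$right) - hw - 1
    nucs <- lattice$nucleosomes[lattice$nucleosomes >= p_lo &
                                lattice$nucleosomes <= p_hi]
    k <- length(nucs)
    if (k == 0) next
    sub <- lattice_state(lattice$length, nucs, lattice$footprint,
                         barriers = lattice$barriers,
                         barrier_footprint = lattice$barrier_hi - lattice$barrier_lo)
    if (k == 1) {
      pos <- p_lo:p_hi
      lam <- vapply(pos, function(p) move_rates(sub, ruler, p, 1)[["right"]], numeric(1))
      mu <- vapply(pos, function(p) move_rates(sub, ruler, p, 1)[["left"]], numeric(1))
      n <- length(pos)
      logpi <- c(0, cumsum(log(lam[-n]) - log(mu[-1])))
      pi <- exp(logpi - max(logpi))
      pi <- pi / sum(pi)
      marginal[pos + 1] <- marginal[pos + 1] + pi
      seg_out[[length(seg_out) + 1]] <-
        list(positions = pos, prob = pi, n_nucleosomes = 1L,
             left = sg$left, right = sg$right)
    } else {
      cfg <- enumerate_configs(p_lo, p_hi, k, lattice$footprint)
      ns <- nrow(cfg)
      key <- apply(cfg, 1, paste, collapse = ",")
      idx <- seq_len(ns)
      names(idx) <- key
      ii <- jj <- integer(0)
      xx <- numeric(0)
      diag_out <- numeric(ns)
      for (s in seq_len(ns)) {
        ps <- cfg[s, ]
        for (i in seq_len(k)) {
          r <- move_rates(sub, ruler, ps, i)
          for (dname in c("left", "right")) {
            rate <- r[[dname]]
            if (rate <= 0) next
            ps2 <- ps
            ps2[i] <- ps2[i] + if (dname == "left") -1L else 1L
            tgt <- idx[[paste(ps2, collapse = ",")]]
            ii <- c(ii, s); jj <- c(jj, tgt); xx <- c(xx, rate)
            diag_out[s] <- diag_out[s] + rate
          }
        }
      }
      Q <- Matrix::sparseMatrix(i = c(ii, seq_len(ns)), j = c(jj, seq_len(ns)),
                                x = c(xx, -diag_out), dims = c(ns, ns))
      A <- Matrix::t(Q)
      A[1, ] <- 1  # replace one balance equation with normalization
      pi <- as.numeric(Matrix::solve(A, c(1, rep(0, ns - 1))))
      pi[pi < 0] <- 0
      pi <- pi / sum(pi)
      for (col in seq_len(k)) {
        tab <- tapply(pi, cfg[, col], sum)
        ppos <- as.integer(names(tab))
        marginal[ppos + 1] <- marginal[ppos + 1] + as.numeric(tab)
      }
      seg_out[[length(seg_out) + 1]] <-
        list(configs = cfg, prob = pi, n_nucleosomes = k,
             left = sg$left, right = sg$right)
    }
  }
  structure(list(marginal = marginal, segments = seg_out,
                 lattice = lattice, ruler = ruler),
            class = "stationary_density")
}

#' Gap-coordinate density relative to a barrier
#'
#' Converts a per-position density (exact or simulated, single nucleosome in
#' the relevant segment) into the distribution of the gap between the
#' nucleosome's proximal flank and a barrier's inner edge.
#'
#' @param density A `stationary_density` or `ruler_occupancy`.
#' @param barrier_index Which barrier of the lattice (default 1).
#' @return data.frame(gap, prob), normalized over non-zero support.
#' @export
gap_density <- function(density, barrier_index = 1) {
  lattice <- density$lattice
  v <- if (inherits(density, "ruler_occupancy")) density$occupancy else density$marginal
  pos <- as.integer(names(v))
  x <- lattice$barriers[barrier_index]
  hi <- lattice$barrier_hi[barrier_index]
  lo <- lattice$barrier_lo[barrier_index]
  # gap on the side of the barrier where the density lives
  right_mass <- sum(v[pos - lattice$hw >= hi])
  left_mass <- sum(v[pos + lattice$hw + 1 <= lo])
  if (right_mass >= left_mass) {
    keep <- pos - lattice$hw >= hi
    gap <- (pos - lattice$hw) - hi
  } else {
    keep <- pos + lattice$hw + 1 <= lo
    gap <- lo - (pos + lattice$hw + 1)
  }
  d <- data.frame(gap = gap[keep], prob = as.numeric(v[keep]))
  d <- d[order(d$gap), ]
  d <- stats::aggregate(prob ~ gap, d, sum)
  d$prob <- d$prob / sum(d$prob)
  d
}

#' Array features of a steady-state occupancy profile
#'
#' Treats a ruler occupancy (or exact density) as a composite profile centered
#' at a barrier and reuses the composite peak caller and feature
#' quantification.
#'
#' @param occupancy A `ruler_occupancy` or `stationary_density`.
#' @param barrier_index Barrier used as the alignment point (default 1).
#' @param half_footprint Half nucleosome footprint for feature conversion
#'   (default from the lattice).
#' @param params A [peak_call_params()].
#' @param barrier_kind Label for the features (default "DSB").
#' @return list(profile, peaks, features).
#' @export
steady_state_features <- function(occupancy, barrier_index = 1,
                                  half_footprint = NULL,
                                  params = peak_call_params(),
                                  barrier_kind = "DSB") {
  lattice <- occupancy$lattice
  v <- if (inherits(occupancy, "ruler_occupancy")) occupancy$occupancy
       else occupancy$marginal
  if (is.null(half_footprint)) half_footprint <- lattice$hw
  x <- lattice$barriers[barrier_index]
  # trim the zero flanks outside the reachable dyad range so edge ramps do not
  # masquerade as peaks
  nz <- which(v > 0)
  keep <- if (length(nz)) seq(min(nz), max(nz)) else seq_along(v)
  v <- v[keep]
  profile <- new_composite_profile(as.integer(names(v)) - round(x), v,
                                   n_sites = max(1L, length(lattice$nucleosomes)))
  peaks <- call_composite_peaks(profile, params)
  features <- if (nrow(peaks$down) + nrow(peaks$up) > 0)
    quantify_array_features(peaks, barrier_kind = barrier_kind,
                            half_footprint = half_footprint)
  else NULL
  list(profile = profile, peaks = peaks, features = features)
}
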