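#!/usr/bin/env Rscript

# The remodeler-ruler model: position-dependent sliding-direction bias around
# a barrier. This script (i) tabulates the piecewise sliding rates for the
# three bias modes, (ii) compares the Gillespie simulator against the exact
# birth-death stationary distribution for a single nucleosome next to a DNA
# end, and (iii) scans nucleosome density to show clamping (density-
# independent steady-state spacing) and its collapse at over-packing.

library(nucruler)

out <- "results/ruler"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## rates ----------------------------------------------------------------------
d <- 0:120
tabs <- lapply(c("reciprocal", "asymmetric", "kinetic_release"), function(m) {
  r <- ruler_rates(ruler_spec(40, 40, 1, 0.5, m), d)
  data.frame(mode = m, gap = d, toward = r$toward, away = r$away)
})
utils::write.table(do.call(rbind, tabs), file.path(out, "ruler_rates.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Region A (gap < 40): sliding toward the barrier disfavored;",
    "region B (40-79): favored; region C: unbiased.\n")

## simulator vs exact oracle --------------------------------------------------
lat <- lattice_state(500, nucleosomes = 113, footprint = 147, barriers = 0)
rs <- ruler_spec(reach_a = 40, reach_b = 40, rate = 1, beta = 0.5)
ex <- stationary_exact(lat, rs)
sim <- simulate_ruler(lat, rs, t_max = Inf, seed = 1, max_events = 1e6,
                      burn_in = 5e4)
tv <- 0.5 * sum(abs(sim$occupancy - ex$marginal))
gd <- gap_density(sim)
cat(sprintf("Single nucleosome, L = 500, a = b = 40, beta = 0.5:\n"))
cat(sprintf("  TV(simulated, exact) = %.4f after %g events\n", tv, sim$n_events))
cat(sprintf("  stationary gap mode  = %d bp (region A/B boundary a = 40)\n",
            gd$gap[which.max(gd$prob)]))
utils::write.table(
  data.frame(position = as.integer(names(ex$marginal)),
             exact = ex$marginal, simulated = sim$occupancy),
  file.path(out, "single_nucleosome_density.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

## clamping scan ---------------------------------------------------------------
steady_linker1 <- function(n, t_max = 4e5, seed = 5) {
  hw <- 73
  span <- (2500 - 1 - hw) - hw
  step <- min(187, span %/% (n - 1))
  lat <- lattice_state(2500, nucleosomes = hw + (0:(n - 1)) * step,
                       footprint = 147, barriers = 0)
  s <- simulate_ruler(lat, rs, t_max = t_max, seed = seed,
                      burn_in = t_max * 0.1)
  f <- steady_state_features(s)$features
  c(n = n, distance = f$distance_to_barrier[["down"]],
    linker1 = f$linker$linker_1[["down"]])
}
scan <- as.data.frame(t(sapply(c(3, 6, 10, 14), steady_linker1)))
utils::write.table(scan, file.path(out, "clamping_scan.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(scan, row.names = FALSE)
cat("Steady-state linker 1 stays at the ruler reach (~40 bp) while arrays fit;\n",
    "at N = 14, N*(147+40) exceeds L = 2500 and spacing is compressed.\n", sep = "")
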