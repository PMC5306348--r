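# Shared fixtures and independent oracles used across the test files.

small_kit <- function(n = 2) make_fixture_kit(n, c(70, 200))

het_genotype <- function(kit, ploidy = "diploid", seed = 11) {
  random_genotype(kit, heterozygous_only = TRUE, ploidy = ploidy, seed = seed)
}

ideal_params <- function(cycles = 6, efficiency = 1) {
  process_params(extraction_efficiency = 1, pcr_aliquot = 1,
                 pcr_cycles = cycles, pcr_efficiency = efficiency,
                 stutter_probability = 0, ce_aliquot = 1)
}

# Deterministic expectation oracle for the two-type (allele/stutter)
# branching process: E[count per fragment size] after `cycles` cycles,
# from the per-cycle recursion
#   E'[s]       = E[s] * (1 + eff * (1 - stutter))
#   E'[s - rep] = E'[s - rep] + E[s] * eff * stutter
expected_pcr_counts <- function(init_sizes, init_counts, cycles, eff,
                                stutter, repeat_bp) {
  E <- stats::setNames(as.numeric(init_counts), as.character(init_sizes))
  for (cy in seq_len(cycles)) {
    newE <- E * (1 + eff * (1 - stutter))
    if (stutter > 0) {
      for (nm in names(E)) {
        tgt <- as.character(as.numeric(nm) - repeat_bp)
        add <- E[[nm]] * eff * stutter
        prev <- if (tgt %in% names(newE)) newE[[tgt]] else 0
        newE[tgt] <- prev + add
      }
    }
    E <- newE
  }
  E
}

# Independent per-molecule brute-force PCR simulator: every molecule is
# tracked individually; each cycle it copies with probability `eff`, the
# copy being a stutter (one repeat shorter) with probability `stutter`.
brute_force_pcr <- function(sizes, cycles, eff, stutter, repeat_bp) {
  for (cy in seq_len(cycles)) {
    n <- length(sizes)
    if (n == 0L) break
    copied <- stats::runif(n) < eff
    is_st <- copied & stats::runif(n) < stutter
    sizes <- c(sizes, sizes[copied & !is_st], sizes[is_st] - repeat_bp)
  }
  sizes
}

# Monte-Carlo standard-error based tolerance: 4 standard errors of the mean
mc_tol <- function(x) 4 * stats::sd(x) / sqrt(length(x))

# Hb values of one simulated haploid sample at a single-locus kit, under
# ideal parameters (used by several distribution-level checks)
sim_haploid_hb <- function(n_samples, cells, seed, cycles = 8) {
  kit <- make_fixture_kit(1)
  g <- het_genotype(kit, ploidy = "haploid", seed = seed)
  pp <- ideal_params(cycles = cycles)
  vapply(seq_len(n_samples), function(i) {
    epg <- simulate_sample(g, kit, pp, ce_identity(), target = cells,
                           seed = derive_seed(seed, i))
    hb <- heterozygote_balance(epg, g)
    if (hb$status[1] == "ok") hb$hb[1] else NA_real_
  }, numeric(1))
}

# Printed reference values: theoretical haploid balance probabilities
# (accepted range 0.60 <= Hb <= 1.67 closed) for 2..256 cells
REF_HAPLOID_BALANCE <- data.frame(
  n = c(2, 4, 8, 16, 32, 64, 128, 256),
  p_accepted = c(0.500, 0.375, 0.711, 0.790, 0.890, 0.967, 0.997, 1.000),
  p_balanced = c(0.500, 0.375, 0.273, 0.196, 0.140, 0.099, 0.070, 0.050))

# Printed reference grid: cells required in the extract (rows: pg in the
# PCR reaction; columns: aliquot 5 / 35 / 100 %), at 6 pg per cell
REF_CELLS_REQUIRED <- matrix(
  c(20, 3, 1,
    40, 6, 2,
    80, 12, 4,
    160, 23, 8,
    320, 46, 16,
    640, 92, 32,
    1280, 183, 64,
    2560, 366, 128),
  ncol = 3, byrow = TRUE,
  dimnames = list(amount_pg = c(6, 12, 24, 48, 96, 192, 384, 768),
                  aliquot = c("5%", "35%", "100%")))

# Printed reference: dual-target qPCR concentrations for nine degraded
# tissue extracts (two kits) with the published DI and P(deg) columns
REF_QUANT <- data.frame(
  sample_id = rep(paste0("D", 1:9), 2),
  kit_label = rep(c("QT", "PQ"), each = 9),
  c_small = c(119.710, 0.058, 45.605, 0.437, 0.256, 0.098, 0.284, 1.437,
              31.510,
              127.850, 0.003, 59.950, 0.547, 0.333, 0.119, 0.292, 1.712,
              55.710),
  c_large = c(83.6300, 0.0009, 1.5170, 0.1357, 0.0111, 0.0079, 0.0036,
              0.0900, 0.0565,
              27.7100, NA, 1.8600, 0.0540, 0.0042, 0.0024, 0.0034, 0.0859,
              0.0077),
  x_small = rep(c(80, 84), each = 9),
  x_large = rep(c(214, 294), each = 9),
  di = c(1.4, 64.9, 30.1, 3.2, 23.1, 12.4, 78.8, 16.0, 557.7,
         4.6, NA, 32.2, 10.1, 79.2, 49.5, 86.0, 19.9, 7235.1),
  p_deg = c(0.0027, 0.0307, 0.0251, 0.0087, 0.0231, 0.0186, 0.0321, 0.0205,
            0.0461,
            0.0073, NA, 0.0164, 0.0110, 0.0206, 0.0184, 0.0210, 0.0141,
            0.0414))
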