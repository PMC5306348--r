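# Config-driven experiment recipes: parameter sweeps over the process
# simulator producing per-sample, per-locus heterozygote-balance records.
# Replicate counts default to the published study sizes; every run is
# reproducible from its seed and carries a machine-readable parameter
# manifest as an attribute.

.manifest <- function(name, seed, replicates, params) {
  list(experiment = name,
       package = "strsim",
       version = as.character(utils::packageVersion("strsim")),
       seed = seed,
       replicates = replicates,
       parameters = params)
}

# Simulate `n` samples under one condition and return stacked Hb records.
.sim_hb_condition <- function(n, genotype, kit, params, ce, target,
                              mode = "fixed", p_deg = 0, seed,
                              pcr_cycles_range = NULL) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- derive_seed(seed, i)
    pp <- params
    if (!is.null(pcr_cycles_range)) {
      set.seed(s)
      pp$pcr_cycles <- sample(pcr_cycles_range, 1L)
    }
    epg <- simulate_sample(genotype, kit, pp, ce, p_deg = p_deg,
                           target = target, mode = mode, seed = s)
    hb <- heterozygote_balance(epg, genotype)
    hb$sample <- i
    if (!is.null(pcr_cycles_range)) hb$pcr_cycles <- pp$pcr_cycles
    rows[[i]] <- hb
  }
  do.call(rbind, rows)
}

.ideal_params <- function(pcr_cycles = 28, pcr_efficiency = 1,
                          extraction_efficiency = 1, pcr_aliquot = 1,
                          ce_aliquot = 1) {
  process_params(extraction_efficiency = extraction_efficiency,
                 pcr_aliquot = pcr_aliquot, pcr_cycles = pcr_cycles,
                 pcr_efficiency = pcr_efficiency, stutter_probability = 0,
                 ce_aliquot = ce_aliquot)
}

.sweep_grid <- function(values, value_name, replicates, kit, seed,
                        cells_diploid, cells_haploid, make_params,
                        pcr_cycles) {
  out <- list()
  idx <- 0L
  for (v in values) for (ploidy in c("diploid", "haploid")) {
    cells <- if (ploidy == "diploid") cells_diploid else cells_haploid
    for (cc in cells) {
      idx <- idx + 1L
      cond_seed <- derive_seed(seed, 100000L + idx)
      g <- random_genotype(kit, ploidy = ploidy,
                           seed = derive_seed(seed, 200000L + idx))
      hb <- .sim_hb_condition(replicates, g, kit, make_params(v), ce_identity(),
                              target = cc, mode = "fixed", seed = cond_seed)
      hb[[value_name]] <- v
      hb$ploidy <- ploidy
      hb$cells <- cc
      out[[idx]] <- hb
    }
  }
  do.call(rbind, out)
}

#' Heterozygote balance versus PCR efficiency
#'
#' Direct-PCR sweep: all selection steps are set to 1 so Hb is shaped only
#' by cell type and PCR efficiency.  Identity CE (molecule counts scored
#' directly), no stutter, fixed cell counts on a doubling grid.
#'
#' @param replicates Samples per condition (default 500).
#' @param efficiencies PCR efficiencies to sweep.
#' @param cells_diploid,cells_haploid Fixed cell-count grids.
#' @param pcr_cycles PCR cycles.
#' @param kit Kit definition.
#' @param seed Master seed.
#' @return Hb records with columns `pcr_efficiency`, `ploidy`, `cells`;
#'   parameter manifest in `attr(, "manifest")`.
#' @export
run_efficiency_sweep <- function(replicates = 500,
                                 efficiencies = c(0.20, 0.80, 1.00),
                                 cells_diploid = 2^(0:7),
                                 cells_haploid = 2^(1:8),
                                 pcr_cycles = 28,
                                 kit = make_fixture_kit(),
                                 seed = 1) {
  res <- .sweep_grid(efficiencies, "pcr_efficiency", replicates, kit, seed,
                     cells_diploid, cells_haploid,
                     function(v) .ideal_params(pcr_cycles, pcr_efficiency = v),
                     pcr_cycles)
  attr(res, "manifest") <- .manifest("efficiency_sweep", seed, replicates,
    list(efficiencies = efficiencies, cells_diploid = cells_diploid,
         cells_haploid = cells_haploid, pcr_cycles = pcr_cycles,
         ex_e = 1, pcr_a = 1, ce_a = 1, stutter_p = 0, ce = "identity"))
  res
}

#' Heterozygote balance versus PCR aliquot
#'
#' Sweep of the aliquot fraction forwarded to PCR with all other selection
#' probabilities at 1 (extraction, PCR efficiency, CE aliquot), fixed cell
#' counts, identity CE, no stutter.
#'
#' @param aliquots PCR aliquot fractions to sweep.
#' @inheritParams run_efficiency_sweep
#' @return Hb records with columns `pcr_aliquot`, `ploidy`, `cells`.
#' @export
run_aliquot_sweep <- function(replicates = 1500,
                              aliquots = c(0.05, 0.35, 1.00),
                              cells_diploid = 2^(0:7),
                              cells_haploid = 2^(1:8),
                              pcr_cycles = 28,
                              kit = make_fixture_kit(),
                              seed = 1) {
  res <- .sweep_grid(aliquots, "pcr_aliquot", replicates, kit, seed,
                     cells_diploid, cells_haploid,
                     function(v) .ideal_params(pcr_cycles, pcr_aliquot = v),
                     pcr_cycles)
  attr(res, "manifest") <- .manifest("aliquot_sweep", seed, replicates,
    list(aliquots = aliquots, cells_diploid = cells_diploid,
         cells_haploid = cells_haploid, pcr_cycles = pcr_cycles,
         ex_e = 1, pcr_e = 1, ce_a = 1, stutter_p = 0, ce = "identity"))
  res
}

#' Heterozygote balance versus extraction efficiency
#'
#' Sweep of the extraction survival probability with the PCR aliquot, PCR
#' efficiency and CE aliquot at 1, fixed cell counts, identity CE, no
#' stutter.
#'
#' @param efficiencies Extraction efficiencies to sweep.
#' @inheritParams run_efficiency_sweep
#' @return Hb records with columns `extraction_efficiency`, `ploidy`,
#'   `cells`.
#' @export
run_extraction_sweep <- function(replicates = 1000,
                                 efficiencies = c(0.30, 0.60, 1.00),
                                 cells_diploid = 2^(0:7),
                                 cells_haploid = 2^(1:8),
                                 pcr_cycles = 28,
                                 kit = make_fixture_kit(),
                                 seed = 1) {
  res <- .sweep_grid(efficiencies, "extraction_efficiency", replicates, kit,
                     seed, cells_diploid, cells_haploid,
                     function(v) .ideal_params(pcr_cycles,
                                               extraction_efficiency = v),
                     pcr_cycles)
  attr(res, "manifest") <- .manifest("extraction_sweep", seed, replicates,
    list(extraction_efficiencies = efficiencies,
         cells_diploid = cells_diploid, cells_haploid = cells_haploid,
         pcr_cycles = pcr_cycles, pcr_a = 1, pcr_e = 1, ce_a = 1,
         stutter_p = 0, ce = "identity"))
  res
}

#' Combined extraction-efficiency x PCR-aliquot sweep
#'
#' Crosses extraction efficiencies with aliquot fractions under realistic
#' amplification (default 30 cycles at 90 % efficiency), identity CE, no
#' stutter, for both cell types.
#'
#' @param extraction Extraction efficiencies.
#' @param aliquots PCR aliquot fractions.
#' @param pcr_efficiency Per-cycle PCR efficiency.
#' @inheritParams run_efficiency_sweep
#' @return Hb records with columns `extraction_efficiency`, `pcr_aliquot`,
#'   `ploidy`, `cells`.
#' @export
run_combined_sweep <- function(replicates = 250,
                               extraction = c(0.30, 1.00),
                               aliquots = c(0.05, 0.35, 1.00),
                               pcr_cycles = 30, pcr_efficiency = 0.90,
                               cells_diploid = 2^(0:7),
                               cells_haploid = 2^(1:8),
                               kit = make_fixture_kit(),
                               seed = 1) {
  out <- list(); idx <- 0L
  for (ex in extraction) for (al in aliquots)
    for (ploidy in c("diploid", "haploid")) {
      cells <- if (ploidy == "diploid") cells_diploid else cells_haploid
      for (cc in cells) {
        idx <- idx + 1L
        g <- random_genotype(kit, ploidy = ploidy,
                             seed = derive_seed(seed, 300000L + idx))
        pp <- process_params(extraction_efficiency = ex, pcr_aliquot = al,
                             pcr_cycles = pcr_cycles,
                             pcr_efficiency = pcr_efficiency,
                             stutter_probability = 0, ce_aliquot = 1)
        hb <- .sim_hb_condition(replicates, g, kit, pp, ce_identity(),
                                target = cc, mode = "fixed",
                                seed = derive_seed(seed, 400000L + idx))
        hb$extraction_efficiency <- ex
        hb$pcr_aliquot <- al
        hb$ploidy <- ploidy
        hb$cells <- cc
        out[[idx]] <- hb
      }
    }
  res <- do.call(rbind, out)
  attr(res, "manifest") <- .manifest("combined_sweep", seed, replicates,
    list(extraction = extraction, aliquots = aliquots,
         pcr_cycles = pcr_cycles, pcr_efficiency = pcr_efficiency,
         cells_diploid = cells_diploid, cells_haploid = cells_haploid,
         ce_a = 1, stutter_p = 0, ce = "identity"))
  res
}

#' Serial dilution versus crime stain comparison
#'
#' Contrasts three ways of arriving at the same average amount of DNA in
#' the PCR reaction.  The dilution arm models a 2-fold serial dilution of a
#' concentrated stock (default 57 ng/ul, 450 ul transfer volumes): every
#' transfer is a binomial thinning of per-allele molecule counts with
#' p = 0.5, and the constant tube-to-reaction fraction delivers amounts
#' from `amount_max` pg halving down over `n_levels` levels (845 down to
#' 1.65 pg by default).  The crime-stain arms draw Poisson cell counts
#' targeting the equivalent amounts (6.6 pg per diploid cell, 3.3 pg per
#' haploid cell) and pass through extraction and aliquot selection under
#' each `(ex_e, pcr_a)` setting.  All arms amplify with the same PCR
#' parameters and are read with a calibrated CE model.
#'
#' @param replicates Samples per arm and amount (default 1000).
#' @param amount_max Largest PCR amount in pg.
#' @param n_levels Number of 2-fold dilution levels.
#' @param stock_ng_ul,stock_volume_ul Stock concentration and volume.
#' @param settings Data frame of crime-stain `(ex_e, pcr_a)` settings.
#' @param pcr_cycles,pcr_efficiency PCR parameters shared by all arms.
#' @param ce CE parameters (default 3500xL calibration, LDT 200 RFU).
#' @param pg_per_diploid_cell Mass per diploid cell (pg).
#' @param kit Kit definition.
#' @param seed Master seed.
#' @return Hb records with columns `arm` (`"dilution"`, `"stain_diploid"`,
#'   `"stain_haploid"`), `setting`, `amount_pg`, `sample`.
#' @export
run_dilution_vs_stain <- function(replicates = 1000,
                                  amount_max = 845, n_levels = 10,
                                  stock_ng_ul = 57, stock_volume_ul = 450,
                                  settings = data.frame(
                                    ex_e = c(0.30, 0.30, 1.00, 1.00),
                                    pcr_a = c(0.35, 1.00, 0.35, 1.00)),
                                  pcr_cycles = 28, pcr_efficiency = 0.90,
                                  ce = ce_3500xl(),
                                  pg_per_diploid_cell = 6.6,
                                  kit = make_fixture_kit(),
                                  seed = 1) {
  amounts <- amount_max / 2^(seq_len(n_levels) - 1L)
  stock_pg <- stock_ng_ul * 1000 * stock_volume_ul
  m0 <- round(stock_pg / pg_per_diploid_cell)      # copies per allele in stock
  to_pcr <- amount_max / stock_pg                  # constant tube->reaction fraction
  out <- list(); idx <- 0L

  # dilution arm: the dilution chain replaces extraction/aliquot selection
  g_dil <- random_genotype(kit, seed = derive_seed(seed, 500000L))
  pp_dil <- process_params(1, 1, pcr_cycles, pcr_efficiency, 0, 1)
  for (r in seq_len(replicates)) {
    s <- derive_seed(seed, 600000L + r)
    set.seed(s)
    mt <- sample_cells(g_dil, m0, "fixed")
    for (lev in seq_len(n_levels)) {
      if (lev > 1L) mt <- binomial_thin(mt, 0.5, "sampled")
      reaction <- binomial_thin(mt, to_pcr, "aliquoted")
      amp <- pcr_amplify(reaction, pcr_cycles, pcr_efficiency)
      epg <- ce_detect(amp, ce, ce_aliquot = 1)
      hb <- heterozygote_balance(epg, g_dil)
      hb$arm <- "dilution"; hb$setting <- "dilution"
      hb$amount_pg <- amounts[lev]; hb$sample <- r
      idx <- idx + 1L; out[[idx]] <- hb
    }
  }

  # crime-stain arms: Poisson cell targets at equivalent amounts
  for (ploidy in c("diploid", "haploid")) {
    pg_cell <- if (ploidy == "diploid") pg_per_diploid_cell else
      pg_per_diploid_cell / 2
    g <- random_genotype(kit, ploidy = ploidy,
                         seed = derive_seed(seed, 700000L +
                                              (ploidy == "haploid")))
    for (si in seq_len(nrow(settings))) {
      pp <- process_params(settings$ex_e[si], settings$pcr_a[si], pcr_cycles,
                           pcr_efficiency, 0, 1)
      setting_lab <- sprintf("ex%.2f_a%.2f", settings$ex_e[si],
                             settings$pcr_a[si])
      for (lev in seq_len(n_levels)) {
        # the stated amount is the PCR-reaction target; the extract must
        # hold amount / (ex_e * pcr_a) on average
        target_cells <- amounts[lev] /
          (pg_cell * settings$ex_e[si] * settings$pcr_a[si])
        hb <- .sim_hb_condition(replicates, g, kit, pp, ce,
                                target = target_cells, mode = "poisson",
                                seed = derive_seed(seed, 800000L +
                                  10000L * si + 100L * lev +
                                  (ploidy == "haploid") * 5000L))
        hb$arm <- paste0("stain_", ploidy); hb$setting <- setting_lab
        hb$amount_pg <- amounts[lev]
        idx <- idx + 1L; out[[idx]] <- hb
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "manifest") <- .manifest("dilution_vs_stain", seed, replicates,
    list(amounts_pg = amounts, stock_ng_ul = stock_ng_ul,
         stock_volume_ul = stock_volume_ul, settings = settings,
         pcr_cycles = pcr_cycles, pcr_efficiency = pcr_efficiency,
         pg_per_diploid_cell = pg_per_diploid_cell,
         ce = unclass(ce)))
  res
}

#' Intact-fragment counts under degradation
#'
#' Illustrative degradation draw: `replicates` binomial samples of intact
#' molecules out of `n_copies` for each fragment size, with per-copy
#' survival `(1 - p_deg)^size`.  Defaults correspond to 1 ng of DNA (167
#' haploid copies) at 100 bp and 300 bp with P(deg) = 0.0099, where the
#' 300 bp fragment survives with probability ~0.05 and the 100 bp fragment
#' with ~0.37.
#'
#' @param replicates Number of draws per size (default 1000).
#' @param n_copies Template copies.
#' @param sizes Fragment sizes in bp.
#' @param p_deg Per-base-pair degradation probability.
#' @param seed Master seed.
#' @return Data frame of draws (`size_bp`, `replicate`, `intact`);
#'   per-size min/max/mean summary in `attr(, "summary")`.
#' @export
run_degradation_demo <- function(replicates = 1000, n_copies = 167,
                                 sizes = c(100, 300), p_deg = 0.0099,
                                 seed = 1) {
  set.seed(derive_seed(seed, 1L))
  out <- do.call(rbind, lapply(sizes, function(x) {
    surv <- p_intact(p_deg, x)
    data.frame(size_bp = x, replicate = seq_len(replicates),
               p_intact = surv,
               intact = stats::rbinom(replicates, n_copies, surv))
  }))
  smry <- do.call(rbind, lapply(split(out, out$size_bp), function(d)
    data.frame(size_bp = d$size_bp[1], p_intact = d$p_intact[1],
               min = min(d$intact), max = max(d$intact),
               mean = mean(d$intact))))
  rownames(smry) <- NULL
  attr(out, "summary") <- smry
  attr(out, "manifest") <- .manifest("degradation_demo", seed, replicates,
    list(n_copies = n_copies, sizes = sizes, p_deg = p_deg))
  out
}

#' Heterozygote balance versus template amount (diamond effect)
#'
#' Simulates low-template samples at a set of mean PCR-reaction amounts
#' under one-tube extraction (`ex_e = 1`) with a small PCR aliquot, cycle
#' numbers drawn uniformly from `pcr_cycles_range` per sample, stutter
#' simulation on, and a calibrated CE read-out (default 3130xL, LDT 50
#' RFU).  Records pass the stutter-pair exclusion and saturation filters
#' before being returned, mirroring how such data are cleaned before Hb is
#' summarised.  The variance of log10(Hb) is expected to be non-monotone
#' in amount: it shrinks again at sub-cell amounts where the copy-number
#' support collapses onto few discrete ratios.
#'
#' @param replicates Samples per amount (default 50, i.e. 200 in total for
#'   the default four amounts).
#' @param amounts_pg Mean amounts of DNA in the PCR reaction (pg).
#' @param pcr_aliquot Aliquot fraction forwarded to PCR.
#' @param pcr_cycles_range Integer range of PCR cycle numbers.
#' @param pcr_efficiency Per-cycle PCR efficiency.
#' @param stutter_probability Stutter probability per amplification event.
#' @param ce CE parameters.
#' @param saturation Saturation threshold in RFU.
#' @param pg_per_cell Mass per diploid cell (pg).
#' @param kit Kit definition.
#' @param seed Master seed.
#' @return Filtered Hb records with columns `amount_pg`, `sample`,
#'   `pcr_cycles`.
#' @export
run_hb_vs_amount <- function(replicates = 50,
                             amounts_pg = c(2.4, 19.5, 31.7, 63.3),
                             pcr_aliquot = 0.05,
                             pcr_cycles_range = 30:35,
                             pcr_efficiency = 0.90,
                             stutter_probability = 0.005,
                             ce = ce_3130xl(),
                             saturation = 10000,
                             pg_per_cell = 6.6,
                             kit = make_fixture_kit(),
                             seed = 1) {
  out <- list(); idx <- 0L
  g <- random_genotype(kit, seed = derive_seed(seed, 900000L))
  for (a in amounts_pg) {
    idx <- idx + 1L
    pp <- process_params(1, pcr_aliquot, pcr_cycles_range[1], pcr_efficiency,
                         stutter_probability, 1)
    target_cells <- a / (pg_per_cell * pcr_aliquot)
    hb <- .sim_hb_condition(replicates, g, kit, pp, ce,
                            target = target_cells, mode = "poisson",
                            seed = derive_seed(seed, 910000L + idx),
                            pcr_cycles_range = pcr_cycles_range)
    hb <- exclude_stutter_pairs(hb, kit)
    hb <- saturation_filter(hb, saturation)
    hb$amount_pg <- a
    out[[idx]] <- hb
  }
  res <- do.call(rbind, out)
  attr(res, "manifest") <- .manifest("hb_vs_amount", seed, replicates,
    list(amounts_pg = amounts_pg, ex_e = 1, pcr_a = pcr_aliquot,
         pcr_cycles_range = range(pcr_cycles_range),
         pcr_efficiency = pcr_efficiency,
         stutter_probability = stutter_probability,
         saturation = saturation, pg_per_cell = pg_per_cell,
         ce = unclass(ce)))
  res
}
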