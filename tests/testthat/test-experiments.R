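# Scaled-down versions of the figure experiments; qualitative assertions
# only (the published experiments are stochastic figures).

kit2 <- make_fixture_kit(2, c(70, 200))

test_that("PCR-efficiency sweep: ideal diploids balance; haploids split discretely", {
  res <- run_efficiency_sweep(replicates = 300, efficiencies = 1,
                              cells_diploid = 4, cells_haploid = 4,
                              kit = kit2, seed = 51)
  dip <- res[res$ploidy == "diploid" & res$status == "ok", ]
  expect_true(all(dip$hb == 1))

  hap <- res[res$ploidy == "haploid", ]
  n <- nrow(hap)
  splits <- c(`0.333` = 0.25, `1` = 0.375, `3` = 0.25)
  for (r in names(splits)) {
    p <- splits[[r]]
    emp <- mean(hap$status == "ok" &
                  abs(hap$hb - as.numeric(r)) < 0.01)
    expect_lt(abs(emp - p), 4 * sqrt(p * (1 - p) / n))
  }
  emp_drop <- mean(hap$status == "dropout")
  expect_lt(abs(emp_drop - 0.125), 4 * sqrt(0.125 * 0.875 / n))
})

test_that("low PCR efficiency smooths and widens the haploid Hb distribution", {
  res <- run_efficiency_sweep(replicates = 200, efficiencies = c(0.2, 1.0),
                              cells_diploid = 8, cells_haploid = 8,
                              pcr_cycles = 12, kit = kit2, seed = 52)
  sdlog <- function(e, pl) {
    hb <- res$hb[res$pcr_efficiency == e & res$ploidy == pl &
                   res$status == "ok"]
    sd(log10(hb))
  }
  expect_gt(sdlog(0.2, "haploid"), sdlog(1.0, "haploid"))
  # at full efficiency diploids are exact; at 0.2 they are not
  expect_equal(sdlog(1.0, "diploid"), 0)
  expect_gt(sdlog(0.2, "diploid"), 0)
})

test_that("PCR-aliquot sweep: full aliquot is exact; small aliquots merge cell types", {
  res <- run_aliquot_sweep(replicates = 250, aliquots = c(0.05, 1.00),
                           cells_diploid = 16, cells_haploid = 32,
                           pcr_cycles = 10, kit = kit2, seed = 53)
  full_dip <- res[res$pcr_aliquot == 1 & res$ploidy == "diploid", ]
  expect_true(all(full_dip$status == "ok" & full_dip$hb == 1))

  lg10 <- function(a, pl) {
    h <- res$hb[res$pcr_aliquot == a & res$ploidy == pl & res$status == "ok"]
    log10(h)
  }
  # equal-amount comparison: n diploid vs 2n haploid cells
  ks_small <- suppressWarnings(
    ks.test(lg10(0.05, "diploid"), lg10(0.05, "haploid")))
  expect_gt(ks_small$p.value, 0.01)  # practically identical
  # at pcr_a = 1 the distributions are categorically different
  ks_full <- suppressWarnings(
    ks.test(lg10(1, "diploid"), lg10(1, "haploid")))
  expect_gt(ks_small$p.value, ks_full$p.value)
  expect_lt(ks_full$p.value, 0.01)
})

test_that("extraction sweep: cell-type difference grows with extraction efficiency", {
  res <- run_extraction_sweep(replicates = 250,
                              efficiencies = c(0.30, 0.60, 1.00),
                              cells_diploid = 8, cells_haploid = 16,
                              pcr_cycles = 10, kit = kit2, seed = 54)
  dstat <- function(ex) {
    d <- log10(res$hb[res$extraction_efficiency == ex &
                        res$ploidy == "diploid" & res$status == "ok"])
    h <- log10(res$hb[res$extraction_efficiency == ex &
                        res$ploidy == "haploid" & res$status == "ok"])
    suppressWarnings(ks.test(d, h))
  }
  expect_true(all(res$hb[res$extraction_efficiency == 1 &
                           res$ploidy == "diploid" &
                           res$status == "ok"] == 1))
  # roughly equal at 0.30; clearly different at 0.60 and at 1.00
  expect_gt(dstat(0.30)$p.value, 0.01)
  expect_lt(dstat(0.60)$p.value, 0.01)
  expect_gt(dstat(0.60)$statistic, dstat(0.30)$statistic)
})

test_that("combined sweep keeps full bookkeeping and a manifest", {
  res <- run_combined_sweep(replicates = 60, extraction = c(0.30, 1.00),
                            aliquots = c(0.35, 1.00),
                            cells_diploid = 16, cells_haploid = 32,
                            pcr_cycles = 10, kit = kit2, seed = 55)
  # rows = replicates x conditions x heterozygous loci scored
  expect_equal(nrow(res), 60 * 2 * 2 * 2 * 2)
  m <- attr(res, "manifest")
  expect_equal(m$experiment, "combined_sweep")
  expect_equal(m$seed, 55)
  expect_true(all(c("extraction_efficiency", "pcr_aliquot", "ploidy",
                    "cells", "hb") %in% names(res)))
  # direct PCR separates the cell types; lossy processing merges them
  d11 <- suppressWarnings(ks.test(
    log10(res$hb[res$extraction_efficiency == 1 & res$pcr_aliquot == 1 &
                   res$ploidy == "diploid" & res$status == "ok"]),
    log10(res$hb[res$extraction_efficiency == 1 & res$pcr_aliquot == 1 &
                   res$ploidy == "haploid" & res$status == "ok"])))
  d33 <- suppressWarnings(ks.test(
    log10(res$hb[res$extraction_efficiency == 0.3 &
                   res$pcr_aliquot == 0.35 &
                   res$ploidy == "diploid" & res$status == "ok"]),
    log10(res$hb[res$extraction_efficiency == 0.3 &
                   res$pcr_aliquot == 0.35 &
                   res$ploidy == "haploid" & res$status == "ok"])))
  expect_gt(d11$statistic, d33$statistic)
})

test_that("degradation demo draws have binomial moments", {
  res <- run_degradation_demo(replicates = 1000, seed = 56)
  s <- attr(res, "summary")
  m300 <- res$intact[res$size_bp == 300]
  m100 <- res$intact[res$size_bp == 100]
  expect_lt(abs(mean(m300) - 167 * p_intact(0.0099, 300)), mc_tol(m300))
  expect_lt(abs(mean(m100) - 167 * p_intact(0.0099, 100)), mc_tol(m100))
  expect_gte(min(m300), 0)
  expect_equal(s$mean[s$size_bp == 100], mean(m100))
  # survival probability one: every draw complete
  res1 <- run_degradation_demo(replicates = 50, sizes = 100, p_deg = 0,
                               seed = 56)
  expect_true(all(res1$intact == 167))
})

test_that("dilution and crime-stain arms cover the amount grid", {
  res <- run_dilution_vs_stain(
    replicates = 30, amount_max = 52.8, n_levels = 2,
    settings = data.frame(ex_e = 0.30, pcr_a = 0.35),
    pcr_cycles = 12, pcr_efficiency = 0.9, ce = ce_identity(),
    kit = kit2, seed = 57)
  expect_setequal(unique(res$arm),
                  c("dilution", "stain_diploid", "stain_haploid"))
  expect_setequal(unique(res$amount_pg), c(52.8, 26.4))
  # every arm scored at both amounts with the right replicate count
  counts <- table(res$arm, res$amount_pg)
  expect_true(all(counts == 30 * 2))  # 2 heterozygous loci per sample
  # the dilution's mean scored signal halves from level to level
  lv <- tapply(res$hmw_signal[res$arm == "dilution"],
               res$amount_pg[res$arm == "dilution"],
               mean, na.rm = TRUE)
  ratio <- lv[["26.4"]] / lv[["52.8"]]
  expect_lt(abs(ratio - 0.5), 0.1)
  s <- hb_summary(res, by = c("arm", "amount_pg"))
  expect_true(all(c("q05", "q95", "dropout_frac") %in% names(s)))
})

test_that("Hb-vs-amount runs are filtered and show amount-dependent drop-out", {
  res <- run_hb_vs_amount(replicates = 30, amounts_pg = c(2.4, 63.3),
                          kit = make_fixture_kit(4), seed = 58)
  expect_true(all(c("filtered_reason", "amount_pg", "pcr_cycles")
                  %in% names(res)))
  expect_true(all(res$pcr_cycles %in% 30:35))
  drop_rate <- tapply(res$status == "dropout", res$amount_pg, mean)
  expect_gt(drop_rate[["2.4"]], drop_rate[["63.3"]])
  # low amounts leave a multi-modal discrete backbone: scored ratios at
  # the lowest amount concentrate on few support points
  lo <- res$hb[res$amount_pg == 2.4 & res$status == "ok" &
                 is.na(res$filtered_reason)]
  expect_true(length(unique(round(lo, 2))) < length(lo) ||
                length(lo) <= 1)
})

test_that("experiments are reproducible from their seed", {
  a <- run_efficiency_sweep(replicates = 10, efficiencies = 0.8,
                            cells_diploid = 4, cells_haploid = 4,
                            pcr_cycles = 8, kit = kit2, seed = 59)
  b <- run_efficiency_sweep(replicates = 10, efficiencies = 0.8,
                            cells_diploid = 4, cells_haploid = 4,
                            pcr_cycles = 8, kit = kit2, seed = 59)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
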