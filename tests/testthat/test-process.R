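test_that("diploid cells contribute both alleles symmetrically", {
  kit <- small_kit()
  g <- het_genotype(kit)
  mt <- sample_cells(g, 4, "fixed", seed = 1)
  expect_s3_class(mt, "molecule_table")
  expect_identical(stage(mt), "sampled")
  expect_true(all(mt$count == 4))
  expect_equal(nrow(mt), 4)  # 2 loci x 2 alleles
  expect_error(sample_cells(g, 2.5, "fixed"), "integer")
  expect_error(sample_cells(g, -1), "non-negative")
})

test_that("haploid cell sampling splits alleles Binomial(n, 1/2)", {
  kit <- make_fixture_kit(1)
  g <- het_genotype(kit, ploidy = "haploid")
  n <- 20000
  set.seed(2)
  a <- vapply(seq_len(n), function(i) sample_cells(g, 4, "fixed")$count[1],
              numeric(1))
  for (k in 0:4) {
    p <- dbinom(k, 4, 0.5)
    tol <- 4 * sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(a == k) - p), tol)
  }
})

test_that("poisson mode draws the cell count from Poisson(target)", {
  kit <- make_fixture_kit(1)
  g <- het_genotype(kit)
  n <- 20000
  set.seed(3)
  cells <- vapply(seq_len(n), function(i)
    attr(sample_cells(g, 0.25, "poisson"), "n_cells"), numeric(1))
  expect_lt(abs(mean(cells) - 0.25), mc_tol(cells))
  expect_lt(abs(var(cells) - 0.25), 4 * 0.25 * sqrt(2 / (n - 1)) + 0.01)
})

test_that("binomial thinning has the right limits and moments", {
  kit <- small_kit()
  mt <- sample_cells(het_genotype(kit), 10, "fixed", seed = 4)
  expect_equal(binomial_thin(mt, 1, "extracted")$count, mt$count)
  expect_true(all(binomial_thin(mt, 0, "extracted")$count == 0))
  expect_error(binomial_thin(mt, 1.2), "must be in \\[0, 1\\]")

  big <- sample_cells(het_genotype(make_fixture_kit(1)), 10000, "fixed",
                      seed = 4)
  set.seed(5)
  draws <- vapply(seq_len(1000), function(i)
    binomial_thin(big, 0.3, "extracted")$count[1], numeric(1))
  expect_lt(abs(mean(draws) - 3000), mc_tol(draws))
  v <- 10000 * 0.3 * 0.7
  expect_lt(abs(var(draws) - v), 4 * v * sqrt(2 / 999))
})

test_that("ideal PCR doubles deterministically; zero efficiency is inert", {
  kit <- make_fixture_kit(1)
  mt <- sample_cells(het_genotype(kit), 5, "fixed", seed = 6)
  for (cyc in c(0, 3, 7)) {
    out <- pcr_amplify(mt, cyc, 1, 0, seed = 6)
    expect_true(all(out$count == 5 * 2^cyc))
  }
  out0 <- pcr_amplify(mt, 12, 0, 0, seed = 6)
  expect_equal(out0$count, mt$count)
})

test_that("PCR replicate means follow the branching-process yield N(1+e)^c", {
  kit <- make_fixture_kit(1)
  g <- het_genotype(kit)
  mt <- sample_cells(g, 100, "fixed", seed = 7)
  set.seed(7)
  for (case in list(c(e = 0.9, c = 28, reps = 200),
                    c(e = 0.5, c = 12, reps = 300),
                    c(e = 0.2, c = 12, reps = 300))) {
    finals <- vapply(seq_len(case[["reps"]]), function(i)
      pcr_amplify(mt, case[["c"]], case[["e"]])$count[1], numeric(1))
    expected <- 100 * (1 + case[["e"]])^case[["c"]]
    expect_lt(abs(mean(finals) - expected), mc_tol(finals))
  }
})

test_that("stutter products appear one repeat short and match the branching oracle", {
  kit <- make_fixture_kit(1)  # repeat unit 4 bp
  g <- het_genotype(kit, seed = 8)
  mt <- sample_cells(g, 4, "fixed", seed = 8)
  parent_sizes <- mt$size_bp

  out <- pcr_amplify(mt, 6, 0.9, 0.2, kit = kit, seed = 8)
  st <- out[out$is_stutter, ]
  expect_true(nrow(st) > 0)
  expect_true(all((parent_sizes[match(st$allele, mt$allele)] - st$size_bp)
                  %% 4 == 0))
  expect_true(all(out$count >= 0))

  # replicate mean of every fragment count vs the deterministic
  # expectation recursion of the two-type branching process
  eff <- 0.6; sp <- 0.1; cycles <- 5; reps <- 1500
  E <- expected_pcr_counts(mt$size_bp[1], 4, cycles, eff, sp, 4)
  set.seed(9)
  single <- mt[1, ]
  class(single) <- class(mt); attr(single, "stage") <- "sampled"
  sums <- matrix(0, nrow = reps, ncol = length(E),
                 dimnames = list(NULL, names(E)))
  for (r in seq_len(reps)) {
    o <- pcr_amplify(single, cycles, eff, sp, kit = kit)
    sums[r, as.character(o$size_bp)] <- o$count
  }
  for (nm in names(E))
    expect_lt(abs(mean(sums[, nm]) - E[[nm]]),
              max(mc_tol(sums[, nm]), 0.02 * E[[nm]], 1e-4))

  # and the per-molecule brute-force simulator agrees on the expected
  # stutter fraction
  set.seed(10)
  bf_frac <- vapply(seq_len(1500), function(i) {
    s <- brute_force_pcr(rep(mt$size_bp[1], 4), cycles, eff, sp, 4)
    mean(s < mt$size_bp[1])
  }, numeric(1))
  impl_frac <- rowSums(sums[, names(E) != as.character(mt$size_bp[1]),
                            drop = FALSE]) / rowSums(sums)
  expect_lt(abs(mean(bf_frac) - mean(impl_frac)),
            sqrt(mc_tol(bf_frac)^2 + mc_tol(impl_frac)^2))
})

test_that("degradation thinning follows the length-dependent survival law", {
  kit <- small_kit()
  mt <- sample_cells(het_genotype(kit), 10, "fixed", seed = 11)
  amp <- pcr_amplify(mt, 10, 1, 0)
  expect_equal(apply_degradation(amp, 0, seed = 1)$count, amp$count)
  expect_error(apply_degradation(amp, 1), "\\[0, 1\\)")

  big <- pcr_amplify(sample_cells(het_genotype(make_fixture_kit(1)), 10000,
                                  "fixed", seed = 11), 0, 1, 0)
  x <- big$size_bp[1]
  set.seed(12)
  draws <- vapply(seq_len(1000), function(i)
    apply_degradation(big, 0.005)$count[1], numeric(1))
  expect_lt(abs(mean(draws) - 10000 * p_intact(0.005, x)), mc_tol(draws))
})

test_that("CE detection: identity heights, absent peaks, monotone scaling", {
  kit <- make_fixture_kit(1)
  g <- het_genotype(kit)
  mt <- sample_cells(g, 1234, "fixed", seed = 13)
  epg <- ce_detect(pcr_amplify(mt, 0, 1, 0), ce_identity(), seed = 13)
  expect_true(all(epg$height_rfu == 1234))
  expect_true(all(epg$detected))
  epg_ldt <- ce_detect(pcr_amplify(mt, 0, 1, 0), ce_identity(ldt = 2000),
                       seed = 13)
  expect_false(any(epg_ldt$detected))

  empty <- sample_cells(g, 0, "fixed", seed = 13)
  expect_equal(nrow(ce_detect(pcr_amplify(empty, 0, 1, 0), ce_identity())), 0)

  # noise-free calibrated mode: height strictly increasing in N
  ce <- ce_params(threshold_intercept = 2, scaling_intercept = -1,
                  scaling_slope = 1.1, ldt = 0)
  heights <- vapply(c(10, 100, 1000, 1e5), function(N) {
    m <- sample_cells(g, N, "fixed", seed = 14)
    e <- ce_detect(pcr_amplify(m, 0, 1, 0), ce, seed = 14)
    if (nrow(e)) e$height_rfu[1] else 0
  }, numeric(1))
  expect_true(all(diff(heights) > 0))
  # sub-trigger counts produce no signal: ln(10) > 2 but ln(5) < 2
  low <- ce_detect(pcr_amplify(sample_cells(g, 5, "fixed", seed = 15),
                               0, 1, 0), ce, seed = 15)
  expect_false(any(low$detected))
})

test_that("detected peaks always meet the LDT", {
  kit <- small_kit()
  g <- het_genotype(kit)
  ce <- ce_3130xl()
  pp <- process_params(1, 0.5, 30, 0.9, 0.005, 1)
  for (i in 1:20) {
    epg <- simulate_sample(g, kit, pp, ce, target = 3, seed = i)
    if (nrow(epg))
      expect_true(all(epg$height_rfu[epg$detected] >= ce$ldt))
  }
})

test_that("the composed pipeline balances ideal diploids and records stages", {
  kit <- small_kit()
  g <- het_genotype(kit)
  pp <- ideal_params(cycles = 8)
  epg <- simulate_sample(g, kit, pp, ce_identity(), target = 6,
                         trace = TRUE, seed = 16)
  hb <- heterozygote_balance(epg, g)
  expect_true(all(hb$status == "ok"))
  expect_true(all(hb$hb == 1))

  tr <- attr(epg, "trace")
  expect_identical(names(tr),
                   c("sampled", "extracted", "aliquoted", "amplified",
                     "injected"))
  # conservation: selections never increase a count, PCR never decreases
  expect_true(all(tr$extracted$count <= tr$sampled$count))
  expect_true(all(tr$aliquoted$count <= tr$extracted$count))
  expect_true(all(tr$amplified$count[match(
    paste(tr$aliquoted$locus, tr$aliquoted$allele),
    paste(tr$amplified$locus, tr$amplified$allele))] >=
      tr$aliquoted$count))

  expect_equal(nrow(simulate_sample(g, kit, pp, ce_identity(), target = 0,
                                    seed = 17)), 0)
})

test_that("a fixed seed reproduces a pipeline run bit-for-bit", {
  kit <- small_kit()
  g <- het_genotype(kit)
  pp <- process_params(0.3, 0.35, 15, 0.85, 0.005, 0.8)
  a <- simulate_sample(g, kit, pp, ce_3130xl(), p_deg = 0.005, target = 20,
                       mode = "poisson", seed = 99)
  b <- simulate_sample(g, kit, pp, ce_3130xl(), p_deg = 0.005, target = 20,
                       mode = "poisson", seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(derive_seed(1, 0:10000) >= 0))
  expect_true(all(derive_seed(1, 0:10000) < 2^31))
  expect_false(any(duplicated(derive_seed(42, 1:10000))))
})
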