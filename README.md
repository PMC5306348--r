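# strsim

Stochastic simulation of the forensic STR profiling process.

## The problem

Forensic DNA profiles are produced by a chain of lossy, random steps:
cells are recovered from a stain, DNA is extracted (a fraction of
molecules is lost), an aliquot of the extract is amplified by PCR (with
imperfect per-cycle efficiency and stutter artefacts), the product may be
degraded, and a capillary electrophoresis (CE) instrument converts the
surviving molecules into peaks.  For low-template samples every one of
these steps contributes stochastic variation to the *heterozygote
balance* — the ratio of the two allele signals at a heterozygous locus —
and to allelic drop-out, the quantities that continuous interpretation
models must be calibrated against.  Laboratory calibration experiments
are expensive and cannot reach sub-cell template amounts at all; `strsim`
lets analysts and method developers explore this regime by simulation.

## The model

Every pre-CE selection step is a binomial thinning of per-fragment
molecule counts `N' ~ Bin(N, p)` with `p` the extraction efficiency
`ex_e`, the PCR aliquot fraction `pcr_a`, or the CE aliquot `ce_a`.  PCR
is a branching process: in each of `pcr_c` cycles every template molecule
independently produces an allelic copy with probability
`pcr_e (1 - stutter_p)`, a stutter copy one repeat unit shorter with
probability `pcr_e * stutter_p`, or nothing; expected yield after c
cycles is `N (1 + pcr_e)^c`.  Degradation is random per-base cleavage: a
fragment of `x` bp survives with probability

    P(!drop_1) = (1 - P(deg))^x,

applied as a post-PCR binomial thinning `N_intact ~ Bin(N, P(!drop_1))`.
Since concentration then decays log-linearly in target length,
`ln c(x) = ln H + x ln(1 - P(deg))`, a dual-target qPCR pair
`(c(x1), c(x2))` identifies the per-base-pair degradation probability

    P(deg) = 1 - exp[(ln c(x2) - ln c(x1)) / (x2 - x1)],

a *kit-independent* alternative to the degradation index
`DI = C_small / C_large`.  Heterozygote balance is scored as
`Hb = signal(HMW) / signal(LMW)`; for `n` haploid cells the allele split
is `Binomial(n, 1/2)`, so the exact Hb distribution (including the
apparent-homozygote drop-out atoms `0/n` and `n/0`) is enumerable in
closed form.

## Worked example

```r
library(strsim)

# exact haploid balance probabilities
enumerate_haploid_hb(8)
#> Hb distribution for 8 haploid cells
#>   P(accepted, 0.60 <= Hb <= 1.67) = 0.711
#>   P(balanced, Hb = 1)            = 0.273
#>   P(drop-out atoms 0/n, n/0)     = 0.007812

# one simulated sample through the whole process
kit <- make_fixture_kit(2)
g   <- random_genotype(kit, seed = 1)
pp  <- process_params(extraction_efficiency = 1, pcr_aliquot = 1,
                      pcr_cycles = 5, pcr_efficiency = 1,
                      stutter_probability = 0, ce_aliquot = 1)
epg <- simulate_sample(g, kit, pp, ce_identity(), target = 4, seed = 1)
heterozygote_balance(epg, g)
#>   locus lmw_allele hmw_allele lmw_size hmw_size lmw_signal hmw_signal hb status filtered_reason
#> 1 STR01         13         18       82      102        128        128  1     ok            <NA>
#> 2 STR02         10         16      414      438        128        128  1     ok            <NA>

# per-bp degradation probability from a dual-target qPCR measurement
estimate_p_deg(31.510, 0.0565, x_small = 80, x_large = 214)
#> degradation model: P(deg) = 0.0461 per bp  (DI = 557.7, targets 80/214 bp)
#>   undegraded concentration H = 1374
```

With all selection probabilities at 1 and perfect PCR, the four diploid
cells give exactly 4 x 2^5 = 128 molecules per allele, hence perfect
balance (`hb = 1`) — the ideal limit.  The degradation fit says that at
this level of decay each additional base pair costs a fragment 4.6 % of
its survival probability, which is why the 214 bp target retains almost
none of the small target's concentration (DI = 558).

Sweep experiments (`run_efficiency_sweep()`, `run_aliquot_sweep()`,
`run_extraction_sweep()`, `run_combined_sweep()`,
`run_dilution_vs_stain()`, `run_hb_vs_amount()`) return tidy Hb record
tables with a parameter manifest attached; `hb_summary()` condenses them
into percentile/drop-out tables.  A command-line entry point is installed
under `exec/strsim` with subcommands `simulate`, `experiment`,
`estimate-deg`, `enumerate`, `cells-required` and `make-kit`.

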