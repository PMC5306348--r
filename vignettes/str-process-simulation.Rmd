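---
title: "Simulating the STR profiling process: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the STR profiling process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strsim)
```

## The process model

`strsim` models the forensic DNA workflow as a chain of random selections
acting on integer molecule counts, kept per *(locus, fragment identity)*
where a fragment identity is an allele designation, a stutter flag, and a
fragment length in base pairs.  All length-dependent physics keys off the
fragment length; allele designations are opaque labels.

1. **Cell sampling.** A stain holds a number of cells — fixed, or drawn
   from a Poisson distribution when the target is a (possibly sub-unit)
   average, the natural model for casework stains.  A diploid cell
   deposits one molecule of each allele at every locus; a haploid cell
   (e.g. a sperm cell) carries one allele per locus, chosen with
   probability 1/2 independently per cell and locus.  For `n` haploid
   cells the allele split at a heterozygous locus is therefore
   `Binomial(n, 1/2)`.
2. **Extraction, PCR aliquot, CE aliquot.** Each is a binomial thinning
   `N' ~ Bin(N, p)` with `p = ex_e`, `pcr_a`, `ce_a`: every molecule
   independently survives or not.
3. **PCR.** A per-cycle branching process.  Each template independently
   yields an allelic copy with probability `pcr_e (1 - stutter_p)`, a
   stutter copy one repeat unit shorter with probability
   `pcr_e * stutter_p`, or no copy — a multinomial selection per
   molecule.  Templates persist and all products template later cycles.
   At `pcr_e = 1`, `stutter_p = 0` this is exact doubling
   (`N 2^c`); in general the expected yield is `N (1 + pcr_e)^c`.
   Per-cycle efficiency is constant: low-template reactions do not reach
   the plateau phase, so plateau kinetics are deliberately out of scope.
4. **Degradation.** Random per-base cleavage with probability `P(deg)`
   per base pair: a fragment of `x` bp is amplifiable only if all `x`
   positions are intact, `P(!drop_1) = (1 - P(deg))^x`.  It is applied as
   a *post-PCR* binomial thinning of the amplified counts, which is how
   the process model defines it; a pre-PCR option
   (`degrade_pre_pcr = TRUE`) reflecting the physical ordering is
   provided but off by default.  Stutter fragments are thinned with their
   own, shorter length.
5. **CE detection.** After the CE-aliquot thinning, a fragment with no
   molecules yields no peak (drop-out).  In *identity mode* the peak
   height is the molecule count and the trigger threshold is zero — the
   convention used for all theoretical sweeps so that sub-threshold
   observations are retained.  In *calibrated mode* a fragment with `N`
   molecules triggers when `ln N >= Ti + Ts ln(h0) + eps_T` (reference
   `h0 = 1` RFU, `eps_T ~ N(0, Tsigma^2)`) and a triggered peak gets
   height `ln h = Si + Ss ln N + eps_S`.  Peaks below the analyst's
   limit-of-detection threshold (LDT) are marked undetected.

### Parameters

| parameter | meaning | unit / domain | default |
|---|---|---|---|
| `extraction_efficiency` (`ex_e`) | P(molecule survives extraction) | [0, 1] | 0.30 |
| `pcr_aliquot` (`pcr_a`) | fraction of extract into PCR | [0, 1] | 0.35 |
| `pcr_cycles` (`pcr_c`) | number of cycles | count | 28 |
| `pcr_efficiency` (`pcr_e`) | P(template copied per cycle) | [0, 1] | 0.90 |
| `stutter_probability` | P(copy is a stutter, given a copy is made) | [0, 1] | 0.005 |
| `ce_aliquot` (`ce_a`) | fraction of product injected | [0, 1] | 1.0 |
| `p_deg` | P(cleavage) per base pair | [0, 1) | 0 |
| `ldt` | limit of detection | RFU | 0 / 200 / 50 |

Defaults describe a realistic casework process: an efficient extraction
(30 %), a generous aliquot (35 %), and a mid-range published PCR
efficiency (90 %) over 28 cycles.  Direct PCR corresponds to
`ex_e = pcr_a = 1`.  Instrument presets `ce_3500xl()` (trigger 14.03744 /
0.82254 / 0.1319579, scaling -14.38233 / 1.173163, LDT 200 RFU) and
`ce_3130xl()` (trigger 15.4653 / 0.9044 / 0.364, scaling -13.66131 /
1.0047 / 0.3836, LDT 50 RFU) carry published calibration constants; no
scaling residual SE is available for the 3500xL, so it uses 0.  The
calibrations are published as intercept/slope/residual-SE triplets
without the underlying regression variables; the log-log contract above
is this package's documented reading, and every theoretical result in
the test suite uses identity mode, which does not depend on it.

Two mass-per-cell constants coexist deliberately: the cells-required
planning grid is built on 6 pg per diploid cell (its published amounts
are exact multiples of 6), while the simulation experiments convert
picograms to cells at 6.6 pg per diploid cell (3.3 pg haploid).  Both
are explicit arguments, never hard-coded, because the two conventions
are genuinely inconsistent with each other.

## Heterozygote balance

`Hb = signal(HMW) / signal(LMW)` — high-molecular-weight over
low-molecular-weight allele, scored from molecule counts in identity
mode and from peak heights otherwise.  `Hb` is undefined at a locus with
a dropped allele; such loci are recorded as drop-outs, excluded from the
accepted-fraction numerator but kept in its denominator.  The accepted
range is the *closed* interval [0.6, 1.67]: the 3/5 and 5/3 splits at
eight haploid cells (5/3 = 1.667) count as accepted, which is required to
reproduce the exact accepted probability 0.711 at n = 8.

`enumerate_haploid_hb()` gives the exact distribution from the
`Binomial(n, 1/2)` split, including the two drop-out atoms `0/n` and
`n/0` with probability `2 * 0.5^n`.  The probabilities are computed as
`choose(n, k) / 2^n`, which is exact in binary floating point for small
`n`.  The binomial enumeration reproduces the published theoretical
balance table at all eight printed cell counts, which is why it — and
not a Poisson construction — is the oracle used throughout.

Two filters mirror practice with real electropherograms:
`exclude_stutter_pairs()` removes loci whose two alleles sit one repeat
unit apart (a stutter of the surviving allele could masquerade as the
dropped partner), and `saturation_filter()` removes loci whose mean
allele height exceeds the camera saturation point (strictly above
10,000 RFU by default).

## Degradation mathematics

The decay model `ln c(x) = ln H + x ln(1 - P(deg))` is inverted from a
single dual-target measurement; the estimator clamps a
model-violating pair (`c_large > c_small`) to `P(deg) = 0` with a
warning rather than returning a negative probability.  Estimates
round-trip exactly (relative error < 1e-12 in the tests) and are kit
independent: pairs generated at 80/214 bp and at 84/294 bp target
lengths from the same extract recover identical `P(deg)` while their
degradation indices differ — the practical argument for reporting
`P(deg)` rather than `DI`.  The n-copy formula
`P(drop_n) = 1 - (1 - P(drop_1))^n` is implemented exactly as printed;
note its semantics — it equals the probability that *at least one* copy
is lost — and downstream reasoning uses the per-copy survival
`(1 - P(deg))^x` only.

## The fixture kit and what the generator does not emulate

`make_fixture_kit()` builds a deterministic ESX17-style panel: loci
spread evenly across 70–450 bp, 4 bp (tetranucleotide) repeat units, ten
alleles per locus, dye channels cycled and size-sorted within dye.  The
repeat-unit length is an assumption (standard tetranucleotide STRs);
the simulator never needs real bin sets because all physics depends on
fragment length alone.  The generator does not produce microvariant
alleles, tri-allelic patterns, dye-specific baselines, pull-up
artefacts, forward (n+1) stutter, or sequence-specific inhibition; the
plateau phase of PCR is approximated away.  Passing tests therefore
demonstrate the stochastic selection/branching model, not these
instrument- and sequence-level effects.  Inhibition that acts by slowing
polymerase can still be emulated through lowered `pcr_e` combined with
`p_deg`.

## Numerical and design choices

* **Counts are doubles.** PCR yields exceed 2^31 long before they lose
  integer exactness in doubles (2^53); all counts remain exact integers
  stored as doubles, and binomial draws at sizes ~1e12 are exercised in
  the tests.
* **Stutter recursion.** Stutter products are templates and may stutter
  again (two repeats down); no back-stutter exception is made because
  the rule is uniform and the mass at `stutter_p = 0.005` is negligible.
  A fragment shorter than one repeat cannot stutter; such events yield
  ordinary copies.
* **Homozygous loci** pool both copies onto one fragment identity —
  balance is undefined there and pooling matches what an EPG shows.
* **Seeding.** Every sample draws from a substream derived
  deterministically via `derive_seed(seed, index)` (two multiplicative
  mixes modulo 2^31 - 1), so experiments are reproducible bit-for-bit
  from one master seed and samples are independently seeded.
* **Degenerate inputs.** Zero cells propagate to an empty EPG (full
  drop-out) rather than an error; `p_deg = 1` is rejected (the decay
  log is undefined); fractional cell targets require Poisson mode.

## Experiment recipes and problem sizes

The `run_*` functions reproduce the published simulation designs with
their replicate counts as defaults (500 for the efficiency sweep, 1500
for the aliquot sweep, 1000 for the extraction sweep and the
dilution-vs-stain comparison, 250 for the combined sweep, 50 per amount
for the balance-versus-amount study).  The dilution arm models each
2-fold transfer as a binomial thinning with p = 0.5 of per-allele counts
starting from a 57 ng/ul x 450 ul stock, with a constant
tube-to-reaction fraction delivering 845 pg down to 1.65 pg — dissociated
molecules thinned independently per allele, which is exactly why a
dilution behaves like a haploid stain and unlike a diploid one under
direct PCR.

The test suite runs scaled-down versions (tens to a few hundred
replicates on 1–2 locus panels) chosen so that every qualitative
assertion retains adequate statistical power: distribution comparisons
use a two-sample Kolmogorov–Smirnov test on log10(Hb) at alpha = 0.01
under fixed seeds, a rank-based formalisation of visual
"practically identical / clearly different" judgements.  The
Monte-Carlo checks of printed probabilities use 10,000 replicates and
4-standard-error tolerances.

## Known limitations

Calibrated CE mode rests on the log-log assumption described above;
identity mode should be preferred for theoretical work.  The
degradation estimator uses exactly two target lengths (fitting more
than two is out of scope).  Very deep stutter cascades (3+ repeats
down) carry vanishing probability and are reported but not validated
against data.  The simulator is not a likelihood-ratio engine: it
produces the stochastic raw material such models are calibrated on.
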