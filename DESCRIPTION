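Package: strsim
Title: Stochastic Simulation of the Forensic STR Profiling Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Whole-process Monte Carlo simulator of forensic short tandem
    repeat (STR) profiling: cell sampling, DNA extraction, PCR aliquoting,
    per-cycle amplification with stutter artefacts as a binomial branching
    process, fragment-length dependent degradation, and capillary
    electrophoresis detection with calibrated peak-height scaling.  Includes
    closed-form degradation mathematics (degradation index, per-base-pair
    degradation probability estimated from dual-target qPCR, intact-fragment
    and drop-out probabilities), heterozygote-balance statistics with an
    exact enumeration oracle for haploid copy-number splits, and config
    driven experiment recipes for studying how extraction efficiency, PCR
    aliquot, PCR efficiency, and template amount shape heterozygote balance
    in diploid and haploid (e.g. sperm) cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
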