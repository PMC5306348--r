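# Parameter containers for the pre-CE stochastic process and for CE detection.

.chk_prob <- function(x, name, max_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  hi_ok <- if (max_open) x < 1 else x <= 1
  if (x < 0 || !hi_ok)
    stop(sprintf("'%s' must be in [0, %s], got %g", name,
                 if (max_open) "1)" else "1]", x), call. = FALSE)
  x
}

.chk_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("'%s' must be a non-negative integer, got %s", name,
                 deparse(x)), call. = FALSE)
  as.integer(x)
}

#' Parameters of the pre-electrophoresis DNA process
#'
#' Bundles the stochastic-process parameters of the simulated workflow:
#' every step before capillary electrophoresis is a binomial selection of
#' molecules, and PCR is a per-cycle branching process.
#'
#' @param extraction_efficiency Probability that a given DNA molecule
#'   survives extraction (`ex_e`).
#' @param pcr_aliquot Fraction of the extract volume forwarded to PCR, i.e.
#'   the probability that a given molecule is selected for amplification
#'   (`pcr_a`).
#' @param pcr_cycles Number of PCR cycles (`pcr_c`).
#' @param pcr_efficiency Per-cycle probability that a template molecule is
#'   copied (`pcr_e`); constant across cycles (low-template reactions never
#'   reach the plateau phase).
#' @param stutter_probability Per-amplification-event probability that the
#'   copy is a stutter product one repeat unit shorter than its template
#'   (`stutter_p`); conditional on amplification.
#' @param ce_aliquot Fraction of the PCR product forwarded to the CE
#'   injection plate (`ce_a`).
#' @return An object of class `process_params` (a named list).
#' @examples
#' process_params(pcr_efficiency = 1, stutter_probability = 0)
#' @export
process_params <- function(extraction_efficiency = 0.30,
                           pcr_aliquot = 0.35,
                           pcr_cycles = 28,
                           pcr_efficiency = 0.90,
                           stutter_probability = 0.005,
                           ce_aliquot = 1.0) {
  p <- list(
    extraction_efficiency = .chk_prob(extraction_efficiency, "extraction_efficiency"),
    pcr_aliquot           = .chk_prob(pcr_aliquot, "pcr_aliquot"),
    pcr_cycles            = .chk_count(pcr_cycles, "pcr_cycles"),
    pcr_efficiency        = .chk_prob(pcr_efficiency, "pcr_efficiency"),
    stutter_probability   = .chk_prob(stutter_probability, "stutter_probability"),
    ce_aliquot            = .chk_prob(ce_aliquot, "ce_aliquot"))
  structure(p, class = "process_params")
}

#' @export
print.process_params <- function(x, ...) {
  cat("STR process parameters:\n")
  cat(sprintf("  extraction efficiency (ex_e) : %.3g\n", x$extraction_efficiency))
  cat(sprintf("  PCR aliquot (pcr_a)          : %.3g\n", x$pcr_aliquot))
  cat(sprintf("  PCR cycles (pcr_c)           : %d\n", x$pcr_cycles))
  cat(sprintf("  PCR efficiency (pcr_e)       : %.3g\n", x$pcr_efficiency))
  cat(sprintf("  stutter probability          : %.3g\n", x$stutter_probability))
  cat(sprintf("  CE aliquot (ce_a)            : %.3g\n", x$ce_aliquot))
  invisible(x)
}

#' Capillary electrophoresis detection parameters
#'
#' Calibration of the CE instrument model: the number of fluorescently
#' labelled molecules needed to trigger a signal (threshold triplet), the
#' conversion of molecule counts into relative fluorescence units
#' (scaling triplet), and the analyst's limit-of-detection threshold (LDT)
#' in RFU.  In `identity` mode no threshold or scaling is applied: the peak
#' height *is* the molecule count and the trigger threshold is zero, the
#' convention used to retain sub-threshold observations in low-template
#' simulation studies.
#'
#' Both calibrations are log-log linear with additive Gaussian error on the
#' log scale: a peak triggers when
#' `ln(N) >= threshold_intercept + threshold_slope * ln(h0) + eps_T`,
#' with `h0 = 1` RFU and `eps_T ~ N(0, threshold_sigma^2)`, and a triggered
#' peak has height `ln(h) = scaling_intercept + scaling_slope * ln(N) +
#' eps_S`, `eps_S ~ N(0, scaling_sigma^2)`.
#'
#' @param threshold_intercept,threshold_slope,threshold_sigma Detection
#'   threshold calibration (intercept, slope, residual SE).
#' @param scaling_intercept,scaling_slope,scaling_sigma Peak-height scaling
#'   calibration (intercept, slope, residual SE).
#' @param ldt Limit-of-detection threshold in RFU; peaks below it are
#'   treated as noise.
#' @param identity Logical; if `TRUE`, detection threshold is zero and peak
#'   height equals the molecule count exactly.
#' @return An object of class `ce_params`.
#' @seealso [ce_identity()], [ce_3500xl()], [ce_3130xl()]
#' @export
ce_params <- function(threshold_intercept = 0, threshold_slope = 0,
                      threshold_sigma = 0,
                      scaling_intercept = 0, scaling_slope = 1,
                      scaling_sigma = 0,
                      ldt = 0, identity = FALSE) {
  num1 <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop(sprintf("'%s' must be a single number", name), call. = FALSE)
    x
  }
  if (num1(threshold_sigma, "threshold_sigma") < 0)
    stop("'threshold_sigma' must be >= 0", call. = FALSE)
  if (num1(scaling_sigma, "scaling_sigma") < 0)
    stop("'scaling_sigma' must be >= 0", call. = FALSE)
  if (num1(ldt, "ldt") < 0)
    stop("'ldt' must be >= 0", call. = FALSE)
  structure(list(
    threshold_intercept = num1(threshold_intercept, "threshold_intercept"),
    threshold_slope     = num1(threshold_slope, "threshold_slope"),
    threshold_sigma     = threshold_sigma,
    scaling_intercept   = num1(scaling_intercept, "scaling_intercept"),
    scaling_slope       = num1(scaling_slope, "scaling_slope"),
    scaling_sigma       = scaling_sigma,
    ldt                 = ldt,
    identity            = isTRUE(identity)),
    class = "ce_params")
}

#' @rdname ce_params
#' @details `ce_identity()` returns the identity-mode parameter set
#'   (`ce_T = 0`, `ce_S = 1`) used when molecule counts are analysed
#'   directly.
#' @export
ce_identity <- function(ldt = 0) ce_params(ldt = ldt, identity = TRUE)

#' @rdname ce_params
#' @details `ce_3500xl()` and `ce_3130xl()` return presets with calibration
#'   constants for two common instruments (3500xL: threshold 14.03744 /
#'   0.82254 / 0.1319579, scaling -14.38233 / 1.173163; 3130xL: threshold
#'   15.4653 / 0.9044 / 0.364, scaling -13.66131 / 1.0047 / 0.3836).  No
#'   scaling residual SE is available for the 3500xL calibration, so 0 is
#'   used.  Default LDTs are 200 and 50 RFU respectively.
#' @export
ce_3500xl <- function(ldt = 200) {
  ce_params(threshold_intercept = 14.03744, threshold_slope = 0.82254,
            threshold_sigma = 0.1319579,
            scaling_intercept = -14.38233, scaling_slope = 1.173163,
            scaling_sigma = 0, ldt = ldt)
}

#' @rdname ce_params
#' @export
ce_3130xl <- function(ldt = 50) {
  ce_params(threshold_intercept = 15.4653, threshold_slope = 0.9044,
            threshold_sigma = 0.364,
            scaling_intercept = -13.66131, scaling_slope = 1.0047,
            scaling_sigma = 0.3836, ldt = ldt)
}

#' @export
print.ce_params <- function(x, ...) {
  if (x$identity) {
    cat(sprintf("CE parameters: identity mode (height = molecules), LDT = %g RFU\n",
                x$ldt))
  } else {
    cat("CE parameters (log-log calibration):\n")
    cat(sprintf("  trigger : intercept %g, slope %g, sigma %g\n",
                x$threshold_intercept, x$threshold_slope, x$threshold_sigma))
    cat(sprintf("  scaling : intercept %g, slope %g, sigma %g\n",
                x$scaling_intercept, x$scaling_slope, x$scaling_sigma))
    cat(sprintf("  LDT     : %g RFU\n", x$ldt))
  }
  invisible(x)
}
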