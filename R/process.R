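# Stage operators of the whole-process simulation model: every pre-CE step
# is a binomial selection of molecules, PCR is a per-cycle branching
# process with multinomial stutter, degradation is a post-PCR length
# dependent thinning, and CE detection converts molecule counts to peaks.

#' Sample cells into a molecule table
#'
#' Draws the cells contributing to a stain and lays down their template
#' molecules.  Each diploid cell contributes one molecule of each of the
#' genotype's alleles at every locus (a homozygous locus receives both
#' copies pooled on one fragment identity).  Each haploid cell carries only
#' one allele per locus, chosen with probability 1/2 independently per cell
#' and locus, i.e. cells are drawn from a pool with equal numbers of the
#' two alleles.
#'
#' @param genotype A `str_genotype` (its `ploidy` attribute selects diploid
#'   or haploid behaviour).
#' @param target Mean cell count; may be fractional in `"poisson"` mode.
#' @param mode `"fixed"` (exactly `target` cells, integer) or `"poisson"`
#'   (cell count drawn from Poisson(`target`), the model for crime stains
#'   with sub-cell average amounts).
#' @param seed Optional integer seed.
#' @return A `molecule_table` at stage `"sampled"`.
#' @examples
#' kit <- make_fixture_kit(2)
#' g <- random_genotype(kit, seed = 1)
#' sample_cells(g, 4, "fixed", seed = 1)
#' @export
sample_cells <- function(genotype, target, mode = c("fixed", "poisson"),
                         seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(target) || length(target) != 1L || is.na(target) || target < 0)
    stop("'target' must be a single non-negative number", call. = FALSE)
  ploidy <- attr(genotype, "ploidy")
  if (is.null(ploidy)) stop("genotype has no ploidy attribute", call. = FALSE)
  .seed_rng(seed)
  n_cells <- switch(mode,
    fixed = {
      if (target != floor(target))
        stop("fixed mode requires an integer 'target'", call. = FALSE)
      target
    },
    poisson = stats::rpois(1L, target))
  rows <- lapply(split(genotype, genotype$locus), function(g) {
    a <- g$allele; sz <- g$size_bp
    homozygous <- length(unique(a)) == 1L
    if (homozygous) { a <- a[1L]; sz <- sz[1L] }
    count <- if (ploidy == "diploid") {
      if (homozygous) 2 * n_cells else c(n_cells, n_cells)
    } else {
      if (homozygous) n_cells else {
        na <- stats::rbinom(1L, n_cells, 0.5)
        c(na, n_cells - na)
      }
    }
    data.frame(locus = g$locus[1L], allele = a, is_stutter = FALSE,
               size_bp = sz, count = count, stringsAsFactors = FALSE)
  })
  mt <- .new_molecule_table(do.call(rbind, rows), "sampled")
  attr(mt, "n_cells") <- n_cells
  mt
}

#' Binomial thinning of a molecule table
#'
#' The elementary selection step of the process model: each fragment count
#' is replaced by an independent Binomial(count, p) draw.  Used for
#' extraction (p = extraction efficiency), the PCR aliquot (p = aliquot
#' fraction), and the CE aliquot.
#'
#' @param mt A `molecule_table`.
#' @param p Selection probability in \[0, 1\].
#' @param new_stage Stage label for the result.
#' @param seed Optional integer seed.
#' @return A `molecule_table` at stage `new_stage`.
#' @export
binomial_thin <- function(mt, p, new_stage = stage(mt), seed = NULL) {
  .validate_molecule_table(mt)
  .chk_prob(p, "p")
  .seed_rng(seed)
  out <- mt
  if (nrow(out) > 0L)
    out$count <- stats::rbinom(nrow(out), out$count, p)
  .new_molecule_table(out, new_stage)
}

#' Per-cycle PCR amplification with stutter
#'
#' Simulates `cycles` rounds of PCR as a branching process.  In each cycle
#' every template molecule independently produces one allelic copy with
#' probability `efficiency * (1 - stutter_prob)`, one stutter copy (one
#' repeat unit shorter) with probability `efficiency * stutter_prob`, or no
#' copy otherwise - a multinomial selection per template.  Templates
#' persist, and all products (including stutter) serve as templates in
#' subsequent cycles, so a stutter product may itself stutter to a fragment
#' two repeats down.
#'
#' With `efficiency = 1` and `stutter_prob = 0` the process is
#' deterministic doubling: N molecules become exactly `N * 2^cycles`.  In
#' general the expected yield after c cycles is `N * (1 + efficiency)^c`.
#'
#' @param mt A `molecule_table`.
#' @param cycles Number of PCR cycles.
#' @param efficiency Per-cycle amplification probability.
#' @param stutter_prob Probability that an amplification event yields a
#'   stutter copy (conditional on amplification).
#' @param kit Kit providing repeat-unit lengths; required when
#'   `stutter_prob > 0`.
#' @param seed Optional integer seed.
#' @return A `molecule_table` at stage `"amplified"`; stutter products
#'   appear as new fragment identities flagged `is_stutter = TRUE`, keyed
#'   by their parent allele.
#' @export
pcr_amplify <- function(mt, cycles, efficiency, stutter_prob = 0,
                        kit = NULL, seed = NULL) {
  .validate_molecule_table(mt)
  cycles <- .chk_count(cycles, "cycles")
  .chk_prob(efficiency, "efficiency")
  .chk_prob(stutter_prob, "stutter_prob")
  if (stutter_prob > 0 && is.null(kit))
    stop("'kit' is required to place stutter products", call. = FALSE)
  .seed_rng(seed)
  loc <- mt$locus; all_ <- mt$allele; stut <- mt$is_stutter
  sz <- mt$size_bp; cnt <- as.numeric(mt$count)
  rep_of <- if (!is.null(kit)) .kit_repeats(kit) else NULL
  key <- paste(loc, all_, sz, sep = "\r")
  for (cyc in seq_len(cycles)) {
    n <- length(cnt)
    amp <- as.numeric(stats::rbinom(n, cnt, efficiency))
    if (stutter_prob > 0) {
      st <- stats::rbinom(n, amp, stutter_prob)
      rbp <- unname(rep_of[loc])
      # a fragment shorter than one repeat cannot lose a repeat; such
      # events yield ordinary copies instead
      bad <- sz - rbp <= 0
      if (any(bad)) st[bad] <- 0L
    } else st <- rep(0, n)
    cnt <- cnt + amp - st
    src <- which(st > 0)
    for (i in src) {
      tsz <- sz[i] - rep_of[[loc[i]]]
      tkey <- paste(loc[i], all_[i], tsz, sep = "\r")
      j <- match(tkey, key)
      if (is.na(j)) {
        loc <- c(loc, loc[i]); all_ <- c(all_, all_[i])
        stut <- c(stut, TRUE); sz <- c(sz, tsz)
        cnt <- c(cnt, st[i]); key <- c(key, tkey)
      } else {
        cnt[j] <- cnt[j] + st[i]
      }
    }
  }
  out <- data.frame(locus = loc, allele = all_, is_stutter = stut,
                    size_bp = sz, count = cnt, stringsAsFactors = FALSE)
  out <- out[order(out$locus, out$size_bp), ]
  .new_molecule_table(out, "amplified")
}

#' Fragment-length dependent degradation thinning
#'
#' Applies random DNA cleavage: a fragment of length x survives intact with
#' probability `(1 - p_deg)^x` (one or more cleavages anywhere within the
#' fragment abolish amplification/visualisation).  Each fragment count is
#' thinned by an independent binomial draw with its own length-specific
#' survival probability; stutter fragments use their own, shorter length.
#' Following the process model's definition this is applied post-PCR, to
#' the amplified molecule numbers.
#'
#' @param mt A `molecule_table`.
#' @param p_deg Per-base-pair degradation probability, in \[0, 1).
#' @param new_stage Stage label (default `"degraded"`).
#' @param seed Optional integer seed.
#' @return A thinned `molecule_table`.
#' @export
apply_degradation <- function(mt, p_deg, new_stage = "degraded", seed = NULL) {
  .validate_molecule_table(mt)
  if (!is.numeric(p_deg) || length(p_deg) != 1L || is.na(p_deg) ||
      p_deg < 0 || p_deg >= 1)
    stop("'p_deg' must be in [0, 1)", call. = FALSE)
  .seed_rng(seed)
  out <- mt
  if (nrow(out) > 0L) {
    surv <- p_intact(p_deg, out$size_bp)
    out$count <- stats::rbinom(nrow(out), out$count, surv)
  }
  .new_molecule_table(out, new_stage)
}

#' Capillary electrophoresis detection
#'
#' Converts amplified (possibly degraded) molecule counts into an
#' electropherogram.  The CE aliquot is a binomial thinning; fragments with
#' no molecules left produce no peak (drop-out).  In identity mode the peak
#' height equals the molecule count and the trigger threshold is zero.  In
#' calibrated mode a fragment with N molecules triggers a signal when
#' `ln(N) >= Ti + Ts*ln(h0) + eps_T` (h0 = 1 RFU, eps_T ~ N(0, Tsigma^2))
#' and a triggered peak has height `ln(h) = Si + Ss*ln(N) + eps_S`.  Peaks
#' with height below the limit-of-detection threshold are marked not
#' detected.
#'
#' @param mt A `molecule_table` at stage amplified/degraded.
#' @param ce A `ce_params` object.
#' @param ce_aliquot Fraction of PCR product injected.
#' @param seed Optional integer seed.
#' @return An `epg` data frame: locus, allele, is_stutter, size_bp,
#'   molecules, height_rfu, detected; carries the `ce_params` used as an
#'   attribute.
#' @export
ce_detect <- function(mt, ce, ce_aliquot = 1, seed = NULL) {
  .validate_molecule_table(mt)
  if (!inherits(ce, "ce_params")) stop("'ce' must be a ce_params object",
                                       call. = FALSE)
  .seed_rng(seed)
  inj <- binomial_thin(mt, ce_aliquot, "injected")
  inj <- inj[inj$count > 0, , drop = FALSE]
  n <- nrow(inj)
  if (n == 0L) {
    peaks <- data.frame(locus = character(), allele = character(),
                        is_stutter = logical(), size_bp = numeric(),
                        molecules = numeric(), height_rfu = numeric(),
                        detected = logical(), stringsAsFactors = FALSE)
    return(structure(peaks, ce = ce, class = c("epg", "data.frame")))
  }
  N <- inj$count
  if (ce$identity) {
    height <- N
    triggered <- rep(TRUE, n)
  } else {
    eps_t <- stats::rnorm(n, 0, ce$threshold_sigma)
    h0 <- 1
    triggered <- log(N) >= ce$threshold_intercept +
      ce$threshold_slope * log(h0) + eps_t
    eps_s <- stats::rnorm(n, 0, ce$scaling_sigma)
    height <- ifelse(triggered,
                     exp(ce$scaling_intercept + ce$scaling_slope * log(N) + eps_s),
                     0)
  }
  detected <- triggered & height >= ce$ldt
  peaks <- data.frame(locus = inj$locus, allele = inj$allele,
                      is_stutter = inj$is_stutter, size_bp = inj$size_bp,
                      molecules = N, height_rfu = height,
                      detected = detected, stringsAsFactors = FALSE)
  rownames(peaks) <- NULL
  structure(peaks, ce = ce, class = c("epg", "data.frame"))
}

#' Simulate one sample through the whole process
#'
#' Composes the full pipeline: cell sampling, extraction loss, PCR aliquot,
#' per-cycle amplification with stutter, degradation thinning, and CE
#' detection, recording a snapshot of the molecule table at every stage.
#'
#' @param genotype A `str_genotype`.
#' @param kit The `str_kit` the genotype was drawn from.
#' @param params A `process_params` object.
#' @param ce A `ce_params` object.
#' @param p_deg Per-base-pair degradation probability (0 = no degradation).
#' @param target Mean cell count.
#' @param mode Cell-count mode, `"fixed"` or `"poisson"`.
#' @param degrade_pre_pcr Apply the degradation thinning to template
#'   molecules before amplification instead of to the PCR product.  The
#'   process model defines degradation on the post-PCR molecule numbers
#'   (the default); the pre-PCR option reflects the physical ordering and
#'   is provided for sensitivity analyses.
#' @param trace Keep per-stage `molecule_table` snapshots.
#' @param seed Optional integer seed; the whole sample is reproducible from
#'   it.
#' @return An `epg`; when `trace = TRUE` the ordered stage snapshots are
#'   attached as attribute `"trace"`.
#' @examples
#' kit <- make_fixture_kit(2)
#' g <- random_genotype(kit, seed = 7)
#' ideal <- process_params(1, 1, 4, 1, 0, 1)
#' simulate_sample(g, kit, ideal, ce_identity(), target = 4, seed = 7)
#' @export
simulate_sample <- function(genotype, kit, params = process_params(),
                            ce = ce_identity(), p_deg = 0,
                            target, mode = c("fixed", "poisson"),
                            degrade_pre_pcr = FALSE, trace = FALSE,
                            seed = NULL) {
  mode <- match.arg(mode)
  if (!inherits(params, "process_params"))
    stop("'params' must be a process_params object", call. = FALSE)
  .seed_rng(seed)
  snap <- list()
  mt <- sample_cells(genotype, target, mode)
  if (trace) snap$sampled <- mt
  mt <- binomial_thin(mt, params$extraction_efficiency, "extracted")
  if (trace) snap$extracted <- mt
  mt <- binomial_thin(mt, params$pcr_aliquot, "aliquoted")
  if (trace) snap$aliquoted <- mt
  if (p_deg > 0 && degrade_pre_pcr) {
    mt <- apply_degradation(mt, p_deg, "aliquoted")
    if (trace) snap$degraded_pre_pcr <- mt
  }
  mt <- pcr_amplify(mt, params$pcr_cycles, params$pcr_efficiency,
                    params$stutter_probability, kit = kit)
  if (trace) snap$amplified <- mt
  if (p_deg > 0 && !degrade_pre_pcr) {
    mt <- apply_degradation(mt, p_deg)
    if (trace) snap$degraded <- mt
  }
  epg <- ce_detect(mt, ce, ce_aliquot = params$ce_aliquot)
  if (trace) {
    snap$injected <- .new_molecule_table(
      data.frame(locus = epg$locus, allele = epg$allele,
                 is_stutter = epg$is_stutter, size_bp = epg$size_bp,
                 count = epg$molecules, stringsAsFactors = FALSE),
      "injected")
    attr(epg, "trace") <- snap
  }
  attr(epg, "params") <- params
  attr(epg, "p_deg") <- p_deg
  epg
}

#' @export
print.epg <- function(x, ...) {
  cat(sprintf("EPG: %d peaks (%d detected) at %d loci\n",
              nrow(x), sum(x$detected), length(unique(x$locus))))
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot an electropherogram
#'
#' Simple base-graphics rendering of peak height against fragment size,
#' with stutter peaks dashed and the LDT drawn as a horizontal line.
#'
#' @param x An `epg`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.epg <- function(x, ...) {
  if (!nrow(x)) {
    graphics::plot(0, 0, type = "n", xlab = "fragment size (bp)",
                   ylab = "height (RFU)", main = "empty EPG (full drop-out)")
    return(invisible(x))
  }
  ce <- attr(x, "ce")
  graphics::plot(x$size_bp, x$height_rfu, type = "h",
                 lty = ifelse(x$is_stutter, 2, 1),
                 col = ifelse(x$detected, "black", "grey60"),
                 xlab = "fragment size (bp)", ylab = "height (RFU)", ...)
  if (!is.null(ce) && ce$ldt > 0)
    graphics::abline(h = ce$ldt, col = "red", lty = 3)
  invisible(x)
}
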