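# Heterozygote balance: Hb = signal(HMW allele) / signal(LMW allele) at a
# heterozygous locus, the filtering rules applied before summarising it,
# and an exact enumeration oracle for small haploid copy numbers.

#' Heterozygote balance per locus
#'
#' Scores every heterozygous locus of the genotype against an EPG.  The
#' signal is the peak height (which equals the molecule count when no CE
#' scaling is used), and the ratio is high-molecular-weight over
#' low-molecular-weight allele.  A locus where either allele produced no
#' detected peak is recorded with status `"dropout"` and an undefined
#' ratio; stutter peaks are never used as allele signals.
#'
#' @param epg An `epg`.
#' @param genotype The `str_genotype` the sample was simulated from.
#' @return A data frame of Hb records: locus, lmw/hmw allele, size, signal,
#'   `hb`, `status` (`"ok"`/`"dropout"`), and `filtered_reason`
#'   (`NA` until a filter marks the record).
#' @examples
#' kit <- make_fixture_kit(2)
#' g <- random_genotype(kit, seed = 1)
#' ideal <- process_params(1, 1, 5, 1, 0, 1)
#' epg <- simulate_sample(g, kit, ideal, ce_identity(), target = 8, seed = 1)
#' heterozygote_balance(epg, g)
#' @export
heterozygote_balance <- function(epg, genotype) {
  if (!inherits(epg, "epg")) stop("'epg' must be an epg object", call. = FALSE)
  het <- .het_loci(genotype)
  rows <- lapply(het, function(loc) {
    g <- genotype[genotype$locus == loc, ]
    g <- g[order(g$size_bp), ]
    lmw <- g[1, ]; hmw <- g[2, ]
    pk <- function(a) {
      i <- which(epg$locus == loc & epg$allele == a & !epg$is_stutter &
                 epg$detected)
      if (length(i)) epg$height_rfu[i[1L]] else NA_real_
    }
    s_l <- pk(lmw$allele); s_h <- pk(hmw$allele)
    ok <- !is.na(s_l) && !is.na(s_h)
    data.frame(locus = loc,
               lmw_allele = lmw$allele, hmw_allele = hmw$allele,
               lmw_size = lmw$size_bp, hmw_size = hmw$size_bp,
               lmw_signal = if (ok) s_l else NA_real_,
               hmw_signal = if (ok) s_h else NA_real_,
               hb = if (ok) s_h / s_l else NA_real_,
               status = if (ok) "ok" else "dropout",
               filtered_reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exclude possible stutter-allele pairs
#'
#' When the true partner allele has dropped out, a stutter peak one repeat
#' below a surviving allele can masquerade as the partner.  To guard Hb
#' statistics against this, loci whose two alleles are exactly one repeat
#' unit apart are removed from the calculation.
#'
#' @param records Hb records from [heterozygote_balance()].
#' @param kit The `str_kit` (provides repeat-unit lengths).
#' @return The records with such loci marked `filtered_reason =
#'   "stutter_pair"`.
#' @export
exclude_stutter_pairs <- function(records, kit) {
  if (!nrow(records)) return(records)
  rep_of <- .kit_repeats(kit)
  gap <- records$hmw_size - records$lmw_size
  hit <- records$status == "ok" & is.na(records$filtered_reason) &
    gap == unname(rep_of[records$locus])
  records$filtered_reason[hit] <- "stutter_pair"
  records
}

#' Remove saturated loci
#'
#' Camera saturation compresses tall peaks, so loci whose mean allele peak
#' height exceeds the instrument's saturation point (strictly greater than
#' the threshold; default 10,000 RFU) are removed from Hb calculations.
#'
#' @param records Hb records.
#' @param threshold Saturation threshold in RFU (> 0).
#' @return The records with saturated loci marked `filtered_reason =
#'   "saturation"`.
#' @export
saturation_filter <- function(records, threshold = 10000) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be a single positive number", call. = FALSE)
  if (!nrow(records)) return(records)
  m <- (records$lmw_signal + records$hmw_signal) / 2
  hit <- records$status == "ok" & is.na(records$filtered_reason) &
    !is.na(m) & m > threshold
  records$filtered_reason[hit] <- "saturation"
  records
}

#' Exact Hb distribution for n haploid cells
#'
#' For a heterozygous (a, b) locus sampled as n haploid cells, the a-count
#' follows Binomial(n, 1/2), so the copy-number ratio takes the discrete
#' support k/(n - k).  This enumerates that distribution exactly:
#' `p_balanced` is the probability of perfect balance (ratio 1),
#' `p_accepted` the unconditional probability that the ratio falls in the
#' accepted range (closed interval, default \[0.6, 1.67\]), and the two
#' drop-out atoms k = 0 and k = n (ratios 0/n and n/0, apparent
#' homozygotes) together carry probability `2 * 0.5^n`.
#'
#' @param n Haploid cell count (>= 1).
#' @param accepted_range Closed Hb acceptance interval.
#' @return An `hb_distribution`: the support with probabilities, `n`,
#'   `p_accepted`, `p_balanced`, `p_dropout`.
#' @examples
#' enumerate_haploid_hb(4)  # splits 1/3, 2/2, 3/1: 0.25, 0.375, 0.25
#' enumerate_haploid_hb(8)  # p_accepted 0.711, p_balanced 0.273
#' @export
enumerate_haploid_hb <- function(n, accepted_range = c(0.6, 1.67)) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  k <- 0:n
  prob <- choose(n, k) * 0.5^n  # exact binary fractions for small n
  ratio <- ifelse(k == n & k > 0, Inf, k / (n - k))  # n/0 -> Inf, 0/n -> 0
  support <- data.frame(k = k, n_minus_k = n - k, ratio = ratio, prob = prob)
  dropout <- k == 0L | k == n
  finite <- !dropout
  accepted <- finite & ratio >= accepted_range[1] & ratio <= accepted_range[2]
  structure(list(
    n = n,
    support = support,
    accepted_range = accepted_range,
    p_accepted = sum(prob[accepted]),
    p_balanced = sum(prob[finite & ratio == 1]),
    p_dropout = sum(prob[dropout])),
    class = "hb_distribution")
}

#' @export
print.hb_distribution <- function(x, ...) {
  cat(sprintf("Hb distribution for %d haploid cells\n", x$n))
  cat(sprintf("  P(accepted, %.2f <= Hb <= %.2f) = %.3f\n",
              x$accepted_range[1], x$accepted_range[2], x$p_accepted))
  cat(sprintf("  P(balanced, Hb = 1)            = %.3f\n", x$p_balanced))
  cat(sprintf("  P(drop-out atoms 0/n, n/0)     = %.4g\n", x$p_dropout))
  invisible(x)
}

#' Theoretical balance probabilities over a cell-count grid
#'
#' Convenience wrapper tabulating [enumerate_haploid_hb()] over several
#' haploid cell counts.
#'
#' @param n_values Haploid cell counts.
#' @param accepted_range Closed Hb acceptance interval.
#' @return Data frame: n, p_accepted, p_balanced, p_dropout.
#' @export
haploid_balance_table <- function(n_values = c(2, 4, 8, 16, 32, 64, 128, 256),
                                  accepted_range = c(0.6, 1.67)) {
  out <- do.call(rbind, lapply(n_values, function(n) {
    d <- enumerate_haploid_hb(n, accepted_range)
    data.frame(n = n, p_accepted = d$p_accepted, p_balanced = d$p_balanced,
               p_dropout = d$p_dropout)
  }))
  rownames(out) <- NULL
  out
}

#' Summarise Hb records by condition
#'
#' Per group: counts of scored/dropped/filtered loci, quantiles of Hb
#' (default the 5th and 95th percentiles), the drop-out fraction, the
#' estimated unconditional probability of an accepted ratio (drop-outs stay
#' in the denominator, filtered records are excluded entirely), and the
#' spread of log10(Hb).
#'
#' @param records Hb records with columns `hb`, `status`, and (optionally)
#'   `filtered_reason`, plus any grouping columns.
#' @param by Character vector of grouping column names; `NULL` summarises
#'   the whole table as one group.
#' @param quantiles Probabilities for the reported Hb quantiles.
#' @param accepted_range Closed Hb acceptance interval.
#' @return Data frame, one row per group; groups with no usable records
#'   are reported with `NA` summaries.
#' @export
hb_summary <- function(records, by = NULL, quantiles = c(0.05, 0.95),
                       accepted_range = c(0.6, 1.67)) {
  if (!"filtered_reason" %in% names(records))
    records$filtered_reason <- NA_character_
  grp <- if (is.null(by)) rep("all", nrow(records)) else
    interaction(records[by], drop = TRUE, sep = "|")
  pieces <- split(records, grp)
  out <- do.call(rbind, lapply(names(pieces), function(gname) {
    r <- pieces[[gname]]
    r <- r[is.na(r$filtered_reason), , drop = FALSE]  # filters remove loci
    n_drop <- sum(r$status == "dropout")
    hb <- r$hb[r$status == "ok"]
    n_ok <- length(hb)
    base <- if (is.null(by)) data.frame(group = gname) else {
      key <- r[1, by, drop = FALSE]
      if (!nrow(key)) key <- pieces[[gname]][1, by, drop = FALSE]
      key
    }
    qs <- if (n_ok) stats::quantile(hb, quantiles, names = FALSE) else
      rep(NA_real_, length(quantiles))
    qdf <- as.data.frame(as.list(qs))
    names(qdf) <- sprintf("q%02d", round(100 * quantiles))
    cbind(base, data.frame(
      n_scored = n_ok, n_dropout = n_drop,
      n_filtered = sum(!is.na(pieces[[gname]]$filtered_reason)),
      dropout_frac = if (n_ok + n_drop) n_drop / (n_ok + n_drop) else NA_real_,
      p_accepted = if (n_ok + n_drop)
        sum(hb >= accepted_range[1] & hb <= accepted_range[2]) / (n_ok + n_drop)
        else NA_real_,
      sd_log10_hb = if (n_ok > 1) stats::sd(log10(hb)) else NA_real_),
      qdf)
  }))
  rownames(out) <- NULL
  out
}
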