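# Closed-form degradation mathematics.  DNA degradation is random cleavage
# with a constant per-base-pair probability P(deg); concentration decays
# log-linearly with target fragment length, ln c(x) = ln H + x ln(1 - P(deg)),
# so two concentration measurements at different target lengths (dual-target
# qPCR) identify P(deg).

#' Degradation index from a dual-target qPCR pair
#'
#' The ratio of the small-target to the large-target concentration, the
#' conventional qualitative indicator reported by quantification kits.
#' Unlike the per-base-pair degradation probability it depends on the kit's
#' target lengths.
#'
#' @param c_small,c_large Concentrations (e.g. ng/ul) of the small and
#'   large autosomal targets; vectorised.
#' @return `c_small / c_large`.
#' @examples
#' degradation_index(119.710, 83.6300)  # 1.4
#' @export
degradation_index <- function(c_small, c_large) {
  if (any(c_small <= 0, na.rm = TRUE) || any(c_large <= 0, na.rm = TRUE))
    stop("concentrations must be positive", call. = FALSE)
  c_small / c_large
}

#' Estimate the per-base-pair degradation probability
#'
#' Inverts the log-linear decay model from one dual-target concentration
#' pair: `ln(1 - P(deg)) = (ln c(x2) - ln c(x1)) / (x2 - x1)` with
#' `x1 < x2`, so `P(deg) = 1 - exp[(ln c(x2) - ln c(x1)) / (x2 - x1)]`.
#' The intercept `H = c(x1) / (1 - P(deg))^x1` (the undegraded
#' concentration) is returned alongside.  Because the model is stated in
#' terms of fragment length only, the estimate is kit independent: kits
#' with different target lengths measuring the same extract should agree
#' on P(deg) even though their degradation indices differ.
#'
#' A pair with `c_large > c_small` violates the decay model (it would give
#' a negative probability); the estimate is clamped to 0 with a warning.
#'
#' @param c_small,c_large Concentrations of the small/large target (> 0).
#' @param x_small,x_large Target amplicon lengths in bp, `x_small < x_large`.
#' @return A `degradation_model` list: `p_deg`, `H`, `di`, and the inputs.
#' @examples
#' estimate_p_deg(31.510, 0.0565, 80, 214)   # p_deg ~ 0.0461
#' @export
estimate_p_deg <- function(c_small, c_large, x_small = 80, x_large = 214) {
  for (nm in c("c_small", "c_large", "x_small", "x_large")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop(sprintf("'%s' must be a single number", nm), call. = FALSE)
  }
  if (c_small <= 0 || c_large <= 0)
    stop("concentrations must be positive", call. = FALSE)
  if (x_small >= x_large)
    stop("'x_small' must be smaller than 'x_large'", call. = FALSE)
  p <- 1 - exp((log(c_large) - log(c_small)) / (x_large - x_small))
  if (p < 0) {
    warning("c_large > c_small violates the decay model; p_deg clamped to 0",
            call. = FALSE)
    p <- 0
  }
  structure(list(p_deg = p,
                 H = c_small / (1 - p)^x_small,
                 di = c_small / c_large,
                 c_small = c_small, c_large = c_large,
                 x_small = x_small, x_large = x_large),
            class = "degradation_model")
}

#' @export
print.degradation_model <- function(x, ...) {
  cat(sprintf("degradation model: P(deg) = %.4f per bp  (DI = %.1f, targets %g/%g bp)\n",
              x$p_deg, x$di, x$x_small, x$x_large))
  cat(sprintf("  undegraded concentration H = %.4g\n", x$H))
  invisible(x)
}

#' Predict target concentrations from a degradation model
#'
#' Evaluates the log-linear decay `c(x) = H * (1 - p_deg)^x`; the
#' round-trip companion of [estimate_p_deg()].
#'
#' @param object A `degradation_model`.
#' @param x Fragment lengths in bp.
#' @param ... Unused.
#' @return Predicted concentrations.
#' @export
predict.degradation_model <- function(object, x, ...) {
  object$H * (1 - object$p_deg)^x
}

#' Probability that a fragment of length x is intact
#'
#' Under independent per-base cleavage, a fragment of x bases survives
#' (and so is available for amplification) with probability
#' `(1 - p_deg)^x`; its complement is the single-copy drop-out
#' probability.
#'
#' @param p_deg Per-base-pair degradation probability in \[0, 1);
#'   vectorised.
#' @param x Fragment length in bp (>= 0); vectorised.
#' @return `(1 - p_deg)^x`.
#' @examples
#' p_intact(0.0099, 100)  # ~0.37
#' p_intact(0.0099, 300)  # ~0.05
#' @export
p_intact <- function(p_deg, x) {
  if (any(p_deg < 0 | p_deg >= 1))
    stop("'p_deg' must be in [0, 1)", call. = FALSE)
  if (any(x < 0)) stop("fragment length 'x' must be >= 0", call. = FALSE)
  (1 - p_deg)^x
}

#' Drop-out probability for n copies
#'
#' Given the single-copy drop-out probability, the probability that all of
#' the events of interest occur among n independent copies:
#' `1 - (1 - p_drop1)^n`.
#'
#' @param p_drop1 Single-copy drop-out probability in \[0, 1\].
#' @param n Copy count (>= 0); vectorised.
#' @return `1 - (1 - p_drop1)^n`.
#' @examples
#' p_dropout_n(0.5, 2)  # 0.75
#' @export
p_dropout_n <- function(p_drop1, n) {
  if (any(p_drop1 < 0 | p_drop1 > 1))
    stop("'p_drop1' must be in [0, 1]", call. = FALSE)
  if (any(n < 0)) stop("'n' must be >= 0", call. = FALSE)
  1 - (1 - p_drop1)^n
}

#' Intact-fragment probability curves
#'
#' Tabulates `p_intact` over a fragment-length range for one or more values
#' of the degradation parameter, one series per value.
#'
#' @param p_deg_values Degradation probabilities in \[0, 1).
#' @param x_range Length-2 bp interval.
#' @param step Tabulation step in bp.
#' @return Data frame with columns `p_deg`, `x`, `p_intact`.
#' @export
intact_curve <- function(p_deg_values, x_range = c(0, 500), step = 1) {
  if (any(p_deg_values < 0 | p_deg_values >= 1))
    stop("'p_deg_values' must be in [0, 1)", call. = FALSE)
  x <- seq(x_range[1], x_range[2], by = step)
  out <- do.call(rbind, lapply(p_deg_values, function(p)
    data.frame(p_deg = p, x = x, p_intact = p_intact(p, x))))
  rownames(out) <- NULL
  out
}

#' Cells required in an extract for a target PCR amount
#'
#' The theoretical number of cells needed in the DNA extract, before an
#' aliquot is taken, to place a given average amount of DNA in the PCR
#' reaction: `ceiling(amount_pg / (pg_per_cell * aliquot))`.
#'
#' @param amount_pg Target amount in the PCR reaction (pg); vectorised.
#' @param aliquot Aliquot fraction in (0, 1\].
#' @param pg_per_cell DNA mass per cell in pg (default 6).
#' @return Cell counts, rounded up.
#' @examples
#' cells_required(768, 0.35)  # 366
#' @export
cells_required <- function(amount_pg, aliquot, pg_per_cell = 6) {
  if (any(amount_pg < 0)) stop("'amount_pg' must be >= 0", call. = FALSE)
  if (any(aliquot <= 0 | aliquot > 1))
    stop("'aliquot' must be in (0, 1]", call. = FALSE)
  if (any(pg_per_cell <= 0)) stop("'pg_per_cell' must be > 0", call. = FALSE)
  ceiling(amount_pg / (pg_per_cell * aliquot))
}

#' Cells-required planning grid
#'
#' Cross-tabulates [cells_required()] over PCR target amounts and aliquot
#' fractions.
#'
#' @param amounts PCR target amounts in pg.
#' @param aliquots Aliquot fractions.
#' @param pg_per_cell DNA mass per cell in pg.
#' @return Integer matrix, rows = amounts, columns = aliquots.
#' @export
cells_required_table <- function(amounts = c(6, 12, 24, 48, 96, 192, 384, 768),
                                 aliquots = c(0.05, 0.35, 1.00),
                                 pg_per_cell = 6) {
  m <- outer(amounts, aliquots,
             function(a, q) cells_required(a, q, pg_per_cell))
  dimnames(m) <- list(amount_pg = amounts,
                      aliquot = sprintf("%g%%", 100 * aliquots))
  m
}
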