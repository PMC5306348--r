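# The simulator's state: per-(locus, fragment-identity) molecule counts at
# a named pipeline stage.  A fragment identity is (allele designation,
# is_stutter flag, fragment length in bp); stage transitions never invent
# identities except the stutter positions created during amplification.

.STAGES <- c("sampled", "extracted", "aliquoted", "amplified", "degraded",
             "injected")
.MT_COLS <- c("locus", "allele", "is_stutter", "size_bp", "count")

.new_molecule_table <- function(df, stage) {
  stopifnot(all(.MT_COLS %in% names(df)))
  df <- as.data.frame(df)[.MT_COLS]
  # counts are stored as doubles: PCR yields exceed the integer range long
  # before they exceed exact double representation (2^53)
  df$count <- as.numeric(df$count)
  rownames(df) <- NULL
  structure(df, stage = stage, class = c("molecule_table", "data.frame"))
}

.validate_molecule_table <- function(mt) {
  if (!inherits(mt, "molecule_table"))
    stop("expected a 'molecule_table'", call. = FALSE)
  if (any(mt$count < 0) || any(mt$count != floor(mt$count)))
    stop("molecule counts must be non-negative integers", call. = FALSE)
  invisible(mt)
}

#' Pipeline stage of a molecule table
#'
#' @param mt A `molecule_table`.
#' @return The stage label (one of sampled, extracted, aliquoted, amplified,
#'   degraded, injected).
#' @export
stage <- function(mt) attr(mt, "stage")

#' @export
print.molecule_table <- function(x, ...) {
  cat(sprintf("molecule table [stage: %s] %d fragment identities, %s molecules\n",
              stage(x), nrow(x), format(sum(x$count), big.mark = ",")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Total molecules per locus
#'
#' @param mt A `molecule_table`.
#' @return Named numeric vector of per-locus totals.
#' @export
locus_totals <- function(mt) {
  r <- tapply(mt$count, mt$locus, sum)
  stats::setNames(as.vector(r), names(r))
}
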