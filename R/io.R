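# Delimited-text I/O: EPG peak tables, Hb record tables, and dual-target
# qPCR quantification tables.  All files are comma-separated with a header
# row, UTF-8, '.' decimal - the tabular shape of GeneMapper-style exports.

.EPG_COLS <- c("sample_id", "locus", "allele", "is_stutter", "size_bp",
               "molecules", "height_rfu", "detected")
.QUANT_COLS <- c("sample_id", "kit_label", "c_small", "c_large",
                 "x_small", "x_large")

#' Write or read an EPG peak table
#'
#' @param epgs A stacked EPG data frame (e.g. from [run_simulation()]) or a
#'   single `epg` (a `sample_id` of 1 is added).
#' @param path File path.
#' @return `write_epg_table()` returns `path` invisibly;
#'   `read_epg_table()` the peak data frame.
#' @export
write_epg_table <- function(epgs, path) {
  df <- as.data.frame(epgs)
  if (!"sample_id" %in% names(df)) df$sample_id <- 1L
  missing <- setdiff(.EPG_COLS, names(df))
  if (length(missing))
    stop("EPG table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  utils::write.csv(df[.EPG_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epg_table
#' @export
read_epg_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.EPG_COLS, names(df))
  if (length(missing))
    stop("EPG table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$allele <- as.character(df$allele)
  df$is_stutter <- as.logical(df$is_stutter)
  df$detected <- as.logical(df$detected)
  df[.EPG_COLS]
}

#' Read a dual-target qPCR quantification table
#'
#' Expects columns `sample_id, kit_label, c_small, c_large, x_small,
#' x_large` (concentrations in ng/ul, target amplicon lengths in bp).
#' Malformed rows are reported with their line number.
#'
#' @param path File path.
#' @return Validated data frame of quantification pairs.
#' @seealso [analyze_quant_pairs()]
#' @export
read_quant_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.QUANT_COLS, names(df))
  if (length(missing))
    stop("quant-pair table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    bad <- (!is.na(row$c_small) && row$c_small <= 0) ||
      (!is.na(row$c_large) && row$c_large <= 0) ||
      is.na(row$x_small) || is.na(row$x_large) ||
      row$x_small >= row$x_large
    if (bad)
      stop(sprintf("malformed quant-pair row at line %d (sample %s)",
                   i + 1L, row$sample_id), call. = FALSE)
  }
  df[.QUANT_COLS]
}

#' Degradation estimates for a quantification table
#'
#' Adds the degradation index and the estimated per-base-pair degradation
#' probability to each row of a quant-pair table.  Rows with a missing
#' concentration yield `NA` estimates.
#'
#' @param pairs Data frame from [read_quant_pairs()] (or with the same
#'   columns).
#' @return The table with `di` and `p_deg` columns appended.
#' @export
analyze_quant_pairs <- function(pairs) {
  n <- nrow(pairs)
  di <- rep(NA_real_, n); p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cs <- pairs$c_small[i]; cl <- pairs$c_large[i]
    if (is.na(cs) || is.na(cl)) next
    fit <- estimate_p_deg(cs, cl, pairs$x_small[i], pairs$x_large[i])
    di[i] <- fit$di; p[i] <- fit$p_deg
  }
  pairs$di <- di
  pairs$p_deg <- p
  pairs
}

#' Write Hb records or an experiment manifest
#'
#' `write_hb_table()` writes Hb records as CSV; `write_manifest()` writes
#' the parameter manifest attached to an experiment result as YAML next to
#' the results.
#'
#' @param records Hb records (any data frame).
#' @param x An experiment result carrying a `"manifest"` attribute.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hb_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_hb_table
#' @export
write_manifest <- function(x, path) {
  m <- attr(x, "manifest")
  if (is.null(m)) stop("no manifest attached to 'x'", call. = FALSE)
  yaml::write_yaml(m, path)
  invisible(path)
}
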