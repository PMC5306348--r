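# STR kit/panel definitions: which loci are typed, their dye channel,
# repeat-unit length, and the allele -> fragment-length (bp) map.  All of
# the simulator's length-dependent physics (degradation, stutter position)
# keys off the fragment length; allele designations are opaque labels.

.KIT_COLS <- c("locus", "dye", "repeat_bp", "allele", "size_bp")

.validate_kit <- function(kit) {
  if (!is.data.frame(kit) || !all(.KIT_COLS %in% names(kit)))
    stop("a kit must be a data frame with columns ",
         paste(.KIT_COLS, collapse = ", "), call. = FALSE)
  if (nrow(kit) == 0L) stop("kit has no alleles", call. = FALSE)
  if (any(kit$size_bp <= 0)) stop("fragment lengths must be > 0", call. = FALSE)
  if (any(kit$repeat_bp <= 0)) stop("repeat-unit lengths must be > 0", call. = FALSE)
  if (anyDuplicated(kit[c("locus", "allele")]))
    stop("duplicated (locus, allele) entries in kit", call. = FALSE)
  for (loc in unique(kit$locus)) {
    sub <- kit[kit$locus == loc, ]
    sz <- sort(sub$size_bp)
    if (length(sz) > 1L && any(diff(sz) != sub$repeat_bp[1L]))
      stop(sprintf("locus %s: adjacent alleles must differ by the repeat-unit length (%d bp)",
                   loc, sub$repeat_bp[1L]), call. = FALSE)
  }
  invisible(kit)
}

#' Generate a deterministic ESX17-style fixture kit
#'
#' Builds a synthetic multiplex STR panel with evenly spread fragment sizes,
#' tetranucleotide (4 bp) repeat units by default, and a fixed allele ladder
#' per locus.  The panel emulates the layout of commercial 16/17-locus kits:
#' loci are distributed across dye channels and ordered by fragment size
#' within each dye.
#'
#' @param n_loci Number of loci (>= 1).
#' @param size_range Length-2 numeric, smallest and largest *smallest-allele*
#'   anchor sizes in bp; must lie within \[50, 500\].
#' @param n_alleles Alleles per locus (>= 8 by default).
#' @param repeat_bp Repeat-unit length in bp.
#' @param dyes Dye channel labels cycled over loci.
#' @return A `str_kit` data frame with columns locus, dye, repeat_bp,
#'   allele, size_bp.
#' @examples
#' kit <- make_fixture_kit(16, c(70, 450))
#' range(kit$size_bp)
#' @export
make_fixture_kit <- function(n_loci = 16, size_range = c(70, 450),
                             n_alleles = 10, repeat_bp = 4,
                             dyes = c("B", "G", "Y", "R")) {
  if (!is.numeric(n_loci) || length(n_loci) != 1L || n_loci < 1 ||
      n_loci != floor(n_loci))
    stop("'n_loci' must be a positive integer", call. = FALSE)
  if (!is.numeric(size_range) || length(size_range) != 2L ||
      size_range[1] > size_range[2] ||
      size_range[1] < 50 || size_range[2] > 500)
    stop("'size_range' must be an increasing interval within [50, 500] bp",
         call. = FALSE)
  if (n_alleles < 2) stop("'n_alleles' must be >= 2", call. = FALSE)
  n_loci <- as.integer(n_loci)
  ladder_span <- (n_alleles - 1) * repeat_bp
  dye <- rep(dyes, length.out = n_loci)
  # anchor (smallest-allele) sizes spread evenly across the range; within a
  # dye the loci are consecutive anchors, hence sorted by size
  hi <- max(size_range[1], size_range[2] - ladder_span)
  anchors <- if (n_loci == 1L) size_range[1] else
    round(seq(size_range[1], hi, length.out = n_loci))
  ord <- order(dye, anchors)
  rows <- lapply(seq_len(n_loci), function(i) {
    j <- ord[i]
    data.frame(
      locus = sprintf("STR%02d", i),
      dye = dye[j],
      repeat_bp = repeat_bp,
      allele = as.character(seq(10L, 10L + n_alleles - 1L)),
      size_bp = anchors[j] + repeat_bp * (seq_len(n_alleles) - 1L),
      stringsAsFactors = FALSE)
  })
  kit <- do.call(rbind, rows)
  .validate_kit(kit)
  structure(kit, class = c("str_kit", "data.frame"))
}

#' @export
print.str_kit <- function(x, ...) {
  cat(sprintf("STR kit: %d loci, %d alleles, fragment sizes %d-%d bp\n",
              length(unique(x$locus)), nrow(x),
              min(x$size_bp), max(x$size_bp)))
  agg <- do.call(rbind, lapply(split(x, x$locus), function(s)
    data.frame(locus = s$locus[1], dye = s$dye[1], repeat_bp = s$repeat_bp[1],
               n_alleles = nrow(s), min_bp = min(s$size_bp),
               max_bp = max(s$size_bp))))
  print.data.frame(agg[order(agg$dye, agg$min_bp), ], row.names = FALSE)
  invisible(x)
}

# named vector locus -> repeat-unit length
.kit_repeats <- function(kit) {
  r <- tapply(kit$repeat_bp, kit$locus, `[`, 1L)
  stats::setNames(as.vector(r), names(r))
}

#' Read or write a kit definition table
#'
#' Kits are exchanged as comma-separated text with columns
#' `locus, dye, repeat_bp, allele, size_bp`.
#'
#' @param path File path.
#' @param kit A `str_kit` data frame.
#' @return `read_kit()` returns a validated `str_kit`; `write_kit()` the
#'   path, invisibly.
#' @export
read_kit <- function(path) {
  kit <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.KIT_COLS, names(kit))
  if (length(missing))
    stop("kit file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  kit$allele <- as.character(kit$allele)
  .validate_kit(kit)
  structure(kit[.KIT_COLS], class = c("str_kit", "data.frame"))
}

#' @rdname read_kit
#' @export
write_kit <- function(kit, path) {
  .validate_kit(kit)
  utils::write.csv(as.data.frame(kit)[.KIT_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Draw a random genotype for a kit
#'
#' Samples one allele pair per locus, uniformly over the kit's allele
#' ladder.  Heterozygote-balance statistics are defined only for
#' heterozygous loci, so `heterozygous_only = TRUE` (the default) forces the
#' two designations to differ at every locus.
#'
#' The genotype records the donor's allele pair regardless of ploidy; for
#' haploid material (e.g. sperm) each sampled *cell* later carries only one
#' of the two alleles (see [sample_cells()]).
#'
#' @param kit A `str_kit`.
#' @param heterozygous_only Force two distinct alleles per locus.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param seed Optional integer seed.
#' @return A `str_genotype` data frame (two rows per locus: columns locus,
#'   allele, size_bp) with a `ploidy` attribute.
#' @export
random_genotype <- function(kit, heterozygous_only = TRUE,
                            ploidy = c("diploid", "haploid"), seed = NULL) {
  .validate_kit(kit)
  ploidy <- match.arg(ploidy)
  .seed_rng(seed)
  rows <- lapply(split(kit, kit$locus), function(sub) {
    if (heterozygous_only && nrow(sub) < 2L)
      stop(sprintf("locus %s has < 2 alleles; cannot draw a heterozygote",
                   sub$locus[1]), call. = FALSE)
    idx <- if (heterozygous_only) sample.int(nrow(sub), 2L)
           else sample.int(nrow(sub), 2L, replace = TRUE)
    data.frame(locus = sub$locus[1], allele = sub$allele[idx],
               size_bp = sub$size_bp[idx], stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, rows)
  rownames(g) <- NULL
  structure(g, ploidy = ploidy, class = c("str_genotype", "data.frame"))
}

#' @export
print.str_genotype <- function(x, ...) {
  cat(sprintf("%s genotype, %d loci\n", attr(x, "ploidy"),
              length(unique(x$locus))))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# loci at which the genotype carries two distinct alleles
.het_loci <- function(genotype) {
  tab <- tapply(genotype$allele, genotype$locus,
                function(a) length(unique(a)) == 2L)
  names(tab)[as.vector(tab)]
}
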