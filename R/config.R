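# Structured-text (YAML) run configuration: validated against every module
# precondition before any simulation starts, with explicit defaults
# recorded so a saved config reproduces the run exactly.

.CFG_SECTIONS <- c("process", "ce", "degradation", "sample", "kit",
                   "replicates", "seed")

.cfg_defaults <- function() {
  list(process = list(extraction_efficiency = 0.30, pcr_aliquot = 0.35,
                      pcr_cycles = 28, pcr_efficiency = 0.90,
                      stutter_probability = 0.005, ce_aliquot = 1.0),
       ce = list(preset = "identity", ldt = 0),
       degradation = list(p_deg = 0, pre_pcr = FALSE),
       sample = list(ploidy = "diploid", target = 4, mode = "fixed"),
       kit = list(n_loci = 16, size_min = 70, size_max = 450),
       replicates = 1, seed = 1)
}

.merge_checked <- function(user, defaults, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown key '%s' in config section '%s'",
                 unknown[1], section), call. = FALSE)
  utils::modifyList(defaults, user)
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, fills in explicit defaults for every
#' unset key, and validates each value against the simulator's parameter
#' domains.  Unknown keys are rejected by name; out-of-range values are
#' rejected with the offending key and bound.
#'
#' Recognised sections: `process` (the [process_params()] fields), `ce`
#' (either `preset`: identity / 3500xl / 3130xl plus `ldt`, or the full
#' [ce_params()] fields), `degradation` (`p_deg`, `pre_pcr`), `sample`
#' (`ploidy`, `target`, `mode`), `kit` (`n_loci`, `size_min`, `size_max`,
#' or `path` to a kit table), and top-level `replicates` and `seed`.
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return A `run_config` list with elements `process` ([process_params()]),
#'   `ce` ([ce_params()]), `degradation`, `sample`, `kit` (a `str_kit`),
#'   `replicates`, `seed`, and `raw` (the fully defaulted key set, suitable
#'   for [save_config()]).
#' @export
load_config <- function(path) {
  user <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), .CFG_SECTIONS)
  if (length(unknown))
    stop(sprintf("unknown config key '%s' (known: %s)", unknown[1],
                 paste(.CFG_SECTIONS, collapse = ", ")), call. = FALSE)
  d <- .cfg_defaults()
  kit_def <- d$kit
  if (!is.null(user$kit) && !is.null(user$kit$path))
    kit_def <- list(path = user$kit$path)
  cfg <- list(
    process = .merge_checked(user$process, d$process, "process"),
    ce = .merge_checked(user$ce,
      if (!is.null(user$ce$preset) || is.null(user$ce))
        d$ce else
        list(preset = NULL, threshold_intercept = 0, threshold_slope = 0,
             threshold_sigma = 0, scaling_intercept = 0, scaling_slope = 1,
             scaling_sigma = 0, ldt = 0, identity = FALSE), "ce"),
    degradation = .merge_checked(user$degradation, d$degradation,
                                 "degradation"),
    sample = .merge_checked(user$sample, d$sample, "sample"),
    kit = .merge_checked(user$kit, kit_def, "kit"),
    replicates = if (is.null(user$replicates)) d$replicates else
      user$replicates,
    seed = if (is.null(user$seed)) d$seed else user$seed)

  process <- do.call(process_params, cfg$process)  # validates bounds by key
  ce <- if (!is.null(cfg$ce$preset)) {
    preset <- match.arg(cfg$ce$preset, c("identity", "3500xl", "3130xl"))
    switch(preset,
           identity = ce_identity(ldt = cfg$ce$ldt %||% 0),
           `3500xl` = ce_3500xl(ldt = cfg$ce$ldt %||% 200),
           `3130xl` = ce_3130xl(ldt = cfg$ce$ldt %||% 50))
  } else do.call(ce_params, cfg$ce[setdiff(names(cfg$ce), "preset")])
  if (cfg$degradation$p_deg < 0 || cfg$degradation$p_deg >= 1)
    stop("'degradation.p_deg' must be in [0, 1)", call. = FALSE)
  if (!cfg$sample$ploidy %in% c("diploid", "haploid"))
    stop("'sample.ploidy' must be diploid or haploid", call. = FALSE)
  if (!cfg$sample$mode %in% c("fixed", "poisson"))
    stop("'sample.mode' must be fixed or poisson", call. = FALSE)
  if (cfg$sample$target < 0)
    stop("'sample.target' must be >= 0", call. = FALSE)
  .chk_count(cfg$replicates, "replicates")
  if (cfg$replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  kit <- if (!is.null(cfg$kit$path)) read_kit(cfg$kit$path) else
    make_fixture_kit(cfg$kit$n_loci, c(cfg$kit$size_min, cfg$kit$size_max))

  structure(list(process = process, ce = ce,
                 degradation = cfg$degradation, sample = cfg$sample,
                 kit = kit, replicates = cfg$replicates, seed = cfg$seed,
                 raw = cfg),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Writes the fully defaulted key set of a `run_config` back to YAML;
#' `load_config(save_config(cfg, f))` reproduces the configuration.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (!inherits(config, "run_config"))
    stop("'config' must be a run_config", call. = FALSE)
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run configuration\n")
  print(x$process)
  print(x$ce)
  cat(sprintf("  degradation p_deg = %g (%s-PCR)\n", x$degradation$p_deg,
              if (isTRUE(x$degradation$pre_pcr)) "pre" else "post"))
  cat(sprintf("  sample: %s, target %g cells (%s)\n", x$sample$ploidy,
              x$sample$target, x$sample$mode))
  cat(sprintf("  kit: %d loci; replicates = %d; seed = %d\n",
              length(unique(x$kit$locus)), x$replicates,
              as.integer(x$seed)))
  invisible(x)
}

#' Run the simulation described by a configuration
#'
#' Simulates `replicates` samples under a `run_config` (one random
#' genotype drawn per run) and stacks the resulting EPG peak tables.
#'
#' @param config A `run_config` (or path to one).
#' @return Data frame of peaks with a `sample_id` column; parameter
#'   manifest in `attr(, "manifest")`.
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "run_config")) config <- load_config(config)
  g <- random_genotype(config$kit, ploidy = config$sample$ploidy,
                       seed = derive_seed(config$seed, 0L))
  out <- vector("list", config$replicates)
  for (i in seq_len(config$replicates)) {
    epg <- simulate_sample(g, config$kit, config$process, config$ce,
                           p_deg = config$degradation$p_deg,
                           target = config$sample$target,
                           mode = config$sample$mode,
                           degrade_pre_pcr = isTRUE(config$degradation$pre_pcr),
                           seed = derive_seed(config$seed, i))
    if (nrow(epg)) {
      epg <- as.data.frame(epg)
      epg$sample_id <- i
      out[[i]] <- epg
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(locus = character(), allele = character(),
                      is_stutter = logical(), size_bp = numeric(),
                      molecules = numeric(), height_rfu = numeric(),
                      detected = logical(), sample_id = integer())
  res <- res[c("sample_id", setdiff(names(res), "sample_id"))]
  attr(res, "manifest") <- .manifest("simulate", config$seed,
                                     config$replicates, config$raw)
  res
}
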