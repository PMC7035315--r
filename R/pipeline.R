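#' Run the analysis pipeline end to end
#'
#' Orchestrates the stages in dependency order — synthesize (or load) a
#' genotype fixture, hard-filter and classify sites, polarize derived
#' alleles, and compute the load statistics — writing per-stage TSV
#' outputs plus a machine-readable run manifest (package version, master
#' seed, thresholds, input digests). Each stage consumes only the outputs
#' of earlier stages; a degenerate intermediate (e.g. an empty retained
#' site set) stops the downstream stages with a stage-named error.
#'
#' Per-stage random streams are derived deterministically from the master
#' seed, so the same configuration always reproduces the same output
#' bytes.
#'
#' @param config list (or path to a YAML file) with elements:
#'   `out_dir` (required); `stages` (subset of
#'   `c("synth", "classify", "stats")`, default all); `seed` (master
#'   seed, default 1); `input_dir` (fixture bundle to read when `synth` is
#'   not run); `cohort_spec` (arguments for [cohort_spec()], used by
#'   `synth`); `thresholds` (arguments for [filter_thresholds()]);
#'   `rxy_x`, `rxy_y` (populations contrasted by the stats stage; defaults
#'   to the first two focal populations).
#' @return invisibly, the run manifest as a tibble (also written to
#'   `run_manifest.tsv`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) abort("config error: 'out_dir' is required")
  stages <- config$stages %||% c("synth", "classify", "stats")
  bad <- setdiff(stages, c("synth", "classify", "stats"))
  if (length(bad)) {
    abort(paste0("config error: unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  seed <- as.integer(config$seed %||% 1L)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  note <- c(paste0("seed: ", seed),
            paste0("mutload version: ",
                   as.character(utils::packageVersion("mutload"))))
  th <- do.call(filter_thresholds, config$thresholds %||% list())

  stage_error <- function(stage, msg) {
    abort(paste0("stage '", stage, "': ", msg))
  }

  # --- synth ---------------------------------------------------------
  if ("synth" %in% stages) {
    spec_args <- config$cohort_spec %||% list()
    spec_args$seed <- derive_seed(seed, 101L)
    spec <- do.call(cohort_spec, spec_args)
    cohort <- generate_cohort(spec)
    write_fixture_bundle(cohort, config$out_dir)
    data <- list(genotypes = cohort$genotypes, samples = cohort$samples,
                 annotations = cohort$annotations)
  } else {
    if (is.null(config$input_dir)) {
      stage_error("classify", "no input_dir and synth stage not requested")
    }
    bundle <- read_fixture_bundle(config$input_dir)
    data <- bundle[c("genotypes", "samples", "annotations")]
  }

  # --- classify ------------------------------------------------------
  if ("classify" %in% stages) {
    ann <- data$annotations
    rate <- genotype_rate_filter(data$genotypes, th$genotype_rate_min,
                                 samples = data$samples)
    retained <- retain_for_load_analysis(ann, th)
    pol <- polarize_derived(data$genotypes, data$samples)
    keep <- retained$retained$site_id[
      retained$retained$site_id %in% rate$site_id[rate$passed]]
    if (!length(keep)) stage_error("classify", "empty retained site set")
    site_class <- retained$retained %>%
      filter(site_id %in% keep) %>%
      mutate(impact = as.character(classify_impact(snpeff_category)),
             gerp_class = as.character(classify_conservation(gerp, "GERP")),
             is_control = intergenic == 1) %>%
      left_join(select(pol, site_id, derived_allele), by = "site_id")
    write_tsv_commented(
      select(site_class, chrom, pos, site_id, derived_allele, impact,
             gerp_class, is_control),
      file.path(config$out_dir, "retained_sites.tsv"), note)
    write_tsv_commented(retained$exclusions,
                        file.path(config$out_dir, "exclusion_report.tsv"),
                        note)
    data$site_class <- site_class
    data$polarized <- pol
  }

  # --- stats ---------------------------------------------------------
  if ("stats" %in% stages) {
    if (is.null(data$site_class)) {
      stage_error("stats", "classify stage outputs missing")
    }
    if (!nrow(data$site_class)) stage_error("stats", "empty retained site set")
    keep_ids <- data$site_class$site_id
    idx <- data$genotypes$site_id %in% keep_ids
    genos <- data$genotypes[idx, , drop = FALSE]
    pol <- data$polarized[data$polarized$site_id %in% keep_ids, ]
    cats <- select(data$site_class, site_id, category = "impact", is_control)
    freqs <- derived_freqs(genos, data$samples, pol)
    pops <- unique(filter(data$samples, role == "focal")$population)
    x <- config$rxy_x %||% pops[1]
    y <- config$rxy_y %||% pops[2]

    sfs <- sfs_by_category(genos, data$samples, pol, cats, population = x)
    write_tsv_commented(sfs, file.path(config$out_dir, "sfs.tsv"), note)
    ic <- individual_counts(genos, data$samples, pol, cats)
    write_tsv_commented(ic, file.path(config$out_dir, "individual_counts.tsv"),
                        note)
    if (!is.na(y)) {
      rx <- rxy(freqs, cats, x = x, y = y)
      write_tsv_commented(tidy(rx), file.path(config$out_dir, "rxy.tsv"),
                          note)
    }
    pi_tab <- purrr::map_dfr(pops, function(p) {
      tibble(population = p,
             pi = nucleotide_diversity(genos, data$samples,
                                       sequence_length_bp = nrow(genos),
                                       population = p))
    })
    write_tsv_commented(pi_tab, file.path(config$out_dir, "pi.tsv"), note)
  }

  manifest <- tibble(
    key = c("seed", "stages", "package_version", "thresholds_digest",
            "out_dir"),
    value = c(as.character(seed), paste(stages, collapse = "+"),
              as.character(utils::packageVersion("mutload")),
              paste(unlist(th), collapse = ","), config$out_dir)
  )
  write_tsv_commented(manifest, file.path(config$out_dir, "run_manifest.tsv"),
                      note)
  invisible(manifest)
}
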