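#' Per-individual derived-allele and derived-homozygote counts
#'
#' For every focal individual, counts derived alleles (genotype dosage
#' summed over sites) and derived homozygotes (sites with dosage 2) across
#' the polarized biallelic site set. Sites whose missing rate across the
#' counted individuals exceeds `max_missing_rate` (default 10%) are dropped
#' first; an individual's own missing genotypes are simply not counted.
#' Sites monomorphic in a given population are retained: they contribute
#' zeros and keep the site set identical across populations.
#'
#' @param genotypes a [genotype_table()].
#' @param samples a [sample_manifest()].
#' @param polarized output of [polarize_derived()]; computed if `NULL`.
#' @param categories optional tibble `site_id`, `category` for
#'   per-category counts.
#' @param max_missing_rate maximum per-site missing rate, default 0.1.
#' @return tibble: `individual`, `population`, `category`,
#'   `allele_count`, `homozygote_count`, `n_sites_used` (sites with a
#'   called genotype for that individual).
#' @export
individual_counts <- function(genotypes, samples, polarized = NULL,
                              categories = NULL, max_missing_rate = 0.1) {
  if (is.null(polarized)) polarized <- polarize_derived(genotypes, samples)
  ids <- focal_ids(samples)
  g <- geno_matrix(genotypes, ids)
  known <- polarized$derived_allele != "UNKNOWN"
  miss_ok <- rowMeans(is.na(g)) <= max_missing_rate
  keep <- known & miss_ok
  g <- g[keep, , drop = FALSE]
  site_id <- genotypes$site_id[keep]
  if (is.null(categories)) {
    cat_of <- rep("all", length(site_id))
  } else {
    cat_of <- categories$category[match(site_id, categories$site_id)]
  }
  pop_of <- setNames(samples$population, samples$sample_id)
  purrr::map_dfr(split(seq_along(site_id), cat_of), function(rows) {
    sub <- g[rows, , drop = FALSE]
    tibble(
      individual = colnames(sub),
      population = unname(pop_of[colnames(sub)]),
      allele_count = as.integer(colSums(sub, na.rm = TRUE)),
      homozygote_count = as.integer(colSums(sub == 2L, na.rm = TRUE)),
      n_sites_used = as.integer(colSums(!is.na(sub)))
    )
  }, .id = "category") %>%
    select(individual, population, category, allele_count,
           homozygote_count, n_sites_used)
}

#' Fraction of polymorphic sites per mutation category
#'
#' Among sites polymorphic within a population (derived allele segregating
#' among called genotypes), the fraction belonging to each category — e.g.
#' the percentage of polymorphic sites that segregate a highly deleterious
#' mutation.
#'
#' @param freqs long table from [derived_freqs()].
#' @param categories tibble `site_id`, `category`.
#' @param population population to evaluate.
#' @return tibble: `category`, `n_polymorphic`, `proportion` (fractions
#'   over all categories sum to 1).
#' @export
category_proportions <- function(freqs, categories, population) {
  pop <- population
  poly <- freqs %>%
    filter(.data$population == pop,
           n_called > 0L, n_derived > 0L, n_derived < n_called) %>%
    inner_join(categories, by = "site_id")
  if (!nrow(poly)) abort("no polymorphic sites in population")
  poly %>%
    count(category, name = "n_polymorphic") %>%
    mutate(proportion = .data$n_polymorphic / sum(.data$n_polymorphic))
}
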