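#' Polarize derived alleles against outgroup species
#'
#' Deleterious mutations are assumed to be overwhelmingly derived, so the
#' load statistics operate on derived rather than alternative alleles. At
#' each biallelic site the ALT state is defined as derived iff its
#' frequency is exactly zero across the called genotypes of every outgroup
#' species; a site where ALT segregates in any outgroup, a multiallelic
#' site (comma in ALT), or a site with no called outgroup genotype is
#' polarized `UNKNOWN` and excluded from derived-allele statistics.
#' Under this rule the derived allele is always ALT when known; REF-derived
#' polarization would require an ALT-fixed outgroup and is not attempted.
#'
#' @param genotypes a [genotype_table()] with focal and outgroup samples.
#' @param samples a [sample_manifest()]; must contain outgroup samples.
#' @return tibble: `site_id`, `chrom`, `pos`, `derived_allele`
#'   (`"ALT"`/`"UNKNOWN"`), `n_outgroup_called` (called outgroup alleles).
#' @export
polarize_derived <- function(genotypes, samples) {
  og <- outgroup_ids(samples)
  if (!length(og)) abort("outgroup manifest is empty")
  g <- geno_matrix(genotypes, og)
  alt_count <- rowSums(g, na.rm = TRUE)
  n_called <- 2L * rowSums(!is.na(g))
  multi <- stringr::str_detect(genotypes$alt, ",")
  none_called <- n_called == 0L
  if (any(none_called)) {
    warn(paste0(sum(none_called),
                " site(s) with all outgroup genotypes missing; polarized UNKNOWN"))
  }
  derived <- ifelse(multi | none_called | alt_count > 0, "UNKNOWN", "ALT")
  tibble(site_id = genotypes$site_id, chrom = genotypes$chrom,
         pos = genotypes$pos, derived_allele = derived,
         n_outgroup_called = n_called)
}

#' Per-population derived-allele counts
#'
#' Tallies derived alleles over called genotypes only, per site and focal
#' population, for sites with known derived state. This long table is the
#' input of the site frequency spectrum and Rxy computations.
#'
#' @param genotypes a [genotype_table()].
#' @param samples a [sample_manifest()].
#' @param polarized output of [polarize_derived()]; computed if `NULL`.
#' @return tibble: `site_id`, `chrom`, `pos`, `population`, `n_derived`
#'   (derived allele count), `n_called` (called alleles, 2 x called
#'   individuals). Sites polarized `UNKNOWN` are dropped.
#' @export
derived_freqs <- function(genotypes, samples, polarized = NULL) {
  if (is.null(polarized)) polarized <- polarize_derived(genotypes, samples)
  known <- polarized$derived_allele != "UNKNOWN"
  pops <- unique(filter(samples, role == "focal")$population)
  purrr::map_dfr(pops, function(p) {
    g <- geno_matrix(genotypes, focal_ids(samples, p))[known, , drop = FALSE]
    tibble(
      site_id = genotypes$site_id[known],
      chrom = genotypes$chrom[known],
      pos = genotypes$pos[known],
      population = p,
      n_derived = as.integer(rowSums(g, na.rm = TRUE)),
      n_called = 2L * as.integer(rowSums(!is.na(g)))
    )
  })
}
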