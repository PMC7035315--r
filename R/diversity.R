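#' Nucleotide diversity
#'
#' Per-site unbiased heterozygosity summed over sites and divided by the
#' surveyed sequence length: with `p` the sample ALT frequency among the
#' `n_i` called alleles at site i,
#' \deqn{\pi_i = 2 \hat p_i (1 - \hat p_i) \frac{n_i}{n_i - 1}, \qquad
#'       \pi = \sum_i \pi_i / L}
#' which equals the mean number of pairwise differences per base pair.
#' Sites with fewer than two called alleles contribute nothing.
#'
#' @param genotypes a [genotype_table()].
#' @param samples a [sample_manifest()].
#' @param sequence_length_bp surveyed length `L` in bp (> 0); monomorphic
#'   surveyed positions are implicitly included via `L`.
#' @param population population(s) to include; `NULL` = all focal.
#' @return a single numeric value.
#' @export
nucleotide_diversity <- function(genotypes, samples, sequence_length_bp,
                                 population = NULL) {
  if (!is.numeric(sequence_length_bp) || sequence_length_bp <= 0) {
    abort("sequence_length_bp must be > 0")
  }
  g <- geno_matrix(genotypes, focal_ids(samples, population))
  n_alleles <- 2 * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / n_alleles
  ok <- n_alleles >= 2
  pi_site <- 2 * p[ok] * (1 - p[ok]) * n_alleles[ok] / (n_alleles[ok] - 1)
  sum(pi_site) / sequence_length_bp
}

#' Individual heterozygosity per kilobase
#'
#' Number of heterozygous genotype calls of one individual per kilobase of
#' callable sequence.
#'
#' @param genotypes a [genotype_table()].
#' @param individual sample id.
#' @param callable_length_bp callable sequence length in bp (> 0).
#' @return heterozygous sites per kb.
#' @export
heterozygosity_per_kb <- function(genotypes, individual, callable_length_bp) {
  if (!is.numeric(callable_length_bp) || callable_length_bp <= 0) {
    abort("callable_length_bp must be > 0")
  }
  g <- geno_matrix(genotypes, individual)
  sum(g == 1L, na.rm = TRUE) * 1000 / callable_length_bp
}

#' Downsampling replicates of a statistic
#'
#' Confidence intervals comparable across populations of unequal sample
#' size: draw `k` individuals without replacement from a population
#' (default 4, the smallest cross-species sample size in the study design
#' this emulates), recompute a statistic, repeat.
#'
#' @param genotypes a [genotype_table()].
#' @param samples a [sample_manifest()].
#' @param population population to downsample.
#' @param statistic function `(genotypes, samples) -> numeric(1)` applied
#'   to the downsampled manifest.
#' @param k individuals per replicate (default 4).
#' @param replicates number of replicates (default 100).
#' @param seed integer seed.
#' @return tibble: `replicate`, `value`.
#' @export
downsample_replicates <- function(genotypes, samples, population, statistic,
                                  k = 4, replicates = 100, seed = 1L) {
  ids <- focal_ids(samples, population)
  if (k > length(ids)) abort("k exceeds population sample size")
  set_master_seed(seed)
  vals <- purrr::map_dbl(seq_len(replicates), function(r) {
    pick <- sample(ids, k)
    statistic(genotypes, filter(samples, sample_id %in% pick))
  })
  tibble(replicate = seq_len(replicates), value = vals)
}
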