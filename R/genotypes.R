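#' Build a genotype table
#'
#' The genotype table is the common currency of the empirical pipeline: one
#' row per biallelic SNP, with site metadata columns and a `geno` matrix
#' column holding per-individual derived-ALT dosages (0, 1, 2; `NA` =
#' missing call). Column names of `geno` are sample identifiers matching the
#' sample manifest.
#'
#' @param chrom character vector of chromosome names (opaque strings).
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-base reference / alternative alleles per site.
#' @param geno integer matrix, sites x individuals, entries in `{0,1,2,NA}`,
#'   with column names set to sample ids.
#' @return A tibble with columns `chrom`, `pos`, `site_id`, `ref`, `alt`,
#'   `geno` (matrix column).
#' @export
genotype_table <- function(chrom, pos, ref, alt, geno) {
  stopifnot(is.matrix(geno), nrow(geno) == length(chrom),
            !is.null(colnames(geno)))
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    abort("genotype dosages must be 0, 1, 2 or NA")
  }
  tibble(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    site_id = paste0(chrom, ":", pos),
    ref = as.character(ref),
    alt = as.character(alt),
    geno = geno
  )
}

#' Build a sample manifest
#'
#' Maps each sample column of a genotype table to its population and
#' species, and marks its role in derived-allele polarization: `"focal"`
#' samples enter the load statistics, `"outgroup"` samples define the
#' ancestral state.
#'
#' @param sample_id character vector of sample ids.
#' @param population population label per sample.
#' @param species species label per sample.
#' @param role `"focal"` or `"outgroup"` per sample.
#' @return tibble with columns `sample_id`, `population`, `species`, `role`.
#' @export
sample_manifest <- function(sample_id, population, species, role) {
  role <- as.character(role)
  if (!all(role %in% c("focal", "outgroup"))) {
    abort("role must be 'focal' or 'outgroup'")
  }
  tibble(sample_id = as.character(sample_id),
         population = as.character(population),
         species = as.character(species),
         role = role)
}

# sample ids of a manifest subset; `population` may name one or more
# populations, or NULL for all focal samples
focal_ids <- function(samples, population = NULL) {
  s <- filter(samples, role == "focal")
  if (!is.null(population)) {
    pop <- population
    s <- filter(s, .data$population %in% pop)
  }
  s$sample_id
}

outgroup_ids <- function(samples) {
  filter(samples, role == "outgroup")$sample_id
}

# genotype submatrix for a set of sample ids, keeping site order
geno_matrix <- function(genotypes, ids) {
  missing_ids <- setdiff(ids, colnames(genotypes$geno))
  if (length(missing_ids)) {
    abort(paste0("samples absent from genotype table: ",
                 paste(missing_ids, collapse = ", ")))
  }
  genotypes$geno[, ids, drop = FALSE]
}
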