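#' Hard-filter and retention thresholds
#'
#' Default values follow the hard-filter settings of a GATK-style short
#' variant workflow tuned on genome-wide quality-statistic distributions,
#' plus the downstream retention rules of the load analysis: a 90% minimum
#' per-site genotyping rate, a 3 bp minimum distance to the nearest SNP
#' (guards against multi-nucleotide polymorphisms), expression support
#' FPKM > 0.3 in at least one organ, and GERP > -2 (restricts to
#' high-quality, non-hypervariable chromosomal regions). All printed
#' comparisons are strict: a site fails on `QD < qd_min`, passes at
#' equality, and so on.
#'
#' The total-allele-number cutoff `an_min = 62` is kept as configured in the
#' original workflow; it does not follow from any simple fraction of the
#' focal sample size and should be adapted to the cohort at hand.
#'
#' @param qd_min,fs_max,sor_max,mq_min variant-quality cutoffs
#'   (quality-by-depth, Fisher strand bias, strand odds ratio, RMS mapping
#'   quality).
#' @param mqranksum_abs_max,readposranksum_abs_max absolute bounds on the
#'   rank-sum annotations; sites lacking them (no heterozygous calls) pass.
#' @param an_min minimum total number of called alleles.
#' @param genotype_rate_min minimum fraction of individuals with a called
#'   genotype, in `(0, 1]`.
#' @param min_snp_distance_bp minimum distance to the nearest SNP on the
#'   same chromosome; closer pairs are both removed.
#' @param fpkm_min expression support cutoff (strict `>`).
#' @param gerp_retention_min minimum GERP score retained (strict `>`).
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(qd_min = 2.0, fs_max = 40.0, sor_max = 5.0,
                              mq_min = 20.0, mqranksum_abs_max = 3.0,
                              readposranksum_abs_max = 3.0, an_min = 62L,
                              genotype_rate_min = 0.9,
                              min_snp_distance_bp = 3L,
                              fpkm_min = 0.3, gerp_retention_min = -2.0) {
  th <- list(qd_min = qd_min, fs_max = fs_max, sor_max = sor_max,
             mq_min = mq_min, mqranksum_abs_max = mqranksum_abs_max,
             readposranksum_abs_max = readposranksum_abs_max,
             an_min = an_min, genotype_rate_min = genotype_rate_min,
             min_snp_distance_bp = min_snp_distance_bp,
             fpkm_min = fpkm_min, gerp_retention_min = gerp_retention_min)
  if (!all(vapply(th, is.finite, logical(1)))) {
    abort("all filter thresholds must be finite")
  }
  if (genotype_rate_min <= 0 || genotype_rate_min > 1) {
    abort("genotype_rate_min must be in (0, 1]")
  }
  structure(th, class = "filter_thresholds")
}

#' Apply variant-calling hard filters to a site table
#'
#' A site fails if any condition is met: `QD < qd_min`, `FS > fs_max`,
#' `SOR > sor_max`, `MQ < mq_min`, `|MQRankSum| > mqranksum_abs_max`,
#' `|ReadPosRankSum| > readposranksum_abs_max`, or `AN < an_min`. Missing
#' rank-sum annotations pass (callers omit them at sites without
#' heterozygotes); any other INFO value that fails to parse as a number
#' flags the site with a parse error and excludes it.
#'
#' @param sites tibble with columns `site_id` and the INFO columns `QD`,
#'   `FS`, `SOR`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `AN` (numeric or
#'   character).
#' @param thresholds a [filter_thresholds()].
#' @return tibble: `site_id`, `passed`, logical per-filter fail columns
#'   (`fail_qd`, ..., `fail_parse`). Per-filter fail totals are attached as
#'   attribute `fail_counts`.
#' @export
apply_hard_filters <- function(sites, thresholds = filter_thresholds()) {
  th <- thresholds
  num <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    x[x %in% c(".", "")] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  ranksum_fields <- c("MQRankSum", "ReadPosRankSum")
  parse_bad <- rep(FALSE, nrow(sites))
  val <- list()
  for (f in c("QD", "FS", "SOR", "MQ", "MQRankSum", "ReadPosRankSum", "AN")) {
    raw <- sites[[f]]
    if (is.null(raw)) abort(paste0("INFO column missing: ", f))
    was_absent <- is.na(raw) | (is.character(raw) & raw %in% c(".", ""))
    v <- num(raw)
    # unparseable text is always an error; a genuinely absent value is
    # tolerated only for the rank-sum fields (treated as passing)
    parse_bad <- parse_bad | (is.na(v) & !was_absent)
    if (!f %in% ranksum_fields) parse_bad <- parse_bad | was_absent
    val[[f]] <- v
  }
  na_false <- function(x) !is.na(x) & x
  res <- tibble(
    site_id = sites$site_id,
    fail_qd = na_false(val$QD < th$qd_min),
    fail_fs = na_false(val$FS > th$fs_max),
    fail_sor = na_false(val$SOR > th$sor_max),
    fail_mq = na_false(val$MQ < th$mq_min),
    fail_mqranksum = na_false(abs(val$MQRankSum) > th$mqranksum_abs_max),
    fail_readposranksum = na_false(abs(val$ReadPosRankSum) > th$readposranksum_abs_max),
    fail_an = na_false(val$AN < th$an_min),
    fail_parse = parse_bad
  )
  res$passed <- !Reduce(`|`, res[startsWith(names(res), "fail_")])
  if (any(parse_bad)) {
    warn(paste0(sum(parse_bad), " site(s) excluded with unparseable INFO values"))
  }
  counts <- colSums(res[startsWith(names(res), "fail_")])
  attr(res, "fail_counts") <- counts
  res
}

#' Per-site genotyping-rate filter
#'
#' A site passes iff the fraction of individuals with a called genotype is
#' at least `rate_min` (default 90%).
#'
#' @param genotypes a [genotype_table()].
#' @param rate_min minimum call rate, in `(0, 1]`.
#' @param samples optional manifest; when given, only its samples count
#'   toward the rate.
#' @return tibble: `site_id`, `call_rate`, `passed`.
#' @export
genotype_rate_filter <- function(genotypes, rate_min = 0.9, samples = NULL) {
  g <- genotypes$geno
  if (!is.null(samples)) g <- g[, samples$sample_id, drop = FALSE]
  rate <- rowMeans(!is.na(g))
  tibble(site_id = genotypes$site_id, call_rate = rate,
         passed = rate >= rate_min)
}

#' Remove SNPs closer than a minimum distance
#'
#' A site fails iff its nearest neighboring SNP on the same chromosome lies
#' at a distance below `min_distance_bp`; both members of a too-close pair
#' fail. A site at exactly the minimum distance passes. Single sites on a
#' chromosome have no neighbor and pass.
#'
#' @param sites tibble with columns `chrom`, `pos` (1-based) and `site_id`.
#' @param min_distance_bp minimum |pos_i - pos_j| allowed, default 3.
#' @return tibble: `site_id`, `passed`.
#' @export
mnp_proximity_filter <- function(sites, min_distance_bp = 3L) {
  if (any(vapply(split(sites$pos, sites$chrom), is.unsorted, logical(1)))) {
    warn("positions not sorted within chromosome; sorting internally")
  }
  res <- sites %>%
    select(site_id, chrom, pos) %>%
    group_by(chrom) %>%
    arrange(pos, .by_group = TRUE) %>%
    mutate(
      d_prev = pos - dplyr::lag(pos),
      d_next = dplyr::lead(pos) - pos,
      nearest = pmin(d_prev, d_next, na.rm = TRUE),
      passed = (is.na(d_prev) & is.na(d_next)) | nearest >= min_distance_bp
    ) %>%
    ungroup() %>%
    select(site_id, passed)
  res[match(sites$site_id, res$site_id), ]
}

#' Retain sites for the load analysis
#'
#' Conjunction of the three retention rules applied after variant-level
#' hard filtering: expression support (`max_fpkm > fpkm_min`, strict),
#' conservation-score retention (`gerp > gerp_retention_min`, strict;
#' missing GERP excluded), and the minimum SNP spacing rule. Returns the
#' retained annotated sites together with a per-criterion exclusion tally
#' (a site can be excluded by several criteria at once).
#'
#' @param annotations per-site tibble with `chrom`, `pos`, `max_fpkm`,
#'   `gerp` (as produced by [generate_cohort()] or read from an annotation
#'   TSV).
#' @param thresholds a [filter_thresholds()].
#' @return list with `retained` (annotation rows passing all three rules,
#'   plus `site_id`) and `exclusions` (tibble: `criterion`, `n_excluded`).
#' @export
retain_for_load_analysis <- function(annotations,
                                     thresholds = filter_thresholds()) {
  th <- thresholds
  ann <- mutate(annotations, site_id = paste0(chrom, ":", pos))
  fpkm_ok <- !is.na(ann$max_fpkm) & ann$max_fpkm > th$fpkm_min
  gerp_ok <- !is.na(ann$gerp) & ann$gerp > th$gerp_retention_min
  prox_ok <- mnp_proximity_filter(ann, th$min_snp_distance_bp)$passed
  keep <- fpkm_ok & gerp_ok & prox_ok
  list(
    retained = ann[keep, , drop = FALSE],
    exclusions = tibble(
      criterion = c("fpkm", "gerp", "proximity"),
      n_excluded = c(sum(!fpkm_ok), sum(!gerp_ok), sum(!prox_ok))
    )
  )
}
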