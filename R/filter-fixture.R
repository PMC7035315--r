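#' Generate a hard-filter test fixture
#'
#' Produces a site table carrying the INFO annotations used by the
#' variant-calling hard filter (`QD`, `FS`, `SOR`, `MQ`, `MQRankSum`,
#' `ReadPosRankSum`, `AN`) such that exactly
#' `round(n_sites * fraction_failing)` sites violate at least one default
#' threshold, each in one or more randomly chosen fields. The remaining
#' sites sit safely inside every threshold; a random subset of passing
#' sites has missing rank-sum annotations, which callers emit only for
#' sites with heterozygous genotypes and which the filter must treat as
#' passing.
#'
#' @param n_sites number of sites.
#' @param fraction_failing fraction of sites planted to fail, in `[0, 1]`.
#' @param seed integer seed.
#' @param thresholds a [filter_thresholds()] object the plant is calibrated
#'   against.
#' @return list with `sites` (tibble: `chrom`, `pos`, `ref`, `alt` and the
#'   seven INFO columns) and `truth_fail` (character vector of failing
#'   `site_id`s).
#' @export
generate_filter_fixture <- function(n_sites, fraction_failing, seed = 1L,
                                    thresholds = filter_thresholds()) {
  if (!is.finite(fraction_failing) || fraction_failing < 0 || fraction_failing > 1) {
    abort("fraction_failing must be in [0, 1]")
  }
  stopifnot(n_sites >= 1)
  set_master_seed(seed)
  th <- thresholds

  n_fail <- round(n_sites * fraction_failing)
  fail_idx <- sort(sample.int(n_sites, n_fail))

  sites <- tibble(
    chrom = "chr1",
    pos = seq_len(n_sites) * 100L,
    ref = "A", alt = "T",
    QD = runif(n_sites, th$qd_min + 1, 30),
    FS = runif(n_sites, 0, th$fs_max - 5),
    SOR = runif(n_sites, 0.5, th$sor_max - 1),
    MQ = runif(n_sites, th$mq_min + 10, 60),
    MQRankSum = runif(n_sites, -th$mqranksum_abs_max + 1, th$mqranksum_abs_max - 1),
    ReadPosRankSum = runif(n_sites, -th$readposranksum_abs_max + 1,
                           th$readposranksum_abs_max - 1),
    AN = sample(seq(th$an_min, th$an_min + 16L), n_sites, replace = TRUE)
  ) %>% mutate(site_id = paste0(chrom, ":", pos))

  # rank-sum fields genuinely absent at some passing sites
  pass_idx <- setdiff(seq_len(n_sites), fail_idx)
  absent <- pass_idx[runif(length(pass_idx)) < 0.1]
  sites$MQRankSum[absent] <- NA_real_
  sites$ReadPosRankSum[absent] <- NA_real_

  fields <- c("QD", "FS", "SOR", "MQ", "MQRankSum", "ReadPosRankSum", "AN")
  for (i in fail_idx) {
    k <- sample(1:2, 1)
    for (f in sample(fields, k)) {
      sites[[f]][i] <- switch(
        f,
        QD = runif(1, 0, th$qd_min * 0.95),
        FS = runif(1, th$fs_max * 1.05, th$fs_max * 2),
        SOR = runif(1, th$sor_max * 1.05, th$sor_max * 2),
        MQ = runif(1, 0, th$mq_min * 0.95),
        MQRankSum = sample(c(-1, 1), 1) * runif(1, th$mqranksum_abs_max * 1.05, 6),
        ReadPosRankSum = sample(c(-1, 1), 1) * runif(1, th$readposranksum_abs_max * 1.05, 6),
        AN = sample.int(th$an_min - 1L, 1)
      )
    }
  }

  list(sites = select(sites, chrom, pos, site_id, ref, alt,
                      "QD", "FS", "SOR", "MQ", "MQRankSum",
                      "ReadPosRankSum", "AN"),
       truth_fail = sites$site_id[fail_idx])
}
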