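#' Parameters of the window-based ROH scan
#'
#' Defaults reproduce a PLINK-style sliding-window scan: 100-SNP windows
#' tolerating at most 2 heterozygous and 5 missing calls; a SNP belongs to
#' a homozygous segment if at least `window_threshold` of the windows
#' spanning it are homozygous; qualifying runs are reported when they hold
#' at least `min_snp` SNPs, span at least `min_kb` kb, average at most
#' `max_density_kb_per_snp` kb per SNP, and contain no gap between
#' consecutive SNPs larger than `max_gap_kb` kb.
#'
#' The window threshold ships at 0.05, the scanning tool's own default; it
#' is exposed because printed workflows occasionally garble this value.
#'
#' @param window_snp SNPs per sliding window.
#' @param window_het maximum heterozygous calls per homozygous window.
#' @param window_missing maximum missing calls per homozygous window.
#' @param window_threshold minimum fraction of spanning windows that are
#'   homozygous for a SNP to qualify.
#' @param min_snp minimum SNPs per reported ROH.
#' @param min_kb minimum ROH length (kb).
#' @param max_density_kb_per_snp maximum average spacing (kb per SNP).
#' @param max_gap_kb maximum gap between consecutive SNPs inside an ROH
#'   (kb).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 100, window_het = 2, window_missing = 5,
                       window_threshold = 0.05, min_snp = 100, min_kb = 500,
                       max_density_kb_per_snp = 10, max_gap_kb = 100) {
  structure(list(window_snp = window_snp, window_het = window_het,
                 window_missing = window_missing,
                 window_threshold = window_threshold, min_snp = min_snp,
                 min_kb = min_kb,
                 max_density_kb_per_snp = max_density_kb_per_snp,
                 max_gap_kb = max_gap_kb),
            class = "roh_params")
}

# windowed sums of a logical vector, window length w
win_sums <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

#' Scan one individual for runs of homozygosity
#'
#' Sliding-window ROH detection on the genotype vector of one individual
#' (see [roh_params()] for the algorithm). Positions must be sorted within
#' chromosome. Chromosomes with fewer SNPs than the window size yield no
#' calls and are reported via a message.
#'
#' @param genotypes a [genotype_table()].
#' @param individual sample id to scan.
#' @param params a [roh_params()].
#' @return tibble: `chrom`, `start`, `end` (1-based inclusive bp of the
#'   first and last SNP in the run), `length_bp`, `n_snps`.
#' @export
roh_scan <- function(genotypes, individual, params = roh_params()) {
  g <- as.vector(geno_matrix(genotypes, individual))
  df <- tibble(chrom = genotypes$chrom, pos = genotypes$pos, g = g)
  out <- purrr::map_dfr(split(df, df$chrom), function(d) {
    d <- arrange(d, pos)
    roh_scan_chrom(d$pos, d$g, params, d$chrom[1])
  })
  if (nrow(out)) arrange(out, chrom, start) else out
}

roh_scan_chrom <- function(pos, g, p, chrom_name) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  length_bp = integer(), n_snps = integer())
  n <- length(pos)
  if (n < p$window_snp) {
    inform(paste0("chromosome ", chrom_name, ": fewer SNPs (", n,
                  ") than window size; no ROH called"))
    return(empty)
  }
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  w <- p$window_snp
  hom_win <- win_sums(het, w) <= p$window_het & win_sums(mis, w) <= p$window_missing
  # for SNP i, spanning windows are max(1, i-w+1) .. min(i, n-w+1)
  nw <- n - w + 1
  cs <- c(0, cumsum(hom_win))
  lo <- pmax(1L, seq_len(n) - w + 1L)
  hi <- pmin(seq_len(n), nw)
  n_span <- hi - lo + 1L
  n_hom <- cs[hi + 1L] - cs[lo]
  qual <- n_hom / n_span >= p$window_threshold

  # maximal runs of qualifying SNPs, split at large gaps
  idx <- which(qual)
  if (!length(idx)) return(empty)
  gap_break <- c(FALSE, diff(idx) > 1 |
                   diff(pos[idx]) > p$max_gap_kb * 1000)
  run_id <- cumsum(gap_break)
  purrr::map_dfr(split(idx, run_id), function(run) {
    len <- pos[run[length(run)]] - pos[run[1]] + 1L
    ns <- length(run)
    if (ns >= p$min_snp && len >= p$min_kb * 1000 &&
        len / ns <= p$max_density_kb_per_snp * 1000) {
      tibble(chrom = chrom_name, start = pos[run[1]],
             end = pos[run[length(run)]], length_bp = len, n_snps = ns)
    } else {
      NULL
    }
  })
}

#' Genome fraction in long runs of homozygosity
#'
#' `F_ROH`: the fraction of the genome covered by ROH at least
#' `min_length_bp` long (default 2.5 Mb, which restricts to recent
#' inbreeding). Overlapping intervals on a chromosome are merged first.
#'
#' @param roh tibble from [roh_scan()].
#' @param genome_length_bp total genome length (> 0).
#' @param min_length_bp minimum ROH length counted, default 2,500,000.
#' @return fraction in `[0, 1]`.
#' @export
f_roh <- function(roh, genome_length_bp, min_length_bp = 2.5e6) {
  if (!is.numeric(genome_length_bp) || genome_length_bp <= 0) {
    abort("genome_length_bp must be > 0")
  }
  if (!nrow(roh)) return(0)
  merged <- roh %>%
    group_by(chrom) %>%
    arrange(start, .by_group = TRUE) %>%
    mutate(grp = cumsum(start > dplyr::lag(cummax(end), default = -Inf) + 1)) %>%
    group_by(chrom, .data$grp) %>%
    summarise(start = min(start), end = max(end), .groups = "drop") %>%
    mutate(length_bp = end - start + 1)
  sum(merged$length_bp[merged$length_bp >= min_length_bp]) / genome_length_bp
}
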