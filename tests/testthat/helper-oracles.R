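# Independent brute-force oracles used to cross-check the package's
# vectorized implementations. These are deliberately written in the most
# literal way possible (explicit loops, no shared code with R/).

# naive O(n * w) ROH scan: for every window, count hets/missing by looping;
# for every SNP, loop over spanning windows; then walk runs left to right.
oracle_roh_chrom <- function(pos, g, p) {
  n <- length(pos)
  w <- p$window_snp
  if (n < w) return(NULL)
  nw <- n - w + 1
  hom_win <- logical(nw)
  for (i in seq_len(nw)) {
    win <- g[i:(i + w - 1)]
    hom_win[i] <- sum(win == 1L, na.rm = TRUE) <= p$window_het &&
      sum(is.na(win)) <= p$window_missing
  }
  qual <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - w + 1)
    hi <- min(i, nw)
    span <- hom_win[lo:hi]
    qual[i] <- mean(span) >= p$window_threshold
  }
  out <- list()
  run <- integer(0)
  flush <- function(run) {
    if (!length(run)) return(NULL)
    len <- pos[run[length(run)]] - pos[run[1]] + 1L
    if (length(run) >= p$min_snp && len >= p$min_kb * 1000 &&
        len / length(run) <= p$max_density_kb_per_snp * 1000) {
      data.frame(start = pos[run[1]], end = pos[run[length(run)]],
                 length_bp = len, n_snps = length(run))
    } else NULL
  }
  for (i in seq_len(n)) {
    if (qual[i]) {
      if (length(run) &&
          (i - run[length(run)] > 1 ||
           pos[i] - pos[run[length(run)]] > p$max_gap_kb * 1000)) {
        out[[length(out) + 1]] <- flush(run)
        run <- integer(0)
      }
      run <- c(run, i)
    } else {
      out[[length(out) + 1]] <- flush(run)
      run <- integer(0)
    }
  }
  out[[length(out) + 1]] <- flush(run)
  do.call(rbind, out)
}

# minimal neutral Wright-Fisher oracle: per-locus binomial resampling of
# allele counts in a population of N diploids, with symmetric-rate mutation
# applied to the allele frequency each generation.
oracle_wf_counts <- function(n_loci, N, mu, back_mu, generations, p0 = 0) {
  counts <- rbinom(n_loci, 2 * N, p0)
  for (g in seq_len(generations)) {
    p <- counts / (2 * N)
    p <- p * (1 - back_mu) + (1 - p) * mu
    counts <- rbinom(n_loci, 2 * N, p)
  }
  counts
}

# tiny genotype fixture builder used across test files
make_geno <- function(dosages, chrom = NULL, pos = NULL, prefix = "s") {
  m <- as.matrix(dosages)
  storage.mode(m) <- "integer"
  colnames(m) <- paste0(prefix, seq_len(ncol(m)))
  genotype_table(
    chrom %||% rep("chr1", nrow(m)),
    pos %||% (seq_len(nrow(m)) * 100L),
    rep("A", nrow(m)), rep("T", nrow(m)), m
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
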