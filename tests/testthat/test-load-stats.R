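# a small fully-called manifest: 3 focal diploids + 1 ancestral outgroup
three_ind <- function(dosages) {
  g <- make_geno(cbind(dosages, 0L))
  sm <- sample_manifest(paste0("s", 1:4), c(rep("p1", 3), "og"),
                        c(rep("sp", 3), "og"),
                        c(rep("focal", 3), "outgroup"))
  list(g = g, sm = sm)
}

test_that("SFS equals the brute-force tally of derived allele counts", {
  fx <- three_ind(rbind(c(1L, 0L, 0L), c(2L, 1L, 0L)))
  sfs <- sfs_by_category(fx$g, fx$sm)
  # site A has count 1, site B count 3; spectrum over 1..5 = [1,0,1,0,0]
  expect_equal(attr(sfs, "n"), 3L)
  expect_equal(sfs$count, c(1, 3))
  expect_equal(sfs$n_sites, c(1L, 1L))

  # fixed-derived sites are not segregating
  fixed <- three_ind(rbind(c(2L, 2L, 2L)))
  expect_equal(nrow(sfs_by_category(fixed$g, fixed$sm)), 0L)
})

test_that("SFS on a random cohort equals an exhaustive per-site tally", {
  spec <- cohort_spec(n_sites_per_category = c(modifier = 150, low = 50,
                                               moderate = 50, high = 50,
                                               intergenic = 100),
                      n_individuals_per_population = c(a = 8, b = 4),
                      missing_rate = 0.05, seed = 17)
  co <- generate_cohort(spec)
  cats <- co$truth %>% dplyr::distinct(site_id, category)
  sfs <- sfs_by_category(co$genotypes, co$samples, categories = cats,
                         population = "a")
  # oracle: loop over sites of population a with no missing call
  ids <- co$samples$sample_id[co$samples$population == "a"]
  g <- co$genotypes$geno[, ids]
  oracle <- table(unlist(lapply(seq_len(nrow(g)), function(i) {
    row <- g[i, ]
    if (any(is.na(row))) return(NULL)
    dac <- sum(row)
    if (dac == 0 || dac == 16) return(NULL)
    dac
  })))
  got <- sfs %>% dplyr::group_by(count) %>%
    dplyr::summarise(n = sum(n_sites))
  expect_equal(got$n, as.integer(oracle[as.character(got$count)]),
               ignore_attr = TRUE)
  expect_equal(sum(sfs$n_sites), sum(oracle))
})

test_that("binned SFS tail reports mean sites per count value in each interval", {
  sfs <- structure(
    tibble::tibble(category = "all", count = c(12, 14), n_sites = c(1L, 1L)),
    n = 15L, class = c("sfs_tbl", "tbl_df", "tbl", "data.frame"))
  b <- sfs_bin_tail(sfs, max_single = 10, interval_width = 5)
  # one interval (10,15] holding 2 sites across 5 count values
  expect_equal(nrow(b), 1L)
  expect_equal(b$mean_sites, 2 / 5)
})

test_that("individual counts equal an exhaustive per-site tally and honour the 10% rule", {
  fx <- three_ind(rbind(c(1L, 0L, 0L), c(1L, 2L, 0L), c(0L, 0L, 0L)))
  ic <- individual_counts(fx$g, fx$sm)
  expect_equal(ic$allele_count[ic$individual == "s1"], 2L)
  expect_equal(ic$homozygote_count[ic$individual == "s1"], 0L)
  expect_equal(ic$allele_count[ic$individual == "s2"], 2L)
  expect_equal(ic$homozygote_count[ic$individual == "s2"], 1L)
  expect_equal(ic$allele_count[ic$individual == "s3"], 0L)

  # 10-site fixture with planted genotypes vs brute-force oracle
  set.seed(99)
  dos <- matrix(sample(c(0L, 1L, 2L, NA), 10 * 6, replace = TRUE,
                       prob = c(.5, .25, .15, .1)), 10, 6)
  g <- make_geno(cbind(dos, matrix(0L, 10, 2)))
  sm <- sample_manifest(paste0("s", 1:8), c(rep("p", 6), "og", "og"),
                        c(rep("sp", 6), "og", "og"),
                        c(rep("focal", 6), "outgroup", "outgroup"))
  ic2 <- individual_counts(g, sm, max_missing_rate = 0.5)
  keep <- rowMeans(is.na(dos)) <= 0.5
  for (j in 1:6) {
    col <- dos[keep, j]
    expect_equal(ic2$allele_count[ic2$individual == paste0("s", j)],
                 sum(col, na.rm = TRUE))
    expect_equal(ic2$homozygote_count[ic2$individual == paste0("s", j)],
                 sum(col == 2L, na.rm = TRUE))
    expect_equal(ic2$n_sites_used[ic2$individual == paste0("s", j)],
                 sum(!is.na(col)))
  }
  # with the strict 10% rule every site containing any NA among 6 samples drops
  ic3 <- individual_counts(g, sm, max_missing_rate = 0.1)
  keep3 <- rowMeans(is.na(dos)) <= 0.1
  expect_equal(unique(ic3$n_sites_used), sum(keep3))
})

test_that("Rxy reproduces the worked ratio, its reciprocal, and unity under symmetry", {
  freqs <- dplyr::bind_rows(
    tibble::tibble(site_id = c("s1", "s2"), chrom = "c1", pos = 1:2,
                   population = "X", n_derived = c(1L, 5L), n_called = 10L),
    tibble::tibble(site_id = c("s1", "s2"), chrom = "c1", pos = 1:2,
                   population = "Y", n_derived = c(5L, 5L), n_called = 10L))
  cats <- tibble::tibble(site_id = c("s1", "s2"),
                         category = c("high", "ctrl"),
                         is_control = c(FALSE, TRUE))
  rx <- rxy(freqs, cats, "X", "Y", jackknife = FALSE)
  expect_equal(rx$rxy, (0.1 * 0.5) / (0.5 * 0.9), tolerance = 1e-12)
  expect_equal(rx$rxy, 0.1111, tolerance = 1e-3)
  ryx <- rxy(freqs, cats, "Y", "X", jackknife = FALSE)
  expect_equal(ryx$rxy, 9, tolerance = 1e-12)
  expect_equal(rx$rxy * ryx$rxy, 1, tolerance = 1e-12)

  # identical frequencies in X and Y at every site -> Rxy = 1
  sym <- dplyr::bind_rows(
    tibble::tibble(site_id = paste0("s", 1:4), chrom = "c1", pos = 1:4,
                   population = "X", n_derived = c(1L, 3L, 2L, 4L), n_called = 10L),
    tibble::tibble(site_id = paste0("s", 1:4), chrom = "c1", pos = 1:4,
                   population = "Y", n_derived = c(1L, 3L, 2L, 4L), n_called = 10L))
  scats <- tibble::tibble(site_id = paste0("s", 1:4),
                          category = c("high", "high", "ctrl", "ctrl"),
                          is_control = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(rxy(sym, scats, "X", "Y", jackknife = FALSE)$rxy, 1)
})

test_that("Rxy errors when the control set carries no derived alleles", {
  freqs <- dplyr::bind_rows(
    tibble::tibble(site_id = c("s1", "s2"), chrom = "c1", pos = 1:2,
                   population = "X", n_derived = c(1L, 0L), n_called = 10L),
    tibble::tibble(site_id = c("s1", "s2"), chrom = "c1", pos = 1:2,
                   population = "Y", n_derived = c(5L, 0L), n_called = 10L))
  cats <- tibble::tibble(site_id = c("s1", "s2"),
                         category = c("high", "ctrl"),
                         is_control = c(FALSE, TRUE))
  expect_error(rxy(freqs, cats, "X", "Y"), "control")
})

test_that("jackknife pseudovalues match leave-one-block recomputation", {
  # two blocks with hand-computable sums
  freqs <- dplyr::bind_rows(
    tibble::tibble(site_id = paste0("s", 1:4),
                   chrom = c("c1", "c1", "c2", "c2"), pos = 1:4,
                   population = "X", n_derived = c(1L, 2L, 3L, 1L), n_called = 10L),
    tibble::tibble(site_id = paste0("s", 1:4),
                   chrom = c("c1", "c1", "c2", "c2"), pos = 1:4,
                   population = "Y", n_derived = c(2L, 2L, 1L, 1L), n_called = 10L))
  cats <- tibble::tibble(site_id = paste0("s", 1:4),
                         category = c("high", "ctrl", "high", "ctrl"),
                         is_control = c(FALSE, TRUE, FALSE, TRUE))
  pv <- jackknife_rxy(freqs, cats, "X", "Y")
  expect_equal(nrow(pv), 2L)
  manual <- function(keep) {
    f <- freqs %>% dplyr::filter(chrom %in% keep)
    rxy(f, cats, "X", "Y", jackknife = FALSE)$rxy
  }
  expect_equal(pv$pseudovalue[pv$block == "c1"], manual("c2"))
  expect_equal(pv$pseudovalue[pv$block == "c2"], manual("c1"))

  # homogeneous blocks: every pseudovalue equals the full estimate
  hom <- dplyr::bind_rows(freqs, freqs %>%
    dplyr::mutate(site_id = paste0(site_id, "b"),
                  chrom = paste0(chrom, "b")))
  hcats <- dplyr::bind_rows(cats, cats %>%
    dplyr::mutate(site_id = paste0(site_id, "b")))
  # make the two blocks identical in composition
  hom2 <- hom %>% dplyr::filter(chrom %in% c("c1", "c1b"))
  hc2 <- hcats %>% dplyr::filter(site_id %in% hom2$site_id)
  full <- rxy(hom2, hc2, "X", "Y", jackknife = FALSE)$rxy
  pv2 <- jackknife_rxy(hom2, hc2, "X", "Y")
  expect_equal(pv2$pseudovalue, rep(full, 2))
})

test_that("nucleotide diversity matches pairwise-difference arithmetic and scales with length", {
  g <- make_geno(matrix(c(0L, 2L, 0L), nrow = 1))
  sm <- sample_manifest(paste0("s", 1:3), c("p", "p", "og"),
                        c("sp", "sp", "og"), c("focal", "focal", "outgroup"))
  # two diploids 0/0 and 1/1: 4 of 6 allele pairs differ -> 2/3
  expect_equal(nucleotide_diversity(g, sm, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(nucleotide_diversity(g, sm, 2), 1 / 3, tolerance = 1e-12)
  mono <- make_geno(matrix(c(0L, 0L, 0L), nrow = 1))
  expect_equal(nucleotide_diversity(mono, sm, 1), 0)
  expect_error(nucleotide_diversity(g, sm, 0), "sequence_length_bp")
})

test_that("pi converges to the Beta-model expectation", {
  # E[pi per site] = 2 E[p(1-p)] exactly (the n/(n-1) factor unbiases the
  # sample heterozygosity); for Beta(0.5, 2): E[p] = 0.2, Var = 0.0457
  spec <- cohort_spec(n_individuals_per_population = c(a = 10),
                      n_sites_per_category = c(modifier = 4000, low = 10,
                                               moderate = 10, high = 10,
                                               intergenic = 4000),
                      derived_frequency_distributions = list(
                        modifier = c(0.5, 2), low = c(0.5, 2),
                        moderate = c(0.5, 2), high = c(0.5, 2),
                        intergenic = c(0.5, 2)),
                      missing_rate = 0, seed = 23)
  co <- generate_cohort(spec)
  n_sites <- nrow(co$genotypes)
  pi_hat <- nucleotide_diversity(co$genotypes, co$samples, n_sites)
  m <- 0.5 / 2.5
  v <- 0.5 * 2 / (2.5^2 * 3.5)
  expected <- 2 * (m - m^2 - v)
  # 3 SE via the empirical per-site spread
  g <- co$genotypes$geno[, co$samples$sample_id[co$samples$role == "focal"]]
  p <- rowMeans(g) / 2
  per_site <- 2 * p * (1 - p) * 20 / 19
  se <- stats::sd(per_site) / sqrt(n_sites)
  expect_lt(abs(pi_hat - expected), 3 * se)
})

test_that("individual heterozygosity per kb is exact arithmetic", {
  g <- make_geno(matrix(c(rep(1L, 5), rep(0L, 5)), ncol = 1))
  expect_equal(heterozygosity_per_kb(g, "s1", 10000), 0.5)
  expect_equal(heterozygosity_per_kb(g, "s1", 20000), 0.25)
  hom <- make_geno(matrix(c(0L, 2L), ncol = 1))
  expect_equal(heterozygosity_per_kb(hom, "s1", 1000), 0)
})

test_that("downsampling replicates are reproducible and unbiased for pi", {
  spec <- cohort_spec(n_individuals_per_population = c(a = 12),
                      n_sites_per_category = c(modifier = 800, low = 10,
                                               moderate = 10, high = 10,
                                               intergenic = 800),
                      missing_rate = 0, seed = 29)
  co <- generate_cohort(spec)
  L <- nrow(co$genotypes)
  stat <- function(g, sm) nucleotide_diversity(g, sm, L)
  r1 <- downsample_replicates(co$genotypes, co$samples, "a", stat,
                              k = 4, replicates = 40, seed = 7)
  r2 <- downsample_replicates(co$genotypes, co$samples, "a", stat,
                              k = 4, replicates = 40, seed = 7)
  expect_identical(r1, r2)
  full <- stat(co$genotypes, co$samples)
  se <- stats::sd(r1$value) / sqrt(nrow(r1))
  expect_lt(abs(mean(r1$value) - full), 3 * se)
  expect_error(downsample_replicates(co$genotypes, co$samples, "a", stat,
                                     k = 13, replicates = 2, seed = 1),
               "exceeds")
  # population of exactly k: every replicate identical
  sm4 <- co$samples[c(1:4, which(co$samples$role == "outgroup")), ]
  r3 <- downsample_replicates(co$genotypes, sm4, "a", stat,
                              k = 4, replicates = 5, seed = 3)
  expect_equal(length(unique(r3$value)), 1L)
})

test_that("category proportions partition the polymorphic site set", {
  spec <- cohort_spec(n_sites_per_category = c(modifier = 200, low = 60,
                                               moderate = 60, high = 30,
                                               intergenic = 150),
                      seed = 37)
  co <- generate_cohort(spec)
  freqs <- derived_freqs(co$genotypes, co$samples)
  cats <- co$truth %>% dplyr::distinct(site_id, category)
  pr <- category_proportions(freqs, cats, "alpine")
  expect_equal(sum(pr$proportion), 1)
  expect_true(all(pr$n_polymorphic >= 0))
  # arithmetic: single HIGH among 100 polymorphic would be 1%
  toy <- tibble::tibble(site_id = paste0("t", 1:100), chrom = "c1",
                        pos = 1:100, population = "p",
                        n_derived = rep(1L, 100), n_called = 10L)
  tcats <- tibble::tibble(site_id = paste0("t", 1:100),
                          category = c("high", rep("modifier", 99)))
  tpr <- category_proportions(toy, tcats, "p")
  expect_equal(tpr$proportion[tpr$category == "high"], 0.01)
})
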