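# Internal genome representation: per patch two integer matrices A and B
# (individuals x loci, entries 0 = ancestral, 1 = derived allele) holding
# the maternally and paternally inherited allele, a logical `female`
# vector, a carrying capacity K and an `extinct` flag. Loci are globally
# described by the `loci` tibble (locus, type, s, h); the first
# n_deleterious loci are under selection, the rest neutral (s = 0).

new_patch <- function(A, B, female, K, extinct = FALSE) {
  list(A = A, B = B, female = female, K = K, extinct = extinct)
}

patch_size <- function(p) if (p$extinct) 0L else nrow(p$A)

#' Multiplicative (or additive) fitness of diploid genotypes
#'
#' Per-locus contributions `1 - h s` for heterozygotes and `1 - s` for
#' derived homozygotes, combined multiplicatively across deleterious loci
#' (or subtracted from 1 under the additive model). Neutral loci
#' contribute nothing. Fitness is truncated below at 0, so a homozygous
#' lethal yields `w = 0`.
#'
#' @param dosage integer matrix (individuals x deleterious loci) of
#'   derived-allele dosages 0/1/2, or a single individual's vector.
#' @param s,h per-locus selection and dominance coefficients.
#' @param model `"multiplicative"` or `"additive"`.
#' @return numeric vector of fitness values, one per individual.
#' @export
genotype_fitness <- function(dosage, s, h, model = c("multiplicative", "additive")) {
  model <- match.arg(model)
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1)
  stopifnot(ncol(dosage) == length(s), length(s) == length(h))
  if (!length(s)) return(rep(1, nrow(dosage)))
  if (all(s == 0)) return(rep(1, nrow(dosage)))
  het <- dosage == 1L
  hom <- dosage == 2L
  if (model == "multiplicative") {
    # logs floored far below any attainable value so that a zero fitness
    # term yields w = 0 without 0 * -Inf artifacts in the matrix product
    log_het <- log(pmax(1 - h * s, 1e-300))
    log_hom <- log(pmax(1 - s, 1e-300))
    w <- exp(het %*% log_het + hom %*% log_hom)
  } else {
    w <- 1 - (het %*% (h * s) + hom %*% s)
  }
  pmax(as.vector(w), 0)
}

#' Initialize the burn-in population
#'
#' One patch of `K` individuals with sexes drawn Bernoulli(1/2) and every
#' allele copy at every locus (deleterious and neutral alike) carrying the
#' derived state independently with probability
#' `params$initial_derived_freq`.
#'
#' @param params a [selection_params()].
#' @param K initial census / carrying capacity.
#' @param seed optional integer seed.
#' @param patch_name name of the founding patch.
#' @return list of class `sim_state` with elements `patches`, `loci`,
#'   `params`, `generation`.
#' @export
initialize_burn_in <- function(params, K = 1000, seed = NULL,
                               patch_name = "main") {
  stopifnot(inherits(params, "selection_params"))
  if (!is.null(seed)) set_master_seed(seed)
  n_del <- params$n_deleterious_loci
  n_neu <- params$n_neutral_loci
  L <- n_del + n_neu
  s <- c(params$s %||%
           sample_selection_coefficients(max(n_del, 1), params$gamma_mean_s,
                                         params$gamma_shape)[seq_len(n_del)],
         rep(0, n_neu))
  if (n_del == 0) s <- rep(0, n_neu)
  h <- ifelse(seq_len(L) <= n_del, dominance_of(s, params$dominance_rate), 0.5)
  loci <- tibble(locus = seq_len(L),
                 type = rep(c("deleterious", "neutral"), c(n_del, n_neu)),
                 s = s, h = h)
  draw <- function() matrix(
    as.integer(runif(K * L) < params$initial_derived_freq), K, L)
  patch <- new_patch(draw(), draw(),
                     female = runif(K) < 0.5, K = K)
  structure(list(patches = setNames(list(patch), patch_name),
                 loci = loci, params = params, generation = 0L),
            class = "sim_state")
}

# gametes of given parent rows: one allele per locus, fair coin per locus
# (free recombination)
gametes_of <- function(A, B, parents) {
  GA <- A[parents, , drop = FALSE]
  GB <- B[parents, , drop = FALSE]
  swap <- matrix(runif(length(GA)) < 0.5, nrow(GA), ncol(GA))
  GA[swap] <- GB[swap]
  GA
}

# sparse mutation: with per-copy rates of 1e-5 order, drawing the number of
# flips and their positions is exactly equivalent to per-copy coin flips and
# far cheaper than a full uniform matrix
mutate_alleles <- function(G, mu, back_mu) {
  anc <- which(G == 0L)
  der <- which(G == 1L)
  if (mu > 0) {
    k <- rbinom(1, length(anc), mu)
    if (k > 0) G[anc[sample.int(length(anc), k)]] <- 1L
  }
  if (back_mu > 0) {
    k <- rbinom(1, length(der), back_mu)
    if (k > 0) G[der[sample.int(length(der), k)]] <- 0L
  }
  G
}

# produce n offspring of a patch (mothers proportional to `mothers` index
# vector, fathers uniformly random); returns list(A, B, female)
make_offspring <- function(patch, mothers, params) {
  males <- which(!patch$female)
  m <- length(mothers)
  fathers <- males[sample.int(length(males), m, replace = TRUE)]
  A <- mutate_alleles(gametes_of(patch$A, patch$B, mothers),
                      params$mu, params$back_mu)
  B <- mutate_alleles(gametes_of(patch$A, patch$B, fathers),
                      params$mu, params$back_mu)
  list(A = A, B = B, female = runif(m) < 0.5)
}

del_cols <- function(state) which(state$loci$type == "deleterious")

offspring_fitness <- function(off, state) {
  dc <- del_cols(state)
  if (!length(dc)) return(rep(1, nrow(off$A)))
  dosage <- off$A[, dc, drop = FALSE] + off$B[, dc, drop = FALSE]
  genotype_fitness(dosage, state$loci$s[dc], state$loci$h[dc],
                   model = state$params$fitness_model)
}

#' Advance the simulation by one generation
#'
#' In every extant patch: each female produces Poisson(fecundity) offspring
#' with an independently drawn random father from the patch (random mating,
#' polygyny allowed); each offspring inherits one allele per locus per
#' parent independently (free recombination) and mutates per allele copy
#' (`mu` forward, `back_mu` back); offspring survive hard viability
#' selection with probability equal to their fitness; survivors are culled
#' uniformly at random to the carrying capacity `K`. A patch with no
#' surviving offspring, or with a single sex remaining, goes extinct;
#' extinction is a recorded outcome, not an error.
#'
#' @param state a `sim_state`.
#' @return the advanced `sim_state`.
#' @export
advance_generation <- function(state) {
  params <- state$params
  for (nm in names(state$patches)) {
    p <- state$patches[[nm]]
    if (p$extinct) next
    females <- which(p$female)
    males <- which(!p$female)
    if (!length(females) || !length(males)) {
      state$patches[[nm]]$extinct <- TRUE
      next
    }
    n_off <- rpois(length(females), params$fecundity_mean)
    mothers <- rep(females, n_off)
    if (!length(mothers)) {
      state$patches[[nm]]$extinct <- TRUE
      next
    }
    off <- make_offspring(p, mothers, params)
    w <- offspring_fitness(off, state)
    alive <- which(runif(length(w)) < w)
    if (!length(alive)) {
      state$patches[[nm]]$extinct <- TRUE
      next
    }
    if (length(alive) > p$K) alive <- sample(alive, p$K)
    newp <- new_patch(off$A[alive, , drop = FALSE],
                      off$B[alive, , drop = FALSE],
                      off$female[alive], K = p$K)
    if (all(newp$female) || all(!newp$female)) newp$extinct <- TRUE
    state$patches[[nm]] <- newp
  }
  state$generation <- state$generation + 1L
  state
}

#' Found a new patch by migration of offspring
#'
#' Founder individuals are drawn as freshly produced offspring of the
#' source patch(es) (random parents from the current adults, inheritance
#' and mutation as in [advance_generation()]), with sexes forced to a 1:1
#' ratio (odd counts: the extra founder is female). With several sources,
#' founder counts per source are concatenated, so the destination starts
#' with `sum(counts)` individuals.
#'
#' @param state a `sim_state`.
#' @param patch name of the new (or re-founded, currently empty) patch.
#' @param sources character vector of source patch names.
#' @param counts founder count per source (each >= 2).
#' @param K carrying capacity of the destination.
#' @return the updated `sim_state`.
#' @export
found_population <- function(state, patch, sources, counts, K) {
  stopifnot(length(sources) == length(counts))
  if (any(counts < 2)) abort("founder counts must be >= 2 per source")
  parts <- purrr::map2(sources, counts, function(src, cnt) {
    sp <- state$patches[[src]]
    if (is.null(sp)) abort(paste0("unknown source patch: ", src))
    if (sp$extinct) abort(paste0("source patch extinct: ", src))
    females <- which(sp$female)
    if (!length(females) || !any(!sp$female)) {
      abort(paste0("source patch lacks one sex: ", src))
    }
    if (patch_size(sp) < cnt) {
      abort(paste0("source patch smaller than founder count: ", src))
    }
    mothers <- females[sample.int(length(females), cnt, replace = TRUE)]
    make_offspring(sp, mothers, state$params)
  })
  A <- do.call(rbind, purrr::map(parts, "A"))
  B <- do.call(rbind, purrr::map(parts, "B"))
  n <- nrow(A)
  n_female <- ceiling(n / 2)
  female <- sample(rep(c(TRUE, FALSE), c(n_female, n - n_female)))
  state$patches[[patch]] <- new_patch(A, B, female, K = K)
  state
}

#' Genetic load of a patch
#'
#' Realized genetic load from female fitness:
#' `L = 1 - W_mean / W_max`, where `W` is each female's expected number of
#' surviving offspring (fitness from her deleterious genotypes scaled by
#' mean fecundity) and `W_max` the maximum across the patch's females.
#' The ratio makes `L` invariant to the fecundity scaling.
#'
#' @param state a `sim_state`.
#' @param patch patch name.
#' @return tibble: `patch`, `w_mean`, `w_max`, `load`, `extinct`.
#' @export
genetic_load <- function(state, patch) {
  p <- state$patches[[patch]]
  if (is.null(p)) abort(paste0("unknown patch: ", patch))
  if (p$extinct || !any(p$female)) {
    return(tibble(patch = patch, w_mean = NA_real_, w_max = NA_real_,
                  load = NA_real_, extinct = TRUE))
  }
  f <- which(p$female)
  dc <- del_cols(state)
  dosage <- p$A[f, dc, drop = FALSE] + p$B[f, dc, drop = FALSE]
  w <- genotype_fitness(dosage, state$loci$s[dc], state$loci$h[dc],
                        model = state$params$fitness_model) *
    state$params$fecundity_mean
  tibble(patch = patch, w_mean = mean(w), w_max = max(w),
         load = if (max(w) > 0) 1 - mean(w) / max(w) else NA_real_,
         extinct = FALSE)
}
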