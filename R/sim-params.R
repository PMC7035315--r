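#' Selection and reproduction parameters of the forward simulator
#'
#' Parameters of the individual-based model: biallelic deleterious loci
#' whose selection coefficients are drawn from a gamma distribution
#' (mean 0.01, shape 0.3), a negative dominance-selection relationship
#' `h = exp(-51 s) / 2` (additive for tiny `s`, fully recessive for large
#' `s`; mean h about 0.37 under the default gamma), hard viability
#' selection on offspring, Poisson fecundity with mean five offspring per
#' female, and free recombination (every locus segregates independently).
#' Deleterious loci mutate ancestral-to-derived at `mu = 5e-5` and back at
#' `5e-7`; the burn-in seeds every locus at the mutation-selection-balance
#' frequency 0.0014.
#'
#' @param n_deleterious_loci,n_neutral_loci locus counts.
#' @param gamma_mean_s,gamma_shape mean and shape of the gamma from which
#'   selection coefficients are drawn (scale = mean/shape).
#' @param dominance_rate rate of the exponential dominance map
#'   `h = exp(-rate * s)/2`.
#' @param mu,back_mu per-allele-copy mutation rates (to derived / back to
#'   ancestral).
#' @param initial_derived_freq initial derived frequency at every locus.
#' @param fecundity_mean mean offspring per female.
#' @param fitness_model `"multiplicative"` (default) or `"additive"`
#'   across loci.
#' @param s optional explicit vector of selection coefficients for the
#'   deleterious loci (overrides the gamma draw).
#' @return list of class `selection_params`.
#' @export
selection_params <- function(n_deleterious_loci = 5000, n_neutral_loci = 500,
                             gamma_mean_s = 0.01, gamma_shape = 0.3,
                             dominance_rate = 51, mu = 5e-5, back_mu = 5e-7,
                             initial_derived_freq = 0.0014,
                             fecundity_mean = 5,
                             fitness_model = c("multiplicative", "additive"),
                             s = NULL) {
  fitness_model <- match.arg(fitness_model)
  rates <- c(mu = mu, back_mu = back_mu,
             initial_derived_freq = initial_derived_freq)
  if (any(rates < 0) || any(rates > 1)) {
    abort("mu, back_mu and initial_derived_freq must lie in [0, 1]")
  }
  if (gamma_mean_s <= 0 || gamma_shape <= 0) {
    abort("gamma parameters must be positive")
  }
  if (n_deleterious_loci < 0 || n_neutral_loci < 0) {
    abort("locus counts must be >= 0")
  }
  if (!is.null(s) && length(s) != n_deleterious_loci) {
    abort("explicit s vector must have length n_deleterious_loci")
  }
  structure(list(n_deleterious_loci = n_deleterious_loci,
                 n_neutral_loci = n_neutral_loci,
                 gamma_mean_s = gamma_mean_s, gamma_shape = gamma_shape,
                 dominance_rate = dominance_rate, mu = mu, back_mu = back_mu,
                 initial_derived_freq = initial_derived_freq,
                 fecundity_mean = fecundity_mean,
                 fitness_model = fitness_model, s = s),
            class = "selection_params")
}

#' Draw selection coefficients
#'
#' i.i.d. gamma draws with the given mean and shape
#' (scale = mean / shape).
#'
#' @param n number of loci.
#' @param gamma_mean,gamma_shape distribution parameters.
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
sample_selection_coefficients <- function(n, gamma_mean = 0.01,
                                          gamma_shape = 0.3, seed = NULL) {
  stopifnot(n >= 1, gamma_mean > 0, gamma_shape > 0)
  if (!is.null(seed)) set_master_seed(seed)
  rgamma(n, shape = gamma_shape, scale = gamma_mean / gamma_shape)
}

#' Dominance coefficient of a selection coefficient
#'
#' Exponential dominance-selection map `h = exp(-rate * s) / 2`: additive
#' (`h = 0.5`) at `s = 0`, approaching full recessivity as `s` grows.
#'
#' @param s selection coefficient(s), `s >= 0`.
#' @param dominance_rate exponential rate, default 51.
#' @return dominance coefficient(s) in `(0, 0.5]`.
#' @examples
#' dominance_of(0.01)  # exp(-0.51)/2 = 0.30025
#' @export
dominance_of <- function(s, dominance_rate = 51) {
  stopifnot(all(s >= 0))
  exp(-dominance_rate * s) / 2
}

#' Harmonic mean of a census series
#'
#' The harmonic mean of yearly census sizes from founding to sampling sets
#' each patch's carrying capacity: it is the effective-size-relevant
#' average under fluctuating census and is dominated by the smallest
#' counts.
#'
#' @param census numeric vector of census sizes, all > 0.
#' @return `n / sum(1/census)`.
#' @examples
#' harmonic_mean(c(10, 1000))  # 19.8
#' @export
harmonic_mean <- function(census) {
  if (any(!is.finite(census)) || any(census <= 0)) {
    abort("census sizes must all be positive")
  }
  length(census) / sum(1 / census)
}
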