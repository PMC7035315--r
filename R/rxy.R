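#' Rxy: relative derived-allele abundance of a mutation category
#'
#' Compares the number of derived alleles found at sites of a category
#' between two populations, standardized by putatively neutral control
#' sites (a random intergenic SNP set), which makes the statistic robust
#' to sampling effects and population substructure. With `f_i^X` the
#' derived-allele frequency at site `i` among called genotypes in
#' population X,
#' \deqn{L_{X \nless Y} = \sum_i f_i^X (1 - f_i^Y)}
#' and symmetrically for Y; then
#' \deqn{R_{XY} = \frac{L_{X \nless Y} / L_{Y \nless X}}
#'                     {L'_{X \nless Y} / L'_{Y \nless X}}}
#' where the primed sums run over the control sites. `Rxy < 1` indicates a
#' relative deficit of derived alleles of that category in X compared to
#' Y; on identical site sets `Rxy(X,Y) * Rxy(Y,X) = 1` exactly.
#'
#' Uncertainty is assessed by a delete-one-block jackknife across
#' chromosomes: each block's category and control sites are removed
#' together and the statistic recomputed; the vector of leave-one-out
#' estimates is returned as the jackknife distribution.
#'
#' @param freqs long table from [derived_freqs()] covering both
#'   populations.
#' @param categories tibble `site_id`, `category`, `is_control` (logical;
#'   control sites standardize every category).
#' @param x,y population labels (X and Y).
#' @param category category level(s) to evaluate; default: all non-control
#'   categories present.
#' @param jackknife logical; compute leave-one-chromosome-out estimates.
#' @param block_of optional named vector mapping `site_id` to jackknife
#'   block; defaults to the site's chromosome.
#' @return tibble of class `rxy_result`: `category`, `rxy`,
#'   `n_category_sites`, `n_control_sites`, `x`, `y`, and if jackknifed a
#'   list-column `pseudovalues` of per-block leave-one-out estimates.
#' @export
rxy <- function(freqs, categories, x, y, category = NULL,
                jackknife = TRUE, block_of = NULL) {
  fx <- filter(freqs, population == x, n_called > 0L)
  fy <- filter(freqs, population == y, n_called > 0L)
  wide <- inner_join(
    select(fx, site_id, chrom, f_x_d = "n_derived", f_x_n = "n_called"),
    select(fy, site_id, f_y_d = "n_derived", f_y_n = "n_called"),
    by = "site_id"
  ) %>%
    mutate(f_x = .data$f_x_d / .data$f_x_n, f_y = .data$f_y_d / .data$f_y_n)
  wide <- inner_join(wide, select(categories, site_id, category, is_control),
                     by = "site_id")
  if (is.null(block_of)) {
    block <- wide$chrom
  } else {
    block <- unname(block_of[wide$site_id])
  }
  wide$block <- block

  ctrl <- filter(wide, is_control)
  if (!nrow(ctrl) || sum(ctrl$f_x) == 0 || sum(ctrl$f_y) == 0) {
    abort("no derived control alleles in one population; enlarge the intergenic control set")
  }
  cats <- category %||% setdiff(unique(wide$category[!wide$is_control]), NA)

  one <- function(cat_sites, ctrl_sites) {
    l_xy <- sum(cat_sites$f_x * (1 - cat_sites$f_y))
    l_yx <- sum(cat_sites$f_y * (1 - cat_sites$f_x))
    lp_xy <- sum(ctrl_sites$f_x * (1 - ctrl_sites$f_y))
    lp_yx <- sum(ctrl_sites$f_y * (1 - ctrl_sites$f_x))
    if (l_yx == 0 || lp_xy == 0 || lp_yx == 0) return(NA_real_)
    (l_xy / l_yx) / (lp_xy / lp_yx)
  }

  res <- purrr::map_dfr(cats, function(cc) {
    cs <- filter(wide, category == cc, !is_control)
    est <- one(cs, ctrl)
    out <- tibble(category = cc, rxy = est,
                  n_category_sites = nrow(cs), n_control_sites = nrow(ctrl),
                  x = x, y = y)
    if (jackknife) {
      blocks <- sort(unique(c(cs$block, ctrl$block)))
      if (length(blocks) < 2) {
        warn("fewer than 2 jackknife blocks; no pseudovalues computed")
        out$pseudovalues <- list(tibble(block = character(), pseudovalue = numeric()))
      } else {
        pv <- purrr::map_dbl(blocks, function(b) {
          one(filter(cs, block != b), filter(ctrl, block != b))
        })
        bad <- is.na(pv)
        if (any(bad)) {
          warn(paste0("undefined leave-one-out estimate for block(s): ",
                      paste(blocks[bad], collapse = ", ")))
        }
        out$pseudovalues <- list(tibble(block = blocks, pseudovalue = pv))
      }
    }
    out
  })
  structure(res, class = c("rxy_result", class(res)))
}

#' @describeIn rxy leave-one-chromosome-out estimates as a long tibble
#'   (`category`, `block`, `pseudovalue`).
#' @export
jackknife_rxy <- function(freqs, categories, x, y, category = NULL,
                          block_of = NULL) {
  res <- rxy(freqs, categories, x, y, category = category,
             jackknife = TRUE, block_of = block_of)
  tidyr::unnest(select(res, category, "pseudovalues"), "pseudovalues")
}

#' Tidy an Rxy result
#'
#' @param x an `rxy_result`.
#' @param ... unused.
#' @return one row per category and jackknife block with the leave-one-out
#'   estimate, or the point estimates if no jackknife was run.
#' @export
tidy.rxy_result <- function(x, ...) {
  if ("pseudovalues" %in% names(x)) {
    tidyr::unnest(select(as_tibble(x), category, "pseudovalues"),
                  "pseudovalues")
  } else {
    select(as_tibble(x), category, "rxy")
  }
}

#' Glance at an Rxy result
#'
#' @param x an `rxy_result`.
#' @param ... unused.
#' @return one row per category: point estimate, jackknife standard error
#'   (delete-one formula on the leave-one-out estimates) and normal-theory
#'   95% interval on the log scale.
#' @export
glance.rxy_result <- function(x, ...) {
  base <- select(as_tibble(x), category, "rxy", "n_category_sites",
                 "n_control_sites")
  if (!"pseudovalues" %in% names(x)) return(base)
  se <- purrr::map_dbl(x$pseudovalues, function(pv) {
    v <- pv$pseudovalue[!is.na(pv$pseudovalue)]
    b <- length(v)
    if (b < 2) return(NA_real_)
    sqrt((b - 1) / b * sum((log(v) - mean(log(v)))^2))
  })
  base %>%
    mutate(log_se_jack = se,
           conf_low = exp(log(.data$rxy) - qnorm(0.975) * se),
           conf_high = exp(log(.data$rxy) + qnorm(0.975) * se))
}

#' @rdname rxy
#' @param object an `rxy_result` with pseudovalues.
#' @param ... unused.
#' @export
autoplot.rxy_result <- function(object, ...) {
  pv <- tidy.rxy_result(object)
  ggplot2::ggplot(pv, ggplot2::aes(x = category, y = pseudovalue)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(y = "Rxy (leave-one-chromosome-out)", x = NULL) +
    ggplot2::theme_minimal()
}
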