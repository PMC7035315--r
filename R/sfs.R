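#' Site frequency spectrum by mutation category
#'
#' Histogram of derived-allele counts across the polymorphic sites of one
#' category in a fixed sample of diploid individuals. Sites with any
#' missing call among the chosen individuals are excluded (so every counted
#' site rests on the same sample size), as are sites monomorphic in the
#' subset (count 0 or 2n).
#'
#' @param genotypes a [genotype_table()].
#' @param samples a [sample_manifest()].
#' @param polarized output of [polarize_derived()]; computed if `NULL`.
#' @param categories optional tibble `site_id`, `category`; when given, one
#'   SFS per category is returned.
#' @param population focal population(s) to include; `NULL` = all focal.
#' @param individuals optional explicit sample ids (overrides
#'   `population`).
#' @return tibble of class `sfs_tbl`: `category`, `count` (derived-allele
#'   count, `1 .. 2n-1`), `n_sites`; attribute `n` is the diploid sample
#'   size. Categories with no segregating site yield no rows (with a
#'   warning).
#' @export
sfs_by_category <- function(genotypes, samples, polarized = NULL,
                            categories = NULL, population = NULL,
                            individuals = NULL) {
  if (is.null(polarized)) polarized <- polarize_derived(genotypes, samples)
  ids <- if (!is.null(individuals)) individuals else focal_ids(samples, population)
  n <- length(ids)
  g <- geno_matrix(genotypes, ids)
  known <- polarized$derived_allele != "UNKNOWN"
  complete <- rowSums(is.na(g)) == 0L
  dac <- rowSums(g)
  keep <- known & complete & dac > 0L & dac < 2L * n
  tab <- tibble(site_id = genotypes$site_id[keep], count = dac[keep])
  if (is.null(categories)) {
    tab$category <- "all"
  } else {
    tab <- inner_join(tab, categories, by = "site_id")
  }
  out <- tab %>%
    count(category, count, name = "n_sites") %>%
    arrange(category, count)
  empty <- setdiff(unique(categories$category), out$category)
  if (length(empty)) {
    warn(paste0("no segregating sites for category: ",
                paste(empty, collapse = ", ")))
  }
  structure(out, n = n, class = c("sfs_tbl", class(out)))
}

#' Bin the high-count tail of an SFS for display
#'
#' Figure-style display of an SFS: derived-allele counts above
#' `max_single` are grouped into intervals of width `interval_width` and
#' shown as the mean number of sites per count value within the interval
#' (so a bin holding 30 sites across 5 count values displays as 6).
#'
#' @param sfs an [sfs_by_category()] result.
#' @param max_single largest count displayed individually (default 10).
#' @param interval_width width of tail intervals in count units.
#' @return tibble: `category`, `interval` (label), `midpoint`,
#'   `mean_sites`.
#' @export
sfs_bin_tail <- function(sfs, max_single = 10, interval_width = 5) {
  n <- attr(sfs, "n")
  upper <- 2 * n - 1
  breaks <- unique(c(seq(max_single, upper, by = interval_width), upper))
  sfs %>%
    filter(count > max_single) %>%
    mutate(bin = cut(count, breaks = breaks, include.lowest = FALSE)) %>%
    group_by(category, .data$bin) %>%
    summarise(n_sites_total = sum(n_sites), .groups = "drop") %>%
    mutate(
      lo = as.numeric(sub("\\((\\-?[0-9.]+),.*", "\\1", .data$bin)),
      hi = as.numeric(sub(".*,(\\-?[0-9.]+)\\]", "\\1", .data$bin)),
      width = .data$hi - .data$lo,
      interval = as.character(.data$bin),
      midpoint = (.data$lo + .data$hi) / 2,
      mean_sites = .data$n_sites_total / .data$width
    ) %>%
    select(category, interval, midpoint, mean_sites)
}

#' @rdname sfs_by_category
#' @param object,x an `sfs_tbl`.
#' @param ... unused.
#' @export
autoplot.sfs_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = count, y = n_sites,
                                       fill = category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "derived allele count", y = "number of sites",
                  fill = "category") +
    ggplot2::theme_minimal()
}

#' @rdname sfs_by_category
#' @export
plot_sfs <- function(x, ...) autoplot.sfs_tbl(x, ...)
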