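#' Export simulator genotypes in the empirical table format
#'
#' Converts the current state of the simulator into the same containers
#' the empirical pipeline consumes — a [genotype_table()] (loci spread
#' round-robin over pseudo-chromosomes, which also serve as jackknife
#' blocks), a [sample_manifest()] with one population per patch, a
#' polarization table (the derived allele is known by construction), and a
#' category table classing loci by selection strength: `neutral` loci are
#' flagged as the control set, deleterious loci are labelled `mild`
#' (`s <= 0.01`), `moderate` (`0.01 < s <= 0.1`) and `high` (`s > 0.1`).
#' The Rxy, SFS and count statistics therefore operate identically on
#' simulated and empirical data.
#'
#' @param state a `sim_state`.
#' @param patches patch names to export; default all extant.
#' @param n_chromosomes pseudo-chromosomes loci are assigned to.
#' @return list with `genotypes`, `samples`, `polarized`, `categories`.
#' @export
sim_genotypes <- function(state, patches = NULL, n_chromosomes = 10) {
  pats <- patches %||% names(state$patches)[
    !purrr::map_lgl(state$patches, "extinct")]
  L <- nrow(state$loci)
  chrom <- paste0("chr", ((state$loci$locus - 1) %% n_chromosomes) + 1)
  pos <- as.integer(100 * (((state$loci$locus - 1) %/% n_chromosomes) + 1))
  geno_cols <- list()
  sample_rows <- list()
  for (nm in pats) {
    p <- state$patches[[nm]]
    if (is.null(p) || p$extinct) next
    d <- t(p$A + p$B)  # loci x individuals
    colnames(d) <- paste0(nm, "_", seq_len(ncol(d)))
    geno_cols[[nm]] <- d
    sample_rows[[nm]] <- tibble(sample_id = colnames(d), population = nm,
                                species = "simulated", role = "focal")
  }
  if (!length(geno_cols)) abort("no extant patch to export")
  geno <- do.call(cbind, geno_cols)
  storage.mode(geno) <- "integer"
  genotypes <- genotype_table(chrom, pos, rep("A", L), rep("T", L), geno)
  categories <- tibble(
    site_id = genotypes$site_id,
    category = case_when(
      state$loci$type == "neutral" ~ "neutral",
      state$loci$s <= 0.01 ~ "mild",
      state$loci$s <= 0.1 ~ "moderate",
      TRUE ~ "high"
    ),
    is_control = state$loci$type == "neutral"
  )
  polarized <- tibble(site_id = genotypes$site_id, chrom = chrom, pos = pos,
                      derived_allele = "ALT",
                      n_outgroup_called = NA_integer_)
  list(genotypes = genotypes, samples = bind_rows(sample_rows),
       polarized = polarized, categories = categories)
}

apply_events <- function(state, events) {
  for (i in seq_len(nrow(events))) {
    if (events$type[i] == "resize") {
      nm <- events$patch[i]
      state$patches[[nm]]$K <- events$K[i]
      # an immediate census above the new K is culled at once
      p <- state$patches[[nm]]
      if (!p$extinct && nrow(p$A) > p$K) {
        keep <- sample.int(nrow(p$A), p$K)
        state$patches[[nm]] <- new_patch(p$A[keep, , drop = FALSE],
                                         p$B[keep, , drop = FALSE],
                                         p$female[keep], K = p$K)
      }
    } else {
      # scenario-level founding is tolerant of demographic accidents: a
      # source that is extinct, lacks a sex, or is too small to supply its
      # founders contributes what it can; an event left with no usable
      # source leaves the patch unfounded, which the tally records as an
      # extinction of that patch
      src <- events$sources[[i]]
      cnt <- as.integer(events$counts[[i]])
      usable <- purrr::map_lgl(src, function(s) {
        p <- state$patches[[s]]
        !is.null(p) && !p$extinct && any(p$female) && any(!p$female)
      })
      cnt <- pmin(cnt[usable],
                  purrr::map_int(src[usable],
                                 ~ patch_size(state$patches[[.x]])))
      src <- src[usable]
      keep <- cnt >= 2L
      src <- src[keep]; cnt <- cnt[keep]
      state$patches[[events$patch[i]]] <- NULL
      if (length(src)) {
        state <- found_population(state, events$patch[i], src, cnt,
                                  K = events$K[i])
      } else {
        state$patches[[events$patch[i]]] <-
          new_patch(matrix(0L, 0, nrow(state$loci)),
                    matrix(0L, 0, nrow(state$loci)),
                    logical(0), K = events$K[i], extinct = TRUE)
      }
    }
  }
  state
}

#' Run a demographic scenario
#'
#' Runs burn-in, bottleneck and founding events in generation order for
#' `replicates` independent replicates. Per replicate, [genetic_load()]
#' and mean per-category individual derived-allele/homozygote counts are
#' recorded every `report_every` generations for every patch, genotypes
#' can be snapshotted at chosen generations in the format of
#' [sim_genotypes()], and patch extinctions are tallied.
#'
#' @param scn a [scenario()].
#' @param params a [selection_params()].
#' @param replicates number of independent replicates.
#' @param seed master seed; replicate r runs on a derived substream, so
#'   results do not depend on execution order.
#' @param report_every reporting interval in generations (0 = only final).
#' @param snapshot_at generations at which to keep genotype exports.
#' @param keep_final keep the final `sim_state` of each replicate.
#' @return list of class `sim_result`: `reports` (tibble: `replicate`,
#'   `generation`, `patch`, `w_mean`, `w_max`, `load`, `extinct`, `size`),
#'   `counts` (tibble of mean per-individual derived allele/homozygote
#'   counts by locus category at reporting generations), `extinctions`
#'   (tibble: `patch`, `n_extinct`, `n_replicates`), `extinction_events`
#'   (long tibble: `replicate`, `patch`), `snapshots` (list by
#'   replicate of genotype exports), `finals` (list of final states, if
#'   kept), `scenario`, `params`.
#' @export
run_scenario <- function(scn, params, replicates = 1, seed = 1L,
                         report_every = 10, snapshot_at = integer(),
                         keep_final = FALSE) {
  stopifnot(inherits(scn, "sim_scenario"))
  reports <- list()
  count_rows <- list()
  snapshots <- vector("list", replicates)
  finals <- vector("list", replicates)
  ever_extinct <- list()

  for (r in seq_len(replicates)) {
    set_master_seed(derive_seed(seed, r))
    state <- initialize_burn_in(params, K = scn$burn_in$K,
                                patch_name = scn$burn_in$patch)
    snaps <- list()
    extinct_seen <- character()
    for (g in seq_len(scn$total_generations)) {
      ev <- scn$events[scn$events$generation == g, , drop = FALSE]
      if (nrow(ev)) state <- apply_events(state, ev)
      state <- advance_generation(state)
      newly_ext <- names(state$patches)[
        purrr::map_lgl(state$patches, "extinct")]
      extinct_seen <- union(extinct_seen, newly_ext)
      report_now <- (report_every > 0 && g %% report_every == 0) ||
        g == scn$total_generations
      if (report_now) {
        for (nm in names(state$patches)) {
          rep_row <- genetic_load(state, nm)
          rep_row$replicate <- r
          rep_row$generation <- g
          rep_row$size <- patch_size(state$patches[[nm]])
          reports[[length(reports) + 1]] <- rep_row
        }
        count_rows[[length(count_rows) + 1]] <-
          mean_category_counts(state) %>%
          mutate(replicate = r, generation = g)
      }
      if (g %in% snapshot_at) {
        any_extant <- !all(purrr::map_lgl(state$patches, "extinct"))
        snaps[[as.character(g)]] <-
          if (any_extant) sim_genotypes(state) else NULL
      }
    }
    snapshots[[r]] <- snaps
    if (keep_final) finals[[r]] <- state
    ever_extinct[[r]] <- extinct_seen
  }

  all_patches <- unique(c(scn$burn_in$patch, scn$events$patch))
  extinctions <- tibble(
    patch = all_patches,
    n_extinct = purrr::map_int(all_patches, function(nm) {
      sum(purrr::map_lgl(ever_extinct, ~ nm %in% .x))
    }),
    n_replicates = replicates
  )
  extinction_events <- purrr::imap_dfr(ever_extinct, function(pats, r) {
    if (!length(pats)) return(NULL)
    tibble(replicate = r, patch = pats)
  })
  structure(list(reports = bind_rows(reports),
                 counts = bind_rows(count_rows),
                 extinctions = extinctions,
                 extinction_events = extinction_events,
                 snapshots = snapshots,
                 finals = finals, scenario = scn, params = params,
                 seed = seed),
            class = "sim_result")
}

# mean per-individual derived allele / homozygote counts per locus class
mean_category_counts <- function(state) {
  cls <- case_when(
    state$loci$type == "neutral" ~ "neutral",
    state$loci$s <= 0.01 ~ "mild",
    state$loci$s <= 0.1 ~ "moderate",
    TRUE ~ "high"
  )
  purrr::map_dfr(names(state$patches), function(nm) {
    p <- state$patches[[nm]]
    if (p$extinct) return(NULL)
    d <- p$A + p$B
    purrr::map_dfr(unique(cls), function(cc) {
      sub <- d[, cls == cc, drop = FALSE]
      tibble(patch = nm, category = cc,
             mean_allele_count = mean(rowSums(sub)),
             mean_homozygote_count = mean(rowSums(sub == 2L)))
    })
  })
}

#' Tidy simulation reports
#'
#' @param x a `sim_result`.
#' @param ... unused.
#' @return the per-generation, per-patch load report tibble.
#' @export
tidy.sim_result <- function(x, ...) as_tibble(x$reports)

#' Final-generation summary of a simulation
#'
#' @param x a `sim_result`.
#' @param ... unused.
#' @return one row per patch: mean final load across replicates, number of
#'   extant replicates and the extinction tally.
#' @export
glance.sim_result <- function(x, ...) {
  x$reports %>%
    filter(generation == max(generation)) %>%
    group_by(patch) %>%
    summarise(mean_load = mean(load, na.rm = TRUE),
              n_extant = sum(!extinct), .groups = "drop") %>%
    left_join(x$extinctions, by = "patch")
}

#' @rdname run_scenario
#' @param object,x a `sim_result`.
#' @param ... unused.
#' @export
autoplot.sim_result <- function(object, ...) {
  ggplot2::ggplot(filter(object$reports, !extinct),
                  ggplot2::aes(x = generation, y = load,
                               colour = patch,
                               group = interaction(replicate, patch))) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(y = "genetic load  L = 1 - W_mean / W_max") +
    ggplot2::theme_minimal()
}
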