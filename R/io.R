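#' Write genotypes to a VCF v4.2 file
#'
#' Plain-text, uncompressed VCF with diploid unphased `GT` calls
#' (`0/0`, `0/1`, `1/1`, missing `./.`). Optional per-site INFO columns
#' (e.g. from [generate_filter_fixture()]) are emitted as typed INFO keys;
#' otherwise `AN` (called allele number) is written.
#'
#' @param genotypes a [genotype_table()].
#' @param path output file.
#' @param info optional tibble aligned with `genotypes` carrying columns
#'   among `QD`, `FS`, `SOR`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `AN`;
#'   `NA` values are omitted from the INFO string.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(genotypes, path, info = NULL) {
  g <- genotypes$geno
  gt <- matrix("./.", nrow(g), ncol(g))
  gt[!is.na(g) & g == 0L] <- "0/0"
  gt[!is.na(g) & g == 1L] <- "0/1"
  gt[!is.na(g) & g == 2L] <- "1/1"

  info_fields <- c("QD", "FS", "SOR", "MQ", "MQRankSum", "ReadPosRankSum", "AN")
  if (is.null(info)) {
    an <- 2L * rowSums(!is.na(g))
    info_str <- paste0("AN=", an)
  } else {
    present <- intersect(info_fields, names(info))
    info_str <- purrr::map_chr(seq_len(nrow(genotypes)), function(i) {
      vals <- purrr::map_chr(present, function(f) {
        v <- info[[f]][i]
        if (is.na(v)) return(NA_character_)
        paste0(f, "=", format(v, scientific = FALSE, trim = TRUE))
      })
      vals <- vals[!is.na(vals)]
      if (length(vals)) paste(vals, collapse = ";") else "."
    })
  }

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mutload",
    paste0("##contig=<ID=", unique(genotypes$chrom), ">"),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total called alleles\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(g)), collapse = "\t")
  )
  body <- paste(genotypes$chrom, genotypes$pos, genotypes$site_id,
                genotypes$ref, genotypes$alt, ".", ".", info_str, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a genotype table
#'
#' Reads diploid `GT` calls with `vcfR` and returns the package's
#' [genotype_table()] (derived-ALT dosage; `./.` becomes `NA`) together
#' with the parsed INFO columns used by [apply_hard_filters()].
#'
#' @param path VCF file (plain or gzipped).
#' @return list with `genotypes` and `info` (tibble with any of the hard
#'   filter INFO columns present, else `NULL`).
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_dose <- function(x) {
    a <- stringr::str_split_fixed(x, "[/|]", 2)
    suppressWarnings(as.integer(a[, 1] != "0") + as.integer(a[, 2] != "0"))
  }
  dos <- apply(gt, 2, alt_dose)
  dos[is.na(gt) | gt %in% c("./.", ".|.", ".")] <- NA_integer_
  dos <- matrix(as.integer(dos), nrow(gt), ncol(gt),
                dimnames = list(NULL, colnames(gt)))
  genotypes <- genotype_table(fix$CHROM, as.integer(fix$POS),
                              fix$REF, fix$ALT, dos)
  info_fields <- c("QD", "FS", "SOR", "MQ", "MQRankSum", "ReadPosRankSum", "AN")
  info_raw <- fix$INFO
  info <- purrr::map(info_fields, function(f) {
    m <- stringr::str_match(info_raw, paste0("(?:^|;)", f, "=([^;]+)"))[, 2]
    suppressWarnings(as.numeric(m))
  })
  names(info) <- info_fields
  info <- as_tibble(info)
  info$site_id <- genotypes$site_id
  list(genotypes = genotypes, info = info)
}

# TSV with '#'-prefixed header comment lines
write_tsv_commented <- function(x, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Write a cohort fixture bundle to disk
#'
#' Serializes a [generate_cohort()] result as self-contained plain-text
#' files: `cohort.vcf` (v4.2), `annotations.tsv`, `manifest.tsv`,
#' `truth.tsv`, `control_sites.txt` (intergenic control site ids) and
#' `scenario.yaml` (the reintroduction demography skeleton). Re-reading
#' with [read_fixture_bundle()] reproduces the in-memory objects exactly.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param scenario optional [scenario()] written alongside; default the
#'   down-scaled [ibex_scenario()].
#' @return invisibly, a named vector of file paths.
#' @export
write_fixture_bundle <- function(cohort, dir, scenario = ibex_scenario(scale = 10)) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", dir))
  }
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             annotations = file.path(dir, "annotations.tsv"),
             manifest = file.path(dir, "manifest.tsv"),
             truth = file.path(dir, "truth.tsv"),
             controls = file.path(dir, "control_sites.txt"),
             scenario = file.path(dir, "scenario.yaml"))
  seed_note <- paste0("seed: ", cohort$spec$seed)
  tryCatch({
    write_vcf(cohort$genotypes, paths[["vcf"]])
    write_tsv_commented(cohort$annotations, paths[["annotations"]], seed_note)
    write_tsv_commented(cohort$samples, paths[["manifest"]], seed_note)
    write_tsv_commented(cohort$truth, paths[["truth"]], seed_note)
    writeLines(unique(cohort$truth$site_id[cohort$truth$is_control]),
               paths[["controls"]])
    write_scenario(scenario, paths[["scenario"]])
  }, error = function(e) {
    abort(paste0("failed writing fixture bundle under ", dir, ": ",
                 conditionMessage(e)))
  })
  invisible(paths)
}

#' @rdname write_fixture_bundle
#' @return [read_fixture_bundle()] returns a list with `genotypes`,
#'   `samples`, `annotations`, `truth`, `control_sites`, `scenario`.
#' @export
read_fixture_bundle <- function(dir) {
  vcf <- read_vcf_genotypes(file.path(dir, "cohort.vcf"))
  list(
    genotypes = vcf$genotypes,
    samples = read_tsv_commented(file.path(dir, "manifest.tsv"),
                                 col_types = "cccc"),
    annotations = read_tsv_commented(file.path(dir, "annotations.tsv")),
    truth = read_tsv_commented(file.path(dir, "truth.tsv")),
    control_sites = readLines(file.path(dir, "control_sites.txt")),
    scenario = read_scenario(file.path(dir, "scenario.yaml"))
  )
}
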