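# Thin I/O layer: cohorts and Ct panels travel as plain CSV, reports as TSV,
# and every study run leaves a manifest naming its seed and settings.

#' Write a cohort to CSV
#'
#' One row per animal; body weights stay as age-suffixed columns
#' (`bw_wk16` etc.).
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' Restores the factor codings [simulate_four_way_cross()] /
#' [simulate_f2_intercross()] produce.
#'
#' @param path CSV file path.
#' @return Cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("ko_allele" %in% names(d)) {
    d$ko_allele <- factor(d$ko_allele, levels = c("B6J", "KO"))
    d$qtl_allele <- factor(d$qtl_allele, levels = c("B6JJcl", "SR"))
    attr(d, "design_kind") <- "four_way"
  }
  if ("genotype" %in% names(d)) {
    d$genotype <- factor(d$genotype,
                         levels = c("KO/KO", "KO/B6J", "B6J/B6J"))
    attr(d, "design_kind") <- "f2"
  }
  d
}

#' Write study output tables and a manifest
#'
#' Writes each table as TSV under `dir` and a `manifest.yaml` recording the
#' settings, the package version and the files written, so a run can be
#' reproduced from its manifest alone.
#'
#' @param dir Output directory (created if needed).
#' @param tables Named list of data frames.
#' @param manifest Named list of run settings.
#' @return The manifest path, invisibly.
#' @export
write_study_outputs <- function(dir, tables, manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, basename(p))
  }
  manifest$package_version <-
    as.character(utils::packageVersion("qtgtest"))
  manifest$r_version <- as.character(getRversion())
  manifest$files <- files
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  invisible(mp)
}
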