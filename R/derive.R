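#' Derive composite traits
#'
#' Adds the standard derived columns to a cohort: `total_fat` (sum of
#' inguinal, gonadal and perirenal fat pads; inguinal + gonadal only when the
#' perirenal pad was not recorded, in which case the result carries the
#' attribute `total_fat_components = "two_pad"`), `total_length`
#' (tail + head-body length, when both are present), and interval body
#' weight gains `gain_wk1_3`, ..., `gain_wk13_16` between consecutive
#' measurement ages.
#'
#' @param cohort Cohort data frame with fat-pad and body-weight columns.
#' @return The cohort with derived columns appended.
#' @export
derive_traits <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  has <- function(x) x %in% names(cohort)
  if (!has("inguinal_fat") || !has("gonadal_fat")) {
    stop("missing fat-pad component columns (inguinal_fat, gonadal_fat)",
         call. = FALSE)
  }
  if (has("perirenal_fat")) {
    cohort$total_fat <- cohort$inguinal_fat + cohort$gonadal_fat +
      cohort$perirenal_fat
    attr(cohort, "total_fat_components") <- "three_pad"
  } else {
    cohort$total_fat <- cohort$inguinal_fat + cohort$gonadal_fat
    attr(cohort, "total_fat_components") <- "two_pad"
    warning("perirenal fat pad absent; total_fat uses inguinal + gonadal only",
            call. = FALSE)
  }
  if (has("tail_length") && has("headbody_length")) {
    cohort$total_length <- cohort$tail_length + cohort$headbody_length
  }

  bw_cols <- grep("^bw_wk[0-9]+$", names(cohort), value = TRUE)
  if (length(bw_cols) >= 2L) {
    ages <- sort(as.integer(sub("^bw_wk", "", bw_cols)))
    for (i in seq_len(length(ages) - 1L)) {
      a1 <- ages[i]; a2 <- ages[i + 1L]
      cohort[[sprintf("gain_wk%d_%d", a1, a2)]] <-
        cohort[[paste0("bw_wk", a2)]] - cohort[[paste0("bw_wk", a1)]]
    }
  }
  cohort
}

#' Default trait groups for multivariate screening
#'
#' The eight trait-group categories used throughout: body weight, body
#' weight gain, body length, organ weight, fat pad weight, and the
#' body-weight-adjusted versions of length, organ and fat. Composite traits
#' (total fat, total length) and the single-sex testis weight are excluded
#' from the grouped multivariate tests and analysed individually.
#'
#' @param adjusted_prefix Prefix of body-weight-adjusted trait columns.
#' @return Named list of character vectors of trait column names.
#' @export
default_trait_groups <- function(adjusted_prefix = "adj_") {
  lengths_ <- c("tail_length", "headbody_length")
  organs <- c("liver_wt", "kidney_wt", "heart_wt", "lung_wt", "spleen_wt")
  fats <- c("inguinal_fat", "gonadal_fat", "perirenal_fat")
  list(
    body_weight = paste0("bw_wk", BW_AGES),
    weight_gain = sprintf("gain_wk%d_%d", BW_AGES[-length(BW_AGES)],
                          BW_AGES[-1]),
    body_length = lengths_,
    organ_weight = organs,
    fat_pad_weight = fats,
    adjusted_body_length = paste0(adjusted_prefix, lengths_),
    adjusted_organ_weight = paste0(adjusted_prefix, organs),
    adjusted_fat_pad_weight = paste0(adjusted_prefix, fats)
  )
}
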