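#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per (sample, gene); each sample's
#' delta-Ct is its mean target Ct minus its mean endogenous-control Ct; and
#' the relative level is `2^-(dCt - dCt_ref)`. Under the default group-mean
#' convention `dCt_ref` is the calibrator group's mean delta-Ct and the
#' levels are then rescaled by the calibrator group's arithmetic mean, so
#' that group's mean relative expression is exactly 1 while per-sample
#' variation is retained. The `reference_sample` convention instead uses the
#' first calibrator sample's delta-Ct as `dCt_ref` with no rescaling.
#'
#' @param panel Long-format Ct panel: `sample_id`, `group`, `gene`
#'   (`"target"`/`"control"`), `ct`, optionally `tissue`, `replicate`.
#' @param calibrator_group Group label used as calibrator.
#' @param convention `"group_mean"` (default) or `"reference_sample"`.
#' @return A `relative_expression` data frame: `sample_id`, `group`,
#'   `ct_target`, `ct_control`, `dct`, `rel_expr`, with attributes
#'   `calibrator_group`, `convention`, `dct_ref`.
#' @export
delta_delta_ct <- function(panel, calibrator_group,
                           convention = c("group_mean", "reference_sample")) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(panel),
            all(c("sample_id", "group", "gene", "ct") %in% names(panel)))
  if (!all(panel$gene %in% c("target", "control"))) {
    stop("`gene` must be \"target\" or \"control\"", call. = FALSE)
  }
  if (any(!is.finite(panel$ct)) || any(panel$ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }

  agg <- stats::aggregate(ct ~ sample_id + group + gene, data = panel,
                          FUN = mean)
  nrep <- stats::aggregate(ct ~ sample_id + gene, data = panel, FUN = length)
  if (any(nrep$ct < 2L)) {
    warning("sample(s) with a single replicate: ",
            paste(unique(nrep$sample_id[nrep$ct < 2L]), collapse = ", "),
            "; using the lone Ct as-is", call. = FALSE)
  }

  wide <- stats::reshape(agg, idvar = c("sample_id", "group"),
                         timevar = "gene", direction = "wide")
  names(wide) <- sub("^ct\\.", "ct_", names(wide))
  if (anyNA(wide$ct_control) || anyNA(wide$ct_target)) {
    bad <- wide$sample_id[is.na(wide$ct_control) | is.na(wide$ct_target)]
    stop("sample(s) missing the target or control gene: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cal <- wide$group == calibrator_group
  if (!any(cal)) {
    stop("calibrator group not present: ", calibrator_group, call. = FALSE)
  }

  wide$dct <- wide$ct_target - wide$ct_control
  if (convention == "group_mean") {
    dct_ref <- mean(wide$dct[cal])
    rel <- 2^(-(wide$dct - dct_ref))
    rel <- rel / mean(rel[cal])
  } else {
    dct_ref <- wide$dct[cal][1L]
    rel <- 2^(-(wide$dct - dct_ref))
  }
  wide$rel_expr <- rel
  out <- wide[order(wide$group, wide$sample_id),
              c("sample_id", "group", "ct_target", "ct_control", "dct",
                "rel_expr")]
  rownames(out) <- NULL
  structure(out, class = c("relative_expression", "data.frame"),
            calibrator_group = calibrator_group, convention = convention,
            dct_ref = dct_ref)
}

#' Group summary of relative expression
#'
#' Arithmetic mean and SEM of the per-sample relative levels per group.
#'
#' @param rel A [delta_delta_ct()] result.
#' @return Data frame: `group`, `n`, `mean_rel_expr`, `sem`.
#' @export
expression_group_summary <- function(rel) {
  stopifnot(inherits(rel, "relative_expression"))
  out <- do.call(rbind, lapply(split(rel$rel_expr, rel$group), function(x) {
    data.frame(n = length(x), mean_rel_expr = mean(x),
               sem = stats::sd(x) / sqrt(length(x)))
  }))
  data.frame(group = rownames(out), out, row.names = NULL)
}
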