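# The quantitative complementation test: in a four-way cross segregating a
# knockout allele and a QTL allele, a significant knockout-by-QTL interaction
# on a trait means the knocked-out locus fails to complement the QTL allele,
# i.e. the two loci are one and the same.

#' Two-way allele-interaction ANOVA
#'
#' Fits `trait ~ ko_allele * qtl_allele` (optionally crossed with sex) on a
#' four-way-cross cohort of adjusted trait values and reports marginal
#' (Type III) F tests for every term, plus least-squares means for the four
#' genotype cells.
#'
#' @param adjusted_cohort Data frame with `ko_allele`, `qtl_allele`
#'   (two-level factors), optionally `sex`, and the trait column (typically
#'   residuals from [adjust_cohort()]).
#' @param trait Trait column name.
#' @param include_sex Cross the allele factors with sex.
#' @return An `interaction_test_result`: list with `trait`, `terms` (term,
#'   F, df1, df2, p), `lsmeans` (ko_allele, qtl_allele, lsmean, se, n),
#'   `p_interaction`.
#' @export
interaction_test <- function(adjusted_cohort, trait, include_sex = FALSE) {
  d <- adjusted_cohort
  stopifnot(is.data.frame(d), trait %in% names(d))
  if (!all(c("ko_allele", "qtl_allele") %in% names(d))) {
    stop("four-way-cross genotype coding (`ko_allele`, `qtl_allele`) required",
         call. = FALSE)
  }
  if (!is.numeric(d[[trait]])) stop("`trait` must be numeric", call. = FALSE)
  need <- c(trait, "ko_allele", "qtl_allele", if (include_sex) "sex")
  d <- d[stats::complete.cases(d[, need]), , drop = FALSE]
  d$ko_allele <- droplevels(factor(d$ko_allele))
  d$qtl_allele <- droplevels(factor(d$qtl_allele))
  cells <- table(d$ko_allele, d$qtl_allele)
  if (any(cells == 0L) || any(dim(cells) != 2L)) {
    stop("inestimable interaction: an allele-combination cell is empty",
         call. = FALSE)
  }

  rhs <- if (include_sex) "ko_allele * qtl_allele * sex"
         else "ko_allele * qtl_allele"
  contr <- list(ko_allele = "contr.sum", qtl_allele = "contr.sum")
  if (include_sex) {
    d$sex <- droplevels(factor(d$sex))
    contr$sex <- "contr.sum"
  }
  fit <- stats::lm(stats::reformulate(rhs, response = trait), data = d,
                   contrasts = contr)
  A <- car::Anova(fit, type = "III")
  terms_ <- setdiff(rownames(A), c("(Intercept)", "Residuals"))
  df_e <- A[rownames(A) == "Residuals", "Df"]
  tt <- data.frame(term = terms_,
                   F = A[terms_, "F value"],
                   df1 = A[terms_, "Df"],
                   df2 = df_e,
                   p = A[terms_, "Pr(>F)"],
                   row.names = NULL)

  em <- as.data.frame(summary(suppressMessages(
    emmeans::emmeans(fit, c("ko_allele", "qtl_allele")))))
  ncell <- as.data.frame(cells, stringsAsFactors = FALSE)
  names(ncell) <- c("ko_allele", "qtl_allele", "n")
  lsm <- merge(data.frame(ko_allele = as.character(em$ko_allele),
                          qtl_allele = as.character(em$qtl_allele),
                          lsmean = em$emmean, se = em$SE),
               ncell, by = c("ko_allele", "qtl_allele"))

  structure(list(trait = trait, terms = tt, lsmeans = lsm,
                 p_interaction = tt$p[tt$term == "ko_allele:qtl_allele"]),
            class = "interaction_test_result")
}

#' Complementation call from an interaction test
#'
#' A significant knockout-by-QTL interaction is a failure to complement
#' (evidence the knocked-out locus is identical to the QTL); a
#' non-significant one is quantitative complementation (the loci are
#' distinct). P values between `alpha` and `marginal_band` are flagged
#' marginal.
#'
#' @param result An [interaction_test()] result, or the interaction P value
#'   itself.
#' @param alpha Significance level.
#' @param marginal_band Upper edge of the marginal zone (P values in
#'   `[alpha, marginal_band]` are flagged).
#' @return A `complementation_call`: list with `label`
#'   (`"failure_to_complement"` or `"complement"`), `marginal`,
#'   `p_interaction`, `alpha`, `marginal_band`, `interpretation`.
#' @export
classify_complementation <- function(result, alpha = 0.05,
                                     marginal_band = 0.10) {
  p <- if (inherits(result, "interaction_test_result")) result$p_interaction
       else as.numeric(result)
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("need a single valid interaction P value", call. = FALSE)
  }
  if (alpha <= 0 || marginal_band < alpha) {
    stop("need 0 < alpha <= marginal_band", call. = FALSE)
  }
  fail <- p < alpha
  structure(list(
    label = if (fail) "failure_to_complement" else "complement",
    marginal = (!fail) && p <= marginal_band,
    p_interaction = p, alpha = alpha, marginal_band = marginal_band,
    interpretation = if (fail) "locus identical to QTL" else "locus distinct"),
    class = "complementation_call")
}

#' Sex-pooling screen per trait group
#'
#' Runs a MANOVA with the full knockout-by-QTL-by-sex factorial per trait
#' group and pools the sexes wherever the three-way interaction is not
#' significant by any of the four multivariate statistics. Downstream
#' per-trait tests should use sex-combined data only where `pool` is `TRUE`.
#'
#' @param adjusted_cohort Four-way-cross adjusted cohort.
#' @param trait_groups Named list of trait-column vectors (see
#'   [default_trait_groups()]); groups with columns missing from the data
#'   are skipped.
#' @param alpha Significance level for the screen.
#' @return Data frame: `group`, `pool`, `min_p` (smallest three-way P over
#'   the four statistics).
#' @export
sex_pooling_decision <- function(adjusted_cohort,
                                 trait_groups = default_trait_groups(),
                                 alpha = 0.05) {
  d <- adjusted_cohort
  stopifnot(is.data.frame(d))
  sexes <- unique(stats::na.omit(as.character(d$sex)))
  groups <- trait_groups[vapply(trait_groups,
                                function(g) all(g %in% names(d)), logical(1))]
  if (length(groups) == 0L) stop("no trait group fully present", call. = FALSE)
  if (length(sexes) < 2L) {
    warning("single-sex cohort: sex pooling is trivially true", call. = FALSE)
    return(data.frame(group = names(groups), pool = TRUE, min_p = NA_real_))
  }
  out <- lapply(names(groups), function(gn) {
    mv <- trait_group_manova(d, groups[[gn]],
                             rhs = "ko_allele * qtl_allele * sex")
    s <- significance_summary(mv, alpha = alpha)
    row <- s[s$term == "ko_allele:qtl_allele:sex", ]
    data.frame(group = gn, pool = !row$significant_any_statistic,
               min_p = row$min_p)
  })
  do.call(rbind, out)
}

#' Run the complementation study end to end
#'
#' Simulates (or takes) a four-way-cross cohort, derives composite traits,
#' residualizes every trait with the mixed-model adjustment, screens the
#' three-way interaction with sex per trait group, runs the group MANOVAs
#' and the per-trait two-way allele-interaction ANOVAs on sex-combined data
#' where the screen allows, and issues a complementation call per trait.
#'
#' @param cohort Optional pre-built cohort; simulated from `design`/`model`
#'   when `NULL`.
#' @param design,model,seed Simulation inputs (see
#'   [simulate_four_way_cross()]).
#' @param alpha,marginal_band Call thresholds (see
#'   [classify_complementation()]).
#' @param trait_groups Trait-group definitions.
#' @param selection Run fixed-effect screening during adjustment.
#' @param out_dir Optional directory; when given, TSV reports and a manifest
#'   are written.
#' @return List: `cohort`, `adjusted`, `pooling`, `manova` (per-group term
#'   summaries), `report` (one row per trait: interaction F/P, cell LS
#'   means, call, marginal flag).
#' @export
run_complementation_study <- function(cohort = NULL,
                                      design = four_way_design(),
                                      model = mediation_model("null"),
                                      seed = 1L,
                                      alpha = 0.05, marginal_band = 0.10,
                                      trait_groups = default_trait_groups(),
                                      selection = TRUE,
                                      out_dir = NULL) {
  if (is.null(cohort)) cohort <- simulate_four_way_cross(design, model, seed)
  cohort <- derive_traits(cohort)
  adjusted <- adjust_cohort(cohort, selection = selection)

  pooling <- sex_pooling_decision(adjusted, trait_groups, alpha = alpha)

  groups <- trait_groups[vapply(trait_groups,
                                function(g) all(g %in% names(adjusted)),
                                logical(1))]
  manova_tabs <- lapply(names(groups), function(gn) {
    mv <- trait_group_manova(adjusted, groups[[gn]],
                             rhs = "ko_allele * qtl_allele * sex")
    cbind(group = gn, significance_summary(mv, alpha = alpha))
  })
  manova_summary <- do.call(rbind, manova_tabs)

  trait_cols <- unique(c(unlist(groups, use.names = FALSE),
                         intersect(c("total_fat", "total_length",
                                     "adj_total_fat", "adj_total_length"),
                                   names(adjusted))))
  group_of <- stats::setNames(rep(names(groups), lengths(groups)),
                              unlist(groups, use.names = FALSE))
  rows <- lapply(trait_cols, function(tr) {
    gn <- group_of[tr]
    pool <- if (!is.na(gn) && gn %in% pooling$group) {
      pooling$pool[pooling$group == gn]
    } else TRUE
    it <- interaction_test(adjusted, tr, include_sex = !pool)
    call <- classify_complementation(it, alpha, marginal_band)
    lsm <- it$lsmeans
    cell <- function(k, q) {
      i <- lsm$ko_allele == k & lsm$qtl_allele == q
      sprintf("%.4f +/- %.4f", lsm$lsmean[i], lsm$se[i])
    }
    data.frame(
      trait = tr, group = ifelse(is.na(gn), "ungrouped", gn),
      sex_pooled = pool,
      F_ko = it$terms$F[it$terms$term == "ko_allele"],
      p_ko = it$terms$p[it$terms$term == "ko_allele"],
      F_qtl = it$terms$F[it$terms$term == "qtl_allele"],
      p_qtl = it$terms$p[it$terms$term == "qtl_allele"],
      F_interaction = it$terms$F[it$terms$term == "ko_allele:qtl_allele"],
      p_interaction = it$p_interaction,
      lsm_B6J_B6JJcl = cell("B6J", "B6JJcl"),
      lsm_B6J_SR = cell("B6J", "SR"),
      lsm_KO_B6JJcl = cell("KO", "B6JJcl"),
      lsm_KO_SR = cell("KO", "SR"),
      call = call$label, marginal = call$marginal,
      row.names = NULL)
  })
  report <- do.call(rbind, rows)

  out <- list(cohort = cohort, adjusted = adjusted, pooling = pooling,
              manova = manova_summary, report = report)
  if (!is.null(out_dir)) {
    write_study_outputs(out_dir, list(
      complementation_report = report,
      manova_summary = manova_summary,
      sex_pooling = pooling,
      adjustment_report = attr(adjusted, "fit_report")),
      manifest = list(study = "complementation", seed = seed, alpha = alpha,
                      marginal_band = marginal_band,
                      n_animals = nrow(cohort)))
  }
  out
}
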