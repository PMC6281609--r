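# Causal inference test (CIT): four conditional linear-model tests deciding
# whether a genotype difference (G) drives a trait difference (T) through an
# expression difference (E). The causal chain G -> E -> T requires
#   Test 1: G associated with T                 (T ~ G)
#   Test 2: G associated with E given T         (E ~ G + T)
#   Test 3: E associated with T given G         (T ~ E + G)
#   Test 4: G independent of T given E          (T ~ E + G, G term n.s.)
# Test 4 accepts the null; its non-significance is evidence only in the
# accept-the-null sense, a documented caveat of the plain-regression form.

.cit_validate <- function(G, E, T_) {
  if (anyNA(G) || anyNA(E) || anyNA(T_)) {
    stop("CIT input must have no missing (G, E, T) triples", call. = FALSE)
  }
  if (is.factor(G) || is.character(G)) {
    lev <- unique(as.character(G))
    if (length(lev) != 2L) {
      stop("categorical G must have exactly 2 levels; supply a numeric ",
           "coding for other designs", call. = FALSE)
    }
    G <- as.numeric(factor(G, levels = lev)) - 1
  }
  G <- as.numeric(G)
  if (length(unique(G)) < 2L) stop("G must have >= 2 levels", call. = FALSE)
  if (any(table(G) < 3L)) {
    stop("need at least 3 animals per genotype", call. = FALSE)
  }
  if (stats::sd(E) == 0 || stats::sd(T_) == 0) {
    stop("degenerate fit: constant E or T", call. = FALSE)
  }
  if (abs(stats::cor(G, E)) > 1 - 1e-12) {
    stop("G and E are perfectly confounded; component tests are not ",
         "identifiable", call. = FALSE)
  }
  if (abs(stats::cor(E, T_)) > 1 - 1e-12) {
    stop("degenerate fit: E and T are collinear (is the trait a copy of ",
         "expression?)", call. = FALSE)
  }
  G
}

#' Four CIT component tests
#'
#' Runs the four conditional regressions (see the header of this file) and
#' returns their component P values, plus the unconditional
#' genotype-expression association P from `E ~ G` for reporting.
#'
#' @param G Genotype: numeric (e.g. 0/1 functional-allele copies in a
#'   two-genotype subset) or a two-level factor.
#' @param E Expression values (fold units or litter-adjusted residuals).
#' @param T_ Trait values (raw or adjusted residuals).
#' @return A `cit_component_result`: list with `p1`, `p2`, `p3`, `p4`,
#'   `p_expression` (unconditional), `n`, `n_per_genotype`.
#' @export
cit_component_tests <- function(G, E, T_) {
  G <- .cit_validate(G, E, T_)
  d <- data.frame(G = G, E = E, T_ = T_)
  coef_p <- function(fit, var) {
    cf <- summary(fit)$coefficients
    if (!var %in% rownames(cf)) {
      stop("degenerate fit: `", var, "` aliased in the component model",
           call. = FALSE)
    }
    cf[var, "Pr(>|t|)"]
  }
  m_gt <- stats::lm(T_ ~ G, data = d)
  m_egt <- stats::lm(E ~ G + T_, data = d)
  m_teg <- stats::lm(T_ ~ E + G, data = d)
  m_eg <- stats::lm(E ~ G, data = d)
  structure(list(p1 = coef_p(m_gt, "G"),
                 p2 = coef_p(m_egt, "G"),
                 p3 = coef_p(m_teg, "E"),
                 p4 = coef_p(m_teg, "G"),
                 p_expression = coef_p(m_eg, "G"),
                 n = nrow(d), n_per_genotype = as.integer(table(G))),
            class = "cit_component_result")
}

#' Classify a CIT result
#'
#' The trait is `causal` (genotype drives the trait through expression) when
#' Tests 1-3 are significant and Test 4 is not; `causal_marginal` when Test 3
#' falls in the marginal band `[alpha, marginal_band]` with Tests 1, 2
#' significant and Test 4 not; otherwise `not_causal`.
#'
#' @param p1,p2,p3,p4 Component P values, or pass a
#'   [cit_component_tests()] result as `p1`.
#' @param alpha Significance level.
#' @param marginal_band Upper edge of the marginal zone for Test 3.
#' @return `"causal"`, `"causal_marginal"` or `"not_causal"`.
#' @export
classify_cit <- function(p1, p2 = NULL, p3 = NULL, p4 = NULL,
                         alpha = 0.05, marginal_band = 0.10) {
  if (inherits(p1, "cit_component_result")) {
    p2 <- p1$p2; p3 <- p1$p3; p4 <- p1$p4; p1 <- p1$p1
  }
  p <- c(p1, p2, p3, p4)
  if (length(p) != 4L || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("need four valid P values", call. = FALSE)
  }
  if (alpha <= 0 || marginal_band < alpha) {
    stop("need 0 < alpha <= marginal_band", call. = FALSE)
  }
  base_ok <- p1 < alpha && p2 < alpha && p4 >= alpha
  if (base_ok && p3 < alpha) return("causal")
  if (base_ok && p3 >= alpha && p3 <= marginal_band) return("causal_marginal")
  "not_causal"
}

#' Trait variance explained by expression
#'
#' Squared Pearson correlation of expression with the trait (the simple
#' regression R^2), with the direction of the association.
#'
#' @param E Expression values.
#' @param T_ Trait values.
#' @return List: `r_squared`, `direction` (`"negative"`/`"positive"`),
#'   `correlation`.
#' @export
variance_explained <- function(E, T_) {
  ok <- !is.na(E) & !is.na(T_)
  E <- E[ok]; T_ <- T_[ok]
  if (length(E) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(E) == 0 || stats::sd(T_) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  r <- stats::cor(E, T_)
  list(r_squared = r^2, direction = if (r < 0) "negative" else "positive",
       correlation = r)
}

#' Screen a panel of traits with the CIT
#'
#' Applies the four component tests and the classification rule to every
#' trait in `traits`, using one aligned expression vector. Traits whose
#' values are collinear with expression (or otherwise degenerate) are
#' excluded with a warning. Least-squares means per genotype come from the
#' per-trait one-factor linear model.
#'
#' @param data Data frame holding genotype, expression and trait columns
#'   (typically litter-adjusted residuals).
#' @param traits Character vector of trait columns.
#' @param genotype_col Genotype column (numeric coding or 2-level factor).
#' @param expression_col Expression column.
#' @param alpha,marginal_band Classification thresholds.
#' @return Data frame, one row per trait: n per genotype, LS mean and SE per
#'   genotype, `p1`..`p4`, `p_expression`, `r_squared`, `label`.
#' @export
cit_screen <- function(data, traits, genotype_col = "b6j_copies",
                       expression_col = "expression",
                       alpha = 0.05, marginal_band = 0.10) {
  stopifnot(is.data.frame(data),
            genotype_col %in% names(data), expression_col %in% names(data))
  if (length(traits) == 0L) {
    return(data.frame(trait = character(), label = character()))
  }
  rows <- list()
  for (tr in traits) {
    if (!tr %in% names(data)) stop("trait absent: ", tr, call. = FALSE)
    ok <- stats::complete.cases(data[, c(genotype_col, expression_col, tr)])
    G <- data[[genotype_col]][ok]
    E <- data[[expression_col]][ok]
    T_ <- data[[tr]][ok]
    res <- tryCatch(cit_component_tests(G, E, T_), error = function(e) e)
    if (inherits(res, "error")) {
      warning("trait `", tr, "` excluded: ", conditionMessage(res),
              call. = FALSE)
      next
    }
    lab <- classify_cit(res, alpha = alpha, marginal_band = marginal_band)
    ve <- variance_explained(E, T_)
    gf <- factor(G)
    fit <- stats::lm(T_ ~ gf)
    em <- as.data.frame(summary(emmeans::emmeans(fit, "gf")))
    ns <- table(gf)
    rows[[tr]] <- data.frame(
      trait = tr,
      n_g1 = as.integer(ns[1]), n_g2 = as.integer(ns[2]),
      lsmean_g1 = em$emmean[1], se_g1 = em$SE[1],
      lsmean_g2 = em$emmean[2], se_g2 = em$SE[2],
      p1 = res$p1, p2 = res$p2, p3 = res$p3, p4 = res$p4,
      p_expression = res$p_expression,
      r_squared = ve$r_squared,
      label = lab, row.names = NULL)
  }
  if (length(rows) == 0L) {
    return(data.frame(trait = character(), label = character()))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the CIT study end to end
#'
#' Simulates (or takes) an F2 cohort, selects the two-genotype male subset
#' the mediation test uses (one vs two functional allele copies), simulates
#' a triplicate liver Ct panel, quantifies expression by [delta_delta_ct()]
#' with the one-copy group as calibrator, litter-adjusts expression and
#' traits, and screens all fat and organ traits with the CIT.
#'
#' @param cohort Optional F2 cohort; simulated from `design`/`model` when
#'   `NULL`.
#' @param design,model,seed Simulation inputs (see
#'   [simulate_f2_intercross()]).
#' @param n_per_genotype Animals per genotype in the expression subset.
#' @param alpha,marginal_band Classification thresholds.
#' @param calibration [delta_delta_ct()] convention.
#' @param litter_adjust `"residualize"` (default: CIT inputs are residuals
#'   from a litter random-intercept model), `"in_model"` (litter enters each
#'   component regression as a fixed factor), or `"none"`.
#' @param qpcr_params Passed to [simulate_ct_panel()].
#' @param out_dir Optional output directory for TSV reports and a manifest.
#' @return List: `cohort`, `subset`, `expression` (per-sample relative
#'   levels), `expression_summary`, `report` (the CIT table: one row per
#'   trait with component P values, R^2 and label).
#' @export
run_cit_study <- function(cohort = NULL,
                          design = f2_design(),
                          model = mediation_model("causal"),
                          seed = 1L,
                          n_per_genotype = 12L,
                          alpha = 0.05, marginal_band = 0.10,
                          calibration = c("group_mean", "reference_sample"),
                          litter_adjust = c("residualize", "in_model", "none"),
                          qpcr_params = list(),
                          out_dir = NULL) {
  calibration <- match.arg(calibration)
  litter_adjust <- match.arg(litter_adjust)
  if (is.null(cohort)) cohort <- simulate_f2_intercross(design, model, seed)
  cohort <- derive_traits(cohort)

  # two-genotype male subset: one vs two functional copies; animals whose
  # true transcript level is at or below zero are below the detection limit
  # of the Ct transform and cannot enter the expression panel
  pool <- cohort[cohort$sex == "M" & cohort$b6j_copies %in% c(1L, 2L) &
                   cohort$expression > 0, ]
  set.seed((as.numeric(seed) + 1) %% .Machine$integer.max)
  take <- unlist(lapply(split(seq_len(nrow(pool)), pool$b6j_copies),
                        function(i) {
    if (length(i) < n_per_genotype) {
      warning("fewer than ", n_per_genotype, " animals in a genotype; ",
              "using all ", length(i), call. = FALSE)
      i
    } else sample(i, n_per_genotype)
  }))
  subset_ <- pool[sort(take), , drop = FALSE]
  if (any(subset_$expression <= 0)) {
    stop("subset contains non-positive true expression; cannot simulate Ct",
         call. = FALSE)
  }

  panel <- simulate_ct_panel(subset_, qpcr_params = qpcr_params,
                             seed = (as.numeric(seed) + 2) %% .Machine$integer.max)
  rel <- delta_delta_ct(panel, calibrator_group = "KO/B6J",
                        convention = calibration)
  subset_$expr_measured <-
    rel$rel_expr[match(subset_$animal_id, rel$sample_id)]

  traits <- intersect(
    c("total_fat", "inguinal_fat", "gonadal_fat", "perirenal_fat",
      "liver_wt", "kidney_wt", "heart_wt", "lung_wt", "spleen_wt",
      "testis_wt"),
    names(subset_))
  work <- subset_
  work$G <- work$b6j_copies - 1L

  if (litter_adjust == "residualize") {
    for (cl in c(traits, "expr_measured")) {
      at <- adjust_trait(work, cl, model_spec())
      work[[paste0("la_", cl)]] <- at$residual + mean(work[[cl]], na.rm = TRUE)
    }
    for (cl in traits) {
      sp <- model_spec(covariate = "bw_wk16")
      at <- adjust_trait(work, cl, sp)
      work[[paste0("la_adj_", cl)]] <- at$residual
    }
    expr_col <- "la_expr_measured"
    screen_traits <- c(paste0("la_", traits), paste0("la_adj_", traits))
  } else {
    for (cl in traits) {
      sp <- model_spec(covariate = "bw_wk16",
                       random_litter = litter_adjust == "in_model")
      at <- adjust_trait(work, cl, sp)
      work[[paste0("adj_", cl)]] <- at$residual
    }
    expr_col <- "expr_measured"
    screen_traits <- c(traits, paste0("adj_", traits))
  }

  report <- cit_screen(work, screen_traits, genotype_col = "G",
                       expression_col = expr_col,
                       alpha = alpha, marginal_band = marginal_band)
  report$trait <- sub("^la_", "", report$trait)

  expr_summary <- expression_group_summary(rel)
  out <- list(cohort = cohort, subset = subset_, expression = rel,
              expression_summary = expr_summary, report = report)
  if (!is.null(out_dir)) {
    write_study_outputs(out_dir, list(
      cit_report = report,
      expression_samples = as.data.frame(rel),
      expression_summary = expr_summary),
      manifest = list(study = "cit", seed = seed, alpha = alpha,
                      marginal_band = marginal_band,
                      calibration = calibration,
                      litter_adjust = litter_adjust,
                      n_subset = nrow(subset_)))
  }
  out
}
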