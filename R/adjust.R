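# Mixed-model trait adjustment: fixed effects screened at a nominal level,
# litter as a random intercept, residuals re-centered to overall mean zero.

#' Adjustment model specification
#'
#' @param fixed_terms Character vector of fixed-effect terms (subset of
#'   `parity`, `litter_size`, `parity:litter_size`, `sex`). An interaction
#'   may only appear together with both of its main effects.
#' @param random_litter Include a litter random intercept (default `TRUE`).
#' @param covariate Optional covariate column (body weight at dissection
#'   age) producing a body-weight-adjusted trait.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(fixed_terms = character(), random_litter = TRUE,
                       covariate = NULL) {
  fixed_terms <- as.character(fixed_terms)
  for (tm in grep(":", fixed_terms, value = TRUE)) {
    parents <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(parents %in% fixed_terms)) {
      stop("interaction `", tm, "` requires both main effects in the spec",
           call. = FALSE)
    }
  }
  structure(list(fixed_terms = fixed_terms,
                 random_litter = isTRUE(random_litter),
                 covariate = covariate),
            class = "model_spec")
}

.check_litter <- function(cohort) {
  if (!"litter_id" %in% names(cohort)) {
    stop("cohort has no `litter_id` column", call. = FALSE)
  }
  if (length(unique(cohort$litter_id)) < 2L) {
    stop("degenerate design: need at least two litters to separate the ",
         "litter effect", call. = FALSE)
  }
}

# Cohort columns prepared for model fitting: parity categorical,
# litter_size continuous.
.prep_model_frame <- function(cohort) {
  d <- cohort
  if ("parity" %in% names(d)) d$parity <- factor(d$parity)
  if ("sex" %in% names(d)) d$sex <- factor(d$sex)
  d
}

# Terms droppable under the hierarchy: no higher-order term present contains
# them. Interactions are therefore eliminated before their main effects.
.droppable <- function(terms) {
  vapply(terms, function(tm) {
    !any(vapply(grep(":", terms, value = TRUE), function(it) {
      it != tm && tm %in% strsplit(it, ":", fixed = TRUE)[[1]]
    }, logical(1)))
  }, logical(1))
}

#' Select significant fixed effects for a trait
#'
#' Backward elimination in the mixed model `trait ~ candidates + (1 |
#' litter)`: at each step the least significant droppable term (interactions
#' first, main effects only once no interaction contains them) with marginal
#' P >= `alpha` is removed and the model refit, until every remaining term
#' is significant at the nominal level. Marginal term tests are Type III F
#' tests with Satterthwaite degrees of freedom.
#'
#' Candidate terms without observed variation (e.g. a single parity level)
#' are excluded before fitting.
#'
#' @param cohort Cohort data frame.
#' @param trait Trait column name.
#' @param candidates Candidate fixed-effect terms.
#' @param alpha Nominal retention level.
#' @return A [model_spec()] with the retained terms; the eliminated terms and
#'   their P values at removal are attached as attribute `dropped`.
#' @export
select_fixed_effects <- function(cohort, trait,
                                 candidates = c("parity", "litter_size",
                                                "parity:litter_size"),
                                 alpha = 0.05) {
  stopifnot(is.data.frame(cohort), trait %in% names(cohort))
  if (!is.numeric(cohort[[trait]])) stop("`trait` must be numeric", call. = FALSE)
  if (length(candidates) == 0L) stop("`candidates` must be non-empty", call. = FALSE)
  .check_litter(cohort)
  d <- .prep_model_frame(cohort)

  varies <- function(v) {
    x <- d[[v]]
    length(unique(x[!is.na(x)])) > 1L
  }
  keep <- vapply(candidates, function(tm) {
    all(vapply(strsplit(tm, ":", fixed = TRUE)[[1]], varies, logical(1)))
  }, logical(1))
  terms <- candidates[keep]

  dropped <- data.frame(term = character(), p = numeric())
  while (length(terms) > 0L) {
    f <- stats::reformulate(c(terms, "(1 | litter_id)"), response = trait)
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(f, data = d, REML = TRUE)))
    at <- suppressWarnings(stats::anova(fit, type = 3))
    pvals <- stats::setNames(at[["Pr(>F)"]], rownames(at))
    cand <- terms[.droppable(terms)]
    p_cand <- pvals[cand]
    p_cand[is.na(p_cand)] <- 1
    worst <- which.max(p_cand)
    if (p_cand[worst] >= alpha) {
      dropped <- rbind(dropped,
                       data.frame(term = cand[worst], p = unname(p_cand[worst])))
      terms <- setdiff(terms, cand[worst])
    } else break
  }
  spec <- model_spec(fixed_terms = terms, random_litter = TRUE)
  attr(spec, "dropped") <- dropped
  spec
}

#' Adjust a trait by its mixed model
#'
#' Fits `trait ~ fixed_terms (+ covariate) + (1 | litter)` by REML and
#' returns the residuals after removing both the fixed-effect predictions
#' and the predicted (BLUP) litter effects, re-centered so the overall mean
#' of the adjusted values is exactly zero. When the litter variance estimate
#' sits at the zero boundary the fit falls back to a fixed-effects-only
#' least-squares model, with a warning.
#'
#' Rows with missing trait or design values keep their position and receive
#' `NA` residuals; the sample is never silently reduced.
#'
#' @param cohort Cohort data frame.
#' @param trait Trait column name.
#' @param spec A [model_spec()].
#' @return An `adjusted_trait` object: data frame `animal_id`, `residual`,
#'   with attributes `spec`, `varcomp` (litter and residual variance),
#'   `n` (rows used), `trait`.
#' @export
adjust_trait <- function(cohort, trait, spec = model_spec()) {
  stopifnot(is.data.frame(cohort), inherits(spec, "model_spec"),
            trait %in% names(cohort))
  .check_litter(cohort)
  d <- .prep_model_frame(cohort)
  rhs <- c(spec$fixed_terms, spec$covariate)
  need <- unique(c(trait, unlist(strsplit(spec$fixed_terms, ":", fixed = TRUE)),
                   spec$covariate, "litter_id"))
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("spec names columns absent from cohort: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ok <- stats::complete.cases(d[, need, drop = FALSE])
  du <- d[ok, , drop = FALSE]
  if (nrow(du) < length(rhs) + 3L) {
    stop("too few complete observations to fit the adjustment model",
         call. = FALSE)
  }

  res <- rep(NA_real_, nrow(d))
  varcomp <- c(litter = NA_real_, residual = NA_real_)
  if (spec$random_litter && length(unique(du$litter_id)) >= 2L) {
    f <- stats::reformulate(c(if (length(rhs)) rhs else "1", "(1 | litter_id)"),
                            response = trait)
    fit <- suppressMessages(suppressWarnings(lme4::lmer(f, data = du, REML = TRUE)))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      warning("litter variance estimated at the zero boundary for `", trait,
              "`; falling back to a fixed-effects-only fit", call. = FALSE)
      fit_lm <- stats::lm(stats::reformulate(if (length(rhs)) rhs else "1",
                                             response = trait), data = du)
      res[ok] <- stats::residuals(fit_lm)
      varcomp <- c(litter = 0, residual = summary(fit_lm)$sigma^2)
    } else {
      res[ok] <- stats::residuals(fit)
      vc <- as.data.frame(lme4::VarCorr(fit))
      varcomp <- c(litter = vc$vcov[vc$grp == "litter_id"],
                   residual = vc$vcov[vc$grp == "Residual"])
    }
  } else {
    fit_lm <- stats::lm(stats::reformulate(if (length(rhs)) rhs else "1",
                                           response = trait), data = du)
    res[ok] <- stats::residuals(fit_lm)
    varcomp <- c(litter = 0, residual = summary(fit_lm)$sigma^2)
  }
  res[ok] <- res[ok] - mean(res[ok])

  out <- data.frame(animal_id = d$animal_id, residual = res,
                    stringsAsFactors = FALSE)
  structure(out, class = c("adjusted_trait", "data.frame"),
            spec = spec, varcomp = varcomp, n = sum(ok), trait = trait)
}

#' Adjust every trait of a cohort
#'
#' Runs [select_fixed_effects()] and [adjust_trait()] per trait and returns
#' the cohort's identifier, covariate and genotype columns together with the
#' residualized traits (same names) and, for traits in `covariate_traits`,
#' body-weight-adjusted residuals under `adj_<trait>`.
#'
#' @param cohort Cohort data frame (run [derive_traits()] first if composite
#'   traits and gains are wanted).
#' @param traits Trait columns to residualize; defaults to body weights,
#'   gains, lengths, organ and fat-pad weights present in the cohort.
#' @param covariate_traits Traits also adjusted for dissection-age body
#'   weight; defaults to lengths, organ and fat traits.
#' @param bw_col Body-weight covariate column.
#' @param candidates,alpha Passed to [select_fixed_effects()]; `selection =
#'   FALSE` skips screening and uses all candidates.
#' @param selection Run backward elimination (default) or keep all candidates.
#' @return Data frame of adjusted traits with attribute `fit_report`
#'   (per-trait terms retained, variance components, n).
#' @export
adjust_cohort <- function(cohort,
                          traits = intersect(
                            c(unlist(default_trait_groups()[1:5],
                                     use.names = FALSE),
                              "total_fat", "total_length", "testis_wt"),
                            names(cohort)),
                          covariate_traits = intersect(
                            c(unlist(default_trait_groups()[3:5],
                                     use.names = FALSE),
                              "total_fat", "total_length", "testis_wt"),
                            traits),
                          bw_col = "bw_wk16",
                          candidates = c("parity", "litter_size",
                                         "parity:litter_size"),
                          alpha = 0.05,
                          selection = TRUE) {
  stopifnot(is.data.frame(cohort))
  id_cols <- intersect(c("animal_id", "sex", "litter_id", "parity",
                         "litter_size", "ko_allele", "qtl_allele",
                         "cross_direction", "b6j_copies", "genotype",
                         "expression", bw_col),
                       names(cohort))
  out <- cohort[, id_cols, drop = FALSE]
  report <- list()
  for (tr in traits) {
    spec <- if (selection) {
      select_fixed_effects(cohort, tr, candidates = candidates, alpha = alpha)
    } else {
      model_spec(fixed_terms = candidates)
    }
    at <- adjust_trait(cohort, tr, spec)
    out[[tr]] <- at$residual
    vc <- attr(at, "varcomp")
    report[[tr]] <- data.frame(
      trait = tr, adjusted_for_bw = FALSE,
      terms = paste(spec$fixed_terms, collapse = "+"),
      var_litter = vc["litter"], var_residual = vc["residual"],
      n = attr(at, "n"), row.names = NULL)
    if (tr %in% covariate_traits) {
      spec_bw <- model_spec(fixed_terms = spec$fixed_terms, covariate = bw_col)
      at_bw <- adjust_trait(cohort, tr, spec_bw)
      out[[paste0("adj_", tr)]] <- at_bw$residual
      vc <- attr(at_bw, "varcomp")
      report[[paste0("adj_", tr)]] <- data.frame(
        trait = tr, adjusted_for_bw = TRUE,
        terms = paste(spec$fixed_terms, collapse = "+"),
        var_litter = vc["litter"], var_residual = vc["residual"],
        n = attr(at_bw, "n"), row.names = NULL)
    }
  }
  attr(out, "fit_report") <- do.call(rbind, report)
  attr(out, "design_kind") <- attr(cohort, "design_kind")
  out
}
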