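# Group-comparison machinery: one-way ANOVA with least-squares means,
# Tukey(-Kramer) HSD with a compact letter display, and MANOVA over trait
# groups with the four classical statistics.

.check_groups <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must have equal length", call. = FALSE)
  }
  ok <- !is.na(values) & !is.na(groups)
  g <- factor(groups[ok])
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  list(y = values[ok], g = g)
}

#' One-way ANOVA with least-squares means
#'
#' Classical between/within decomposition for a single factor, optionally
#' with sex as an additive covariate (the group F is then the marginal test
#' of the factor given sex). Least-squares means and standard errors come
#' from the fitted linear model, so they are covariate-adjusted under
#' unbalance.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param sex Optional sex covariate (factor-like); included additively when
#'   it has two observed levels.
#' @return A `one_way_result`: list with `F`, `df1`, `df2`, `p`, and
#'   `lsmeans` (group, lsmean, se, n).
#' @export
one_way_anova <- function(values, groups, sex = NULL) {
  ck <- .check_groups(values, groups)
  d <- data.frame(y = ck$y, g = ck$g)
  use_sex <- FALSE
  if (!is.null(sex)) {
    ok <- !is.na(values) & !is.na(groups)
    d$sex <- factor(sex[ok])
    use_sex <- nlevels(droplevels(d$sex)) > 1L
  }
  ns <- table(d$g)

  if (stats::var(d$y) == 0) {
    # all values identical: no between- or within-group variation
    lsm <- data.frame(group = levels(d$g), lsmean = d$y[1], se = 0,
                      n = as.integer(ns))
    return(structure(list(F = 0, df1 = nlevels(d$g) - 1L,
                          df2 = nrow(d) - nlevels(d$g), p = 1, lsmeans = lsm),
                     class = "one_way_result"))
  }

  f <- if (use_sex) y ~ sex + g else y ~ g
  fit <- stats::lm(f, data = d)
  at <- stats::anova(fit)
  row <- which(rownames(at) == "g")
  em <- emmeans::emmeans(fit, "g")
  es <- as.data.frame(summary(em))
  lsm <- data.frame(group = as.character(es$g), lsmean = es$emmean,
                    se = es$SE, n = as.integer(ns[as.character(es$g)]))
  structure(list(F = at$`F value`[row], df1 = at$Df[row],
                 df2 = at$Df[nrow(at)], p = at$`Pr(>F)`[row], lsmeans = lsm),
            class = "one_way_result")
}

# Compact letter display by insert-and-absorb: start from one set holding
# all groups; each significant pair splits every set containing both; subsets
# are absorbed. Groups share a letter iff their pairwise P >= alpha.
.assign_letters <- function(group_names, sig_pairs) {
  sets <- list(group_names)
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs$g1[r]; b <- sig_pairs$g2[r]
      new_sets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else new_sets <- c(new_sets, list(s))
      }
      # absorb: drop sets contained in another set
      keep <- rep(TRUE, length(new_sets))
      for (i in seq_along(new_sets)) {
        for (j in seq_along(new_sets)) {
          if (i != j && keep[j] &&
              all(new_sets[[i]] %in% new_sets[[j]]) &&
              (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      sets <- unique(new_sets[keep])
      sets <- sets[lengths(sets) > 0L]
    }
  }
  letters_out <- stats::setNames(rep("", length(group_names)), group_names)
  for (k in seq_along(sets)) {
    for (gname in sets[[k]]) {
      letters_out[gname] <- paste0(letters_out[gname], letters[k])
    }
  }
  letters_out
}

#' Tukey HSD pairwise comparisons with letter grouping
#'
#' All-pairs comparisons on the studentized range distribution with the
#' pooled within-group variance; unequal group sizes use the Tukey-Kramer
#' standard error. Groups sharing a letter are not significantly different
#' at `alpha`.
#'
#' @inheritParams one_way_anova
#' @param alpha Family-wise level for the letter display.
#' @return A `tukey_result`: list with `pairs` (g1, g2, diff, se, q, p) and
#'   `letters` (group, lsmean, n, letters).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  ck <- .check_groups(values, groups)
  y <- ck$y; g <- ck$g
  k <- nlevels(g)
  ns <- tapply(y, g, length)
  ms <- tapply(y, g, mean)
  df_e <- length(y) - k
  s2 <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df_e

  cmb <- utils::combn(levels(g), 2)
  pairs <- data.frame(g1 = cmb[1, ], g2 = cmb[2, ])
  pairs$diff <- ms[pairs$g1] - ms[pairs$g2]
  pairs$se <- sqrt(s2 / 2 * (1 / ns[pairs$g1] + 1 / ns[pairs$g2]))
  if (s2 == 0) {
    pairs$q <- ifelse(pairs$diff == 0, 0, Inf)
    pairs$p <- ifelse(pairs$diff == 0, 1, 0)
  } else {
    pairs$q <- abs(pairs$diff) / pairs$se
    pairs$p <- stats::ptukey(pairs$q, nmeans = k, df = df_e,
                             lower.tail = FALSE)
  }
  rownames(pairs) <- NULL

  sig <- pairs[pairs$p < alpha, c("g1", "g2"), drop = FALSE]
  let <- .assign_letters(levels(g), sig)
  letters_tab <- data.frame(group = levels(g), lsmean = as.numeric(ms),
                            n = as.integer(ns), letters = unname(let))
  structure(list(pairs = pairs, letters = letters_tab, alpha = alpha,
                 ms_within = s2, df = df_e),
            class = "tukey_result")
}

# The four multivariate statistics with their standard F approximations,
# from the hypothesis (H) and error (E) SSCP matrices: Rao's F for Wilks,
# the usual approximations for Pillai and Hotelling-Lawley, and an
# upper-bound F for Roy's maximum root.
.mv_stats <- function(H, E, df_h, df_e) {
  p <- nrow(E)
  q <- df_h
  v <- df_e
  lam <- Re(eigen(solve(E, H), only.values = TRUE)$values)
  lam <- pmax(lam, 0)
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (v - p - 1) / 2

  wilks <- prod(1 / (1 + lam))
  tt <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- v + q - (p + q + 1) / 2
  df1_w <- p * q
  df2_w <- w * tt - (p * q) / 2 + 1
  F_w <- ((1 - wilks^(1 / tt)) / wilks^(1 / tt)) * df2_w / df1_w

  pillai <- sum(lam / (1 + lam))
  df1_p <- s * (2 * m + s + 1)
  df2_p <- s * (2 * nn + s + 1)
  F_p <- (pillai / (s - pillai)) * df2_p / df1_p

  hl <- sum(lam)
  df1_h <- s * (2 * m + s + 1)
  df2_h <- 2 * (s * nn + 1)
  F_h <- df2_h * hl / (s * df1_h)

  roy <- max(lam)
  r <- max(p, q)
  df1_r <- r
  df2_r <- v - r + q
  F_r <- roy * df2_r / r

  data.frame(
    statistic = c("Pillai", "Wilks", "Hotelling-Lawley", "Roy"),
    value = c(pillai, wilks, hl, roy),
    approx_F = c(F_p, F_w, F_h, F_r),
    df1 = c(df1_p, df1_w, df1_h, df1_r),
    df2 = c(df2_p, df2_w, df2_h, df2_r),
    p = c(stats::pf(F_p, df1_p, df2_p, lower.tail = FALSE),
          stats::pf(F_w, df1_w, df2_w, lower.tail = FALSE),
          stats::pf(F_h, df1_h, df2_h, lower.tail = FALSE),
          stats::pf(F_r, df1_r, df2_r, lower.tail = FALSE))
  )
}

#' MANOVA over a trait group
#'
#' Fits the multivariate linear model `cbind(responses) ~ rhs` on complete
#' cases with sum-to-zero factor contrasts, takes marginal (Type III) SSCP
#' matrices per term, and reports Wilks' lambda, Pillai's trace, the
#' Hotelling-Lawley trace and Roy's maximum root with their standard
#' approximate F tests. With a single response all four reduce exactly to
#' the univariate ANOVA F.
#'
#' @param data Data frame holding responses and factors.
#' @param responses Character vector of response columns.
#' @param rhs Right-hand side of the model formula, e.g.
#'   `"ko_allele * qtl_allele * sex"`.
#' @return A `manova_result`: data frame with one row per term and
#'   statistic (term, statistic, value, approx_F, df1, df2, p), plus
#'   attributes `n` and `responses`.
#' @export
trait_group_manova <- function(data, responses, rhs) {
  stopifnot(is.data.frame(data), length(responses) >= 1L)
  miss <- setdiff(responses, names(data))
  if (length(miss)) {
    stop("responses absent from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rhs_vars <- all.vars(stats::reformulate(rhs))
  d <- data[stats::complete.cases(data[, c(responses, rhs_vars)]), , drop = FALSE]
  for (v in rhs_vars) if (!is.numeric(d[[v]])) d[[v]] <- factor(d[[v]])

  Y <- as.matrix(d[, responses, drop = FALSE])
  f <- stats::as.formula(paste("Y ~", rhs))
  contr <- lapply(stats::setNames(rhs_vars, rhs_vars), function(v) {
    if (is.factor(d[[v]])) "contr.sum" else NULL
  })
  contr <- contr[!vapply(contr, is.null, logical(1))]
  mod <- stats::lm(f, data = d, contrasts = contr)

  rank_x <- mod$rank
  if (nrow(d) <= length(responses) + rank_x) {
    stop("too few complete cases: n must exceed #responses + model df",
         call. = FALSE)
  }
  E <- crossprod(as.matrix(stats::residuals(mod)))
  dimnames(E) <- list(responses, responses)
  if (qr(E)$rank < nrow(E)) {
    stop("singular error SSCP: responses are collinear (",
         paste(responses, collapse = ", "), ")", call. = FALSE)
  }

  if (length(responses) == 1L) {
    # univariate fit: marginal SS per term, all four statistics reduce to
    # the ANOVA F
    A <- car::Anova(mod, type = "III")
    terms_ <- setdiff(rownames(A), c("(Intercept)", "Residuals"))
    df_e <- A["Residuals", "Df"]
    out <- do.call(rbind, lapply(terms_, function(tm) {
      st <- .mv_stats(matrix(A[tm, "Sum Sq"]), E, df_h = A[tm, "Df"],
                      df_e = df_e)
      cbind(term = tm, st)
    }))
  } else {
    A <- car::Anova(mod, type = "III")
    terms_ <- setdiff(A$terms, "(Intercept)")
    out <- do.call(rbind, lapply(terms_, function(tm) {
      st <- .mv_stats(as.matrix(A$SSP[[tm]]), E, df_h = A$df[[tm]],
                      df_e = A$error.df)
      cbind(term = tm, st)
    }))
  }
  structure(out, class = c("manova_result", "data.frame"),
            n = nrow(d), responses = responses)
}

#' Summarize MANOVA term significance
#'
#' For each model term, reports whether any of the four multivariate
#' statistics is significant at `alpha` (the permissive reading, "at least
#' one statistic") and whether all four are.
#'
#' @param result A [trait_group_manova()] result.
#' @param alpha Significance level.
#' @return Data frame: term, `significant_any_statistic`,
#'   `significant_all_statistics`, `min_p`, `max_p`.
#' @export
significance_summary <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "manova_result"))
  terms_ <- unique(result$term)
  do.call(rbind, lapply(terms_, function(tm) {
    p <- result$p[result$term == tm]
    data.frame(term = tm,
               significant_any_statistic = any(p < alpha),
               significant_all_statistics = all(p < alpha),
               min_p = min(p), max_p = max(p))
  }))
}
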