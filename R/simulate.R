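# Cohort simulators. One master seed per call; internal stages draw from the
# stream sequentially, so a fixed seed reproduces the cohort field for field.

TRAIT_PARAMS <- data.frame(
  trait     = c("inguinal_fat", "gonadal_fat", "perirenal_fat",
                "liver_wt", "kidney_wt", "heart_wt", "lung_wt", "spleen_wt",
                "testis_wt", "tail_length", "headbody_length"),
  mean      = c(2.30, 1.80, 0.95, 1.15, 0.36, 0.120, 0.140, 0.080,
                0.21, 7.6, 9.3),
  sd        = c(0.31, 0.25, 0.12, 0.09, 0.025, 0.008, 0.008, 0.012,
                0.05, 0.25, 0.30),
  bw_slope  = c(0.08, 0.06, 0.03, 0.03, 0.008, 0.002, 0.002, 0.001,
                0.002, 0.02, 0.03),
  sex_eff   = c(0.20, 0.30, 0.10, 0.10, 0.05, 0.010, 0.010, 0.005,
                0, 0.20, 0.30),
  stringsAsFactors = FALSE
)

BW_AGES <- c(1L, 3L, 6L, 10L, 13L, 16L)
BW_MEANS <- c(5.2, 11.5, 21, 27, 31, 35)
BW_MALE_ADD <- c(0.2, 0.8, 2.0, 3.0, 3.5, 4.0)

# Round-robin litter assignment with target sizes drawn uniformly from the
# design's range; parity drawn uniformly per litter.
.assign_litters <- function(design) {
  sizes <- sample(seq(design$litter_size_range[1], design$litter_size_range[2]),
                  design$n_litters, replace = TRUE)
  if (sum(sizes) < design$n_animals) {
    # top up target sizes (still within range at the max) so capacity suffices
    sizes <- pmin(sizes + ceiling((design$n_animals - sum(sizes)) /
                                    design$n_litters),
                  design$litter_size_range[2])
  }
  if (sum(sizes) < design$n_animals) {
    stop("litter capacity below cohort size; increase `n_litters`",
         call. = FALSE)
  }
  parity <- sample(design$parity_levels, design$n_litters, replace = TRUE)
  litter <- integer(design$n_animals)
  fill <- integer(design$n_litters)
  j <- 1L
  for (i in seq_len(design$n_animals)) {
    while (fill[j] >= sizes[j]) j <- if (j == design$n_litters) 1L else j + 1L
    litter[i] <- j
    fill[j] <- fill[j] + 1L
    j <- if (j == design$n_litters) 1L else j + 1L
  }
  data.frame(
    litter_id = sprintf("L%03d", litter),
    parity = parity[litter],
    litter_size = fill[litter]
  )
}

# Sex, litter structure, longitudinal body weights and the baseline
# (non-focal) dissection traits shared by both cross kinds.
.simulate_base <- function(design, model) {
  n <- design$n_animals
  lit <- .assign_litters(design)
  sex <- ifelse(stats::runif(n) < design$sex_ratio, "M", "F")
  male <- as.numeric(sex == "M")

  lit_idx <- as.integer(factor(lit$litter_id))
  n_lit <- max(lit_idx)
  u_bw <- stats::rnorm(n_lit)
  z <- stats::rnorm(n)
  bw <- sapply(seq_along(BW_AGES), function(a) {
    m <- BW_MEANS[a] + BW_MALE_ADD[a] * male
    s <- 0.09 * BW_MEANS[a]
    pmax(m + s * (0.6 * z + 0.4 * u_bw[lit_idx] + 0.5 * stats::rnorm(n)), 0.1)
  })
  colnames(bw) <- paste0("bw_wk", BW_AGES)

  # per-trait litter intercepts share the model's litter-to-residual ratio
  lit_scale <- if (model$sigma_T > 0) model$sigma_litter / model$sigma_T else 0
  traits <- matrix(NA_real_, n, nrow(TRAIT_PARAMS),
                   dimnames = list(NULL, TRAIT_PARAMS$trait))
  bw_dev <- bw[, "bw_wk16"] - mean(bw[, "bw_wk16"])
  for (k in seq_len(nrow(TRAIT_PARAMS))) {
    p <- TRAIT_PARAMS[k, ]
    u <- stats::rnorm(n_lit)
    val <- p$mean + p$sex_eff * male + p$bw_slope * bw_dev +
      p$sd * (lit_scale * u[lit_idx] + stats::rnorm(n))
    traits[, k] <- pmax(val, 0)
  }
  traits[sex == "F", "testis_wt"] <- NA_real_

  out <- data.frame(
    animal_id = sprintf("A%04d", seq_len(n)),
    sex = sex, lit,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(bw), as.data.frame(traits))
  list(cohort = out, lit_idx = lit_idx, n_lit = n_lit, male = male,
       bw_dev = bw_dev)
}

# Focal-trait covariate contribution common to all topologies.
.focal_covariates <- function(model, base) {
  model$beta_sex * base$male +
    model$beta_parity * base$cohort$parity +
    model$beta_litter_size * base$cohort$litter_size +
    model$beta_bw * base$bw_dev
}

#' Simulate a four-way cross cohort
#'
#' Each animal receives, independently with probability 1/2 each, one allele
#' at the knockout locus (functional `B6J` or disrupted `KO`) from one F1
#' parent and one allele at the QTL locus (`B6JJcl` or introgressed `SR`)
#' from the other, so the four genotype classes segregate 1:1:1:1. Factorial
#' effects from the [mediation_model()] (`effect_ko`, `effect_qtl`,
#' `effect_interaction`, `effect_sex3`) act on the model's
#' `affected_traits`, scaled by each trait's dispersion relative to the
#' focal trait. Expression is not measured in this design (`NA`).
#'
#' @param design A [cross_design()] of kind `"four_way"`.
#' @param model A [mediation_model()].
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#' @return A data frame with one row per animal: identifiers, sex, litter
#'   structure, `ko_allele`, `qtl_allele`, reciprocal `cross_direction`,
#'   body weights `bw_wk1` ... `bw_wk16`, dissection traits, `expression`.
#' @export
simulate_four_way_cross <- function(design, model, seed = NULL) {
  stopifnot(inherits(design, "cross_design"), inherits(model, "mediation_model"))
  if (design$kind != "four_way") {
    stop("`design` must have kind \"four_way\"", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  base <- .simulate_base(design, model)
  cohort <- base$cohort
  n <- design$n_animals

  ko <- ifelse(stats::runif(n) < 0.5, "KO", "B6J")
  qtl <- ifelse(stats::runif(n) < 0.5, "SR", "B6JJcl")
  cohort$ko_allele <- factor(ko, levels = c("B6J", "KO"))
  cohort$qtl_allele <- factor(qtl, levels = c("B6JJcl", "SR"))
  cohort$cross_direction <- factor(
    ifelse(stats::runif(n) < 0.5, "F1ko_x_F1qtl", "F1qtl_x_F1ko"))

  k <- as.numeric(ko == "KO")
  q <- as.numeric(qtl == "SR")
  sd_focal <- TRAIT_PARAMS$sd[TRAIT_PARAMS$trait == model$focal_trait]
  for (tr in model$affected_traits) {
    if (!tr %in% names(cohort)) {
      stop("affected trait not in cohort: ", tr, call. = FALSE)
    }
    sd_t <- TRAIT_PARAMS$sd[TRAIT_PARAMS$trait == tr]
    shift <- (model$effect_ko * k + model$effect_qtl * q +
                (model$effect_interaction + model$effect_sex3 * base$male) *
                k * q) * sd_t / sd_focal
    cohort[[tr]] <- pmax(cohort[[tr]] + shift, 0)
  }
  # covariate structure on the focal trait (sex/parity/litter-size/body weight)
  cohort[[model$focal_trait]] <-
    pmax(cohort[[model$focal_trait]] + .focal_covariates(model, base), 0)

  cohort$expression <- NA_real_
  attr(cohort, "design_kind") <- "four_way"
  cohort
}

#' Simulate an F2 intercross cohort
#'
#' The number of functional (`B6J`-derived) allele copies is drawn 1/4 : 1/2
#' : 1/4 for 0, 1, 2 copies (genotypes `KO/KO`, `KO/B6J`, `B6J/B6J`).
#' Expression and the focal trait are generated according to the
#' [mediation_model()] topology; all other traits carry only covariate,
#' litter and residual structure, so they are non-mediated by construction.
#'
#' @inheritParams simulate_four_way_cross
#' @param design A [cross_design()] of kind `"f2"`.
#' @return A data frame as in [simulate_four_way_cross()], with
#'   `b6j_copies` (0/1/2), a `genotype` label, and a continuous
#'   `expression` column (liver transcript level, fold units).
#' @export
simulate_f2_intercross <- function(design, model, seed = NULL) {
  stopifnot(inherits(design, "cross_design"), inherits(model, "mediation_model"))
  if (design$kind != "f2") stop("`design` must have kind \"f2\"", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  base <- .simulate_base(design, model)
  cohort <- base$cohort
  n <- design$n_animals

  g <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  cohort$b6j_copies <- g
  cohort$genotype <- factor(c("KO/KO", "KO/B6J", "B6J/B6J")[g + 1L],
                            levels = c("KO/KO", "KO/B6J", "B6J/B6J"))

  v_E <- stats::rnorm(base$n_lit, sd = model$sigma_litter_E)[base$lit_idx]
  u_T <- stats::rnorm(base$n_lit, sd = model$sigma_litter)[base$lit_idx]
  eps_E <- stats::rnorm(n, sd = model$sigma_E)
  eps_T <- stats::rnorm(n, sd = model$sigma_T)
  covar <- .focal_covariates(model, base)

  if (model$topology == "reactive") {
    T_val <- model$mu_T + model$beta_GT * g + covar + u_T + eps_T
    E_val <- model$mu_E + model$beta_TE * (T_val - model$mu_T) + v_E + eps_E
  } else {
    E_val <- model$mu_E + model$beta_GE * g + v_E + eps_E
    T_val <- model$mu_T + model$beta_ET * E_val + model$beta_GT * g +
      covar + u_T + eps_T
  }
  cohort$expression <- E_val
  cohort[[model$focal_trait]] <- pmax(T_val, 0)

  attr(cohort, "design_kind") <- "f2"
  cohort
}

#' Simulate a qPCR Ct panel from true expression values
#'
#' Inverse of the 2^-ddCt transform: for each animal carrying a true
#' expression value, the target gene's cycle threshold is
#' `baseline_ct - log2(expression)` plus replicate noise, and the endogenous
#' control gene sits at a constant `control_ct` plus noise. Doubling an
#' animal's true expression therefore lowers its expected target Ct by
#' exactly one cycle.
#'
#' @param cohort A simulated cohort; rows with non-missing `expression` are
#'   used. All used expression values must be strictly positive.
#' @param qpcr_params List with `baseline_ct` (target Ct at expression 1),
#'   `control_ct`, `replicate_sd` (cycles), `n_replicates`.
#' @param seed Integer seed.
#' @param tissue Tissue label recorded on every row.
#' @return Long-format data frame: `sample_id`, `group` (genotype label),
#'   `tissue`, `gene` (`"target"`/`"control"`), `replicate`, `ct`.
#' @export
simulate_ct_panel <- function(cohort,
                              qpcr_params = list(baseline_ct = 25,
                                                 control_ct = 20,
                                                 replicate_sd = 0.15,
                                                 n_replicates = 3L),
                              seed = NULL, tissue = "liver") {
  stopifnot(is.data.frame(cohort), "expression" %in% names(cohort))
  p <- utils::modifyList(list(baseline_ct = 25, control_ct = 20,
                              replicate_sd = 0.15, n_replicates = 3L),
                         qpcr_params)
  use <- cohort[!is.na(cohort$expression), , drop = FALSE]
  if (nrow(use) == 0L) stop("no expression values in cohort", call. = FALSE)
  if (any(use$expression <= 0)) {
    stop("true expression must be strictly positive to simulate Ct values; ",
         "subset the cohort first", call. = FALSE)
  }
  if (p$n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  grp <- if ("genotype" %in% names(use)) as.character(use$genotype)
         else paste(use$ko_allele, use$qtl_allele, sep = "/")
  nrep <- as.integer(p$n_replicates)
  n <- nrow(use)
  idx <- rep(seq_len(n), each = 2L * nrep)
  gene <- rep(rep(c("target", "control"), each = nrep), times = n)
  mu_ct <- ifelse(gene == "target",
                  p$baseline_ct - log2(use$expression[idx]),
                  p$control_ct)
  data.frame(
    sample_id = use$animal_id[idx],
    group = grp[idx],
    tissue = tissue,
    gene = gene,
    replicate = rep(rep(seq_len(nrep), 2L), times = n),
    ct = mu_ct + stats::rnorm(length(idx), sd = p$replicate_sd),
    stringsAsFactors = FALSE
  )
}
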