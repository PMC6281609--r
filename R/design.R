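#' Cross design specification
#'
#' Describes the mating design a simulated cohort is drawn from: either a
#' four-way cross (two F1 hybrids crossed, each parent segregating one allele
#' pair, so the knockout and QTL alleles segregate 1:1 independently) or an
#' F2 intercross (a single heterozygous locus segregating 1:2:1).
#'
#' Litters are filled round-robin with target sizes drawn uniformly from
#' `litter_size_range`, and each litter receives a parity drawn uniformly
#' from `parity_levels`.
#'
#' @param kind `"four_way"` or `"f2"`.
#' @param n_animals Number of animals in the cohort.
#' @param sex_ratio Expected fraction of males.
#' @param n_litters Number of litters; must give enough capacity for
#'   `n_animals` at the maximum litter size.
#' @param parity_levels Ordinal parity values litters are sampled from.
#' @param litter_size_range Integer interval of target litter sizes.
#' @return An object of class `cross_design`.
#' @seealso [four_way_design()], [f2_design()] for the default cohorts.
#' @export
cross_design <- function(kind = c("four_way", "f2"),
                         n_animals,
                         sex_ratio = 0.5,
                         n_litters = ceiling(n_animals / 8),
                         parity_levels = 1:3,
                         litter_size_range = c(6L, 10L)) {
  kind <- match.arg(kind)
  n_animals <- as.integer(n_animals)
  if (is.na(n_animals) || n_animals <= 0L) {
    stop("`n_animals` must be a positive integer", call. = FALSE)
  }
  if (sex_ratio < 0 || sex_ratio > 1) {
    stop("`sex_ratio` must lie in [0, 1]", call. = FALSE)
  }
  n_litters <- as.integer(n_litters)
  if (n_litters <= 0L) stop("`n_litters` must be positive", call. = FALSE)
  litter_size_range <- as.integer(round(litter_size_range))
  if (length(litter_size_range) != 2L || any(litter_size_range <= 0L) ||
      litter_size_range[1] > litter_size_range[2]) {
    stop("`litter_size_range` must be a positive integer interval c(lo, hi)",
         call. = FALSE)
  }
  if (n_litters * litter_size_range[2] < n_animals) {
    stop("litter capacity (n_litters * max size) is below `n_animals`; ",
         "increase `n_litters`", call. = FALSE)
  }
  if (length(parity_levels) < 1L) {
    stop("`parity_levels` must be non-empty", call. = FALSE)
  }
  structure(
    list(kind = kind, n_animals = n_animals, sex_ratio = sex_ratio,
         n_litters = n_litters, parity_levels = as.integer(parity_levels),
         litter_size_range = litter_size_range),
    class = "cross_design"
  )
}

#' Default four-way cross design
#'
#' A 352-animal four-way cross (the knockout strain and the subcongenic QTL
#' strain crossed through their background strains), with a slight male
#' excess and 44 litters of 6-10 pups.
#'
#' @param n_animals Cohort size.
#' @param ... Passed to [cross_design()].
#' @return A `cross_design` of kind `"four_way"`.
#' @export
four_way_design <- function(n_animals = 352L, ...) {
  cross_design(kind = "four_way", n_animals = n_animals, sex_ratio = 0.52,
               n_litters = ceiling(n_animals / 8), ...)
}

#' Default F2 intercross design
#'
#' A 108-animal F2 intercross between the knockout and background strains,
#' male-biased as dissection cohorts of this kind typically are.
#'
#' @param n_animals Cohort size.
#' @param ... Passed to [cross_design()].
#' @return A `cross_design` of kind `"f2"`.
#' @export
f2_design <- function(n_animals = 108L, ...) {
  cross_design(kind = "f2", n_animals = n_animals, sex_ratio = 0.62,
               n_litters = ceiling(n_animals / 8), ...)
}

#' Genotype-expression-trait mediation model
#'
#' Generative model for one focal trait `T`, one transcript `E`, and the
#' genotype `G` (copies of the functional allele), under one of four
#' topologies:
#'
#' * `causal`: `G -> E -> T` (`beta_GT` forced to 0),
#' * `reactive`: `G -> T -> E`,
#' * `independent`: `G -> E` and `G -> T` with no `E -> T` path,
#' * `null`: no genotype effect anywhere (all genotype effect sizes forced
#'   to 0).
#'
#' Defaults are calibrated to the validated obesity-resistance locus regime:
#' expression fold levels of about 1.0 and 2.1 in animals carrying one and
#' two functional copies, a focal fat-pad difference of about 0.35 g between
#' those groups, and a population R^2 of roughly 0.29 for the expression ->
#' trait regression in a two-genotype subset of a dozen animals per group.
#'
#' For four-way cross cohorts the factorial effects `effect_ko`,
#' `effect_qtl` and `effect_interaction` (trait units, applied to
#' `affected_traits` scaled by each trait's own dispersion) drive the
#' complementation-test signal; `effect_sex3` injects a three-way
#' allele-by-allele-by-sex interaction for the sex-pooling screen.
#'
#' @param topology One of `"causal"`, `"reactive"`, `"independent"`, `"null"`.
#' @param beta_GE Expression units (fold) per functional allele copy.
#' @param beta_ET Trait units per expression unit (causal topology).
#' @param beta_GT Direct genotype-to-trait effect (trait units per copy);
#'   defaults to `beta_GE * beta_ET` under `independent`/`reactive` so the
#'   marginal genotype-trait association matches the causal topology.
#' @param beta_TE Expression units per trait unit (reactive topology).
#' @param mu_E,mu_T Intercepts of the expression and focal-trait models.
#' @param sigma_E,sigma_T Residual SDs of expression and focal trait.
#' @param sigma_litter,sigma_litter_E Litter random-intercept SDs for the
#'   trait side and the expression side.
#' @param beta_sex Additive male effect on the focal trait (grams).
#' @param beta_parity Focal-trait effect per parity level.
#' @param beta_litter_size Focal-trait effect per pup of litter size.
#' @param beta_bw Focal-trait effect per gram of dissection-age body weight
#'   (deviation from the cohort mean).
#' @param effect_ko,effect_qtl,effect_interaction Four-way factorial effects
#'   (trait units on the focal scale) of carrying the knockout allele, the
#'   QTL allele, and both.
#' @param effect_sex3 Sex-specific increment of the interaction effect
#'   (males only), i.e. a three-way interaction.
#' @param affected_traits Trait columns the factorial effects act on.
#' @param focal_trait The mediated trait.
#' @return An object of class `mediation_model`.
#' @export
mediation_model <- function(topology = c("causal", "reactive", "independent", "null"),
                            beta_GE = 1.13,
                            beta_ET = -0.31,
                            beta_GT = NULL,
                            beta_TE = NULL,
                            mu_E = -0.13,
                            mu_T = 2.73,
                            sigma_E = 0.31,
                            sigma_T = 0.31,
                            sigma_litter = 0.10,
                            sigma_litter_E = 0.10,
                            beta_sex = 0.2,
                            beta_parity = 0,
                            beta_litter_size = 0,
                            beta_bw = 0.05,
                            effect_ko = 0,
                            effect_qtl = 0,
                            effect_interaction = 0,
                            effect_sex3 = 0,
                            affected_traits = c("inguinal_fat", "gonadal_fat",
                                                "perirenal_fat"),
                            focal_trait = "inguinal_fat") {
  topology <- match.arg(topology)
  sds <- c(sigma_E = sigma_E, sigma_T = sigma_T,
           sigma_litter = sigma_litter, sigma_litter_E = sigma_litter_E)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)

  if (topology == "null") {
    beta_GE <- 0; beta_ET <- 0; beta_GT <- 0; beta_TE <- 0
    effect_ko <- 0; effect_qtl <- 0; effect_interaction <- 0; effect_sex3 <- 0
  }
  if (topology == "causal") {
    if (!is.null(beta_GT) && beta_GT != 0) {
      stop("under topology = \"causal\" the direct path `beta_GT` must be 0",
           call. = FALSE)
    }
    beta_GT <- 0
    if (beta_GE == 0 || beta_ET == 0) {
      stop("topology = \"causal\" needs non-zero `beta_GE` and `beta_ET`",
           call. = FALSE)
    }
  }
  if (topology == "independent") {
    if (is.null(beta_GT)) beta_GT <- beta_GE * beta_ET
    beta_ET <- 0
  }
  if (topology == "reactive") {
    if (is.null(beta_GT)) beta_GT <- beta_GE * beta_ET
    if (beta_GT == 0) {
      stop("topology = \"reactive\" needs a non-zero genotype-to-trait path",
           call. = FALSE)
    }
    if (is.null(beta_TE)) beta_TE <- beta_GE / beta_GT
    beta_ET <- 0
  }
  if (is.null(beta_GT)) beta_GT <- 0
  if (is.null(beta_TE)) beta_TE <- 0

  structure(
    list(topology = topology,
         beta_GE = beta_GE, beta_ET = beta_ET, beta_GT = beta_GT,
         beta_TE = beta_TE, mu_E = mu_E, mu_T = mu_T,
         sigma_E = sigma_E, sigma_T = sigma_T,
         sigma_litter = sigma_litter, sigma_litter_E = sigma_litter_E,
         beta_sex = beta_sex, beta_parity = beta_parity,
         beta_litter_size = beta_litter_size, beta_bw = beta_bw,
         effect_ko = effect_ko, effect_qtl = effect_qtl,
         effect_interaction = effect_interaction, effect_sex3 = effect_sex3,
         affected_traits = affected_traits, focal_trait = focal_trait),
    class = "mediation_model"
  )
}

#' Read a run configuration file
#'
#' Reads a YAML (or JSON, which YAML subsumes) key-value file mirroring the
#' [cross_design()] and [mediation_model()] fields plus analysis settings
#' (`alpha`, `marginal_band`, `seed`, `calibration`), and returns validated
#' constructor output.
#'
#' Recognised top-level keys: `design` (list of `cross_design` arguments,
#' must include `kind` and `n_animals`), `model` (list of `mediation_model`
#' arguments), `alpha`, `marginal_band`, `seed`, `calibration`
#' (`"group_mean"` or `"reference_sample"`).
#'
#' @param path Path to the YAML/JSON config file.
#' @return A list with elements `design`, `model`, `alpha`, `marginal_band`,
#'   `seed`, `calibration`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a key-value mapping", call. = FALSE)
  known <- c("design", "model", "alpha", "marginal_band", "seed", "calibration")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  design <- if (!is.null(raw$design)) do.call(cross_design, raw$design) else NULL
  model <- if (!is.null(raw$model)) do.call(mediation_model, raw$model)
           else mediation_model("causal")
  alpha <- raw$alpha %||% 0.05
  band <- raw$marginal_band %||% 0.10
  if (alpha <= 0 || alpha >= 1 || band < alpha || band >= 1) {
    stop("need 0 < alpha <= marginal_band < 1", call. = FALSE)
  }
  calibration <- match.arg(raw$calibration %||% "group_mean",
                           c("group_mean", "reference_sample"))
  list(design = design, model = model, alpha = alpha, marginal_band = band,
       seed = raw$seed %||% 1L, calibration = calibration)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
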