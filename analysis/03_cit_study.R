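#!/usr/bin/env Rscript
# Causal inference test (CIT) study on the two-genotype F2 male subset.
#
# Twelve one-copy (KO/B6J) and twelve two-copy (B6J/B6J) males get a
# triplicate liver qPCR panel; relative expression comes from the 2^-ddCt
# method with the one-copy group as calibrator; expression and the fat/organ
# traits are litter-adjusted; and every trait is screened with the four CIT
# component tests. The simulated truth is causal mediation on inguinal fat
# only.
#
# The script also replays the decision rule over the published component
# P values of the motivating study's 20-trait table (shipped as a fixture)
# to show the classification logic reproduces those labels.

suppressPackageStartupMessages(library(qtgtest))

seed <- 20260922L
out_dir <- "results/cit"

res <- suppressWarnings(run_cit_study(seed = seed, out_dir = out_dir))

cat("== CIT study (simulated cohort) ==\n")
cat("\nRelative liver expression (calibrator = one-copy group):\n")
print(res$expression_summary, row.names = FALSE, digits = 3)

cat("\nCIT screen (p1: G-T; p2: G-E | T; p3: E-T | G; p4: G-T | E):\n")
cols <- c("trait", "p1", "p2", "p3", "p4", "r_squared", "label")
print(res$report[, cols], row.names = FALSE, digits = 3)

flagged <- res$report$trait[res$report$label != "not_causal"]
cat("\nTraits on the causal path in this run:",
    if (length(flagged)) paste(flagged, collapse = ", ") else "none", "\n")

# A single 12-vs-12 subset is one draw from a modest-power regime, so the
# run above may or may not flag the mediated trait. Estimate the power of
# the causal call on the mediated fat trait over replicate cohorts.
set.seed(seed)
n_rep <- 60
hits <- replicate(n_rep, {
  r <- suppressWarnings(run_cit_study(seed = sample.int(1e6, 1)))
  row <- r$report[r$report$trait == "inguinal_fat", ]
  row$label != "not_causal"
})
cat(sprintf("\nPower of the causal call on the mediated trait over %d",
            n_rep),
    sprintf("replicate cohorts (12/genotype): %.2f\n", mean(hits)))

# -- decision-rule replay on the published 20-trait component P values -----
pub <- utils::read.csv(system.file("extdata", "cit_published_pvalues.csv",
                                   package = "qtgtest"))
pub$label <- mapply(classify_cit, pub$p1, pub$p2, pub$p3, pub$p4,
                    MoreArgs = list(alpha = 0.05, marginal_band = 0.10))
agree <- pub$label == pub$published_label
cat(sprintf("\nDecision-rule replay on the published table: %d/%d labels match\n",
            sum(agree), nrow(pub)))
print(pub[pub$label != "not_causal", c("trait", "p1", "p2", "p3", "p4",
                                       "label")], row.names = FALSE)
write_study_outputs(out_dir, list(published_rule_replay = pub),
                    manifest = list(study = "cit_published_replay",
                                    seed = seed, alpha = 0.05,
                                    marginal_band = 0.10))
cat("\nFull tables in", out_dir, "\n")
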