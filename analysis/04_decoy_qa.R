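#!/usr/bin/env Rscript
# The headline decoy quality-assessment analysis, at two scales.
#
# (a) Structure level: four study targets get graded decoy ensembles
#     (mixed noise levels, so each holds correct and incorrect models)
#     plus one all-noise target with no correct decoy; run_qa pools a
#     balanced optimal threshold on long-range satisfaction, filters
#     every ensemble, and must list the all-noise target as a modelling
#     failure.
# (b) Ensemble level: the 10 000-decoy imbalanced testbed quantifies
#     ROC separation per measure, enrichment, false negatives and the
#     impact of filtering on the best / energy-ranked top-5 decoys.

source("analysis/00_study_design.R")

out <- results_dir()

## (a) structure-level run ---------------------------------------------------
targets <- study_targets()[1:4, ]
tgs <- lapply(seq_len(nrow(targets)), function(k) {
  row <- targets[k, ]
  cfg <- generator_config(seed = row$seed, L = row$L, topology = row$topology,
                          decoy_noise_sigmas = c(1, 8),
                          n_decoys_per_sigma = 8L,
                          prediction_precision = 0.8,
                          prediction_count = row$L,
                          long_range_fraction = 0.2)
  nat <- build_native(row)
  qa_target(id = row$id, structure = nat,
            predictions = make_predictions(extract_contacts(nat), cfg),
            decoys = make_decoys(nat, cfg))
})
# an all-noise target: no correct decoy can exist
fail_row <- data.frame(id = "T_fail", topology = "beta_hairpin_stack",
                       L = 60, seed = STUDY_SEED + 99)
cfg_fail <- generator_config(seed = fail_row$seed, L = 60,
                             topology = "beta_hairpin_stack",
                             decoy_noise_sigmas = 20,
                             n_decoys_per_sigma = 16L,
                             prediction_precision = 0.8,
                             prediction_count = 60,
                             long_range_fraction = 0.5)
nat_fail <- build_native(fail_row)
tgs <- c(tgs, list(qa_target(
  id = "T_fail", structure = nat_fail,
  predictions = make_predictions(extract_contacts(nat_fail), cfg_fail),
  decoys = make_decoys(nat_fail, cfg_fail))))

run <- run_qa(tgs, threshold = "auto")
stopifnot(length(run$errors) == 0)
write_tsv_report(run$per_target, file.path(out, "qa_per_target.tsv"))

cat(sprintf("Structure-level QA over %d targets, pooled balanced threshold %.3f:\n",
            nrow(run$per_target), run$threshold))
print(run$per_target, row.names = FALSE, digits = 3)
cat("Modelling failures flagged:",
    if (length(run$failed_targets)) paste(run$failed_targets, collapse = ", ")
    else "none", "\n")
# satisfied-contact / quality association on the pooled profiles
cr <- correlation_report(run$profiles, run$profiles$tm_score)
write_tsv_report(cr, file.path(out, "qa_correlation.tsv"))
cat("Spearman rho between satisfaction and TM-score per measure:\n")
print(cr, row.names = FALSE, digits = 2)

## (b) ensemble-level run ----------------------------------------------------
qa <- make_qa_ensemble(generator_config(seed = STUDY_SEED))
aucs <- vapply(c("long", "short", "all"), function(m)
  roc_auc(decoy_roc(qa$profiles, qa$truth_labels, m)), numeric(1))
th <- optimal_threshold(qa$profiles, qa$truth_labels, "long", balance = TRUE)
s <- summarize_filtering(qa$profiles, qa$truth_labels, th, "long")

set.seed(STUDY_SEED)
score_table <- data.frame(
  decoy_id = qa$profiles$decoy_id,
  # decoy generator's energy ranking: informative but imperfect
  tm_score = pmin(1, pmax(0, ifelse(qa$truth_labels,
                                    rnorm(nrow(qa$profiles), 0.6, 0.08),
                                    rnorm(nrow(qa$profiles), 0.3, 0.08)))),
  energy_rank = NA_integer_)
score_table$energy_rank <- rank(-score_table$tm_score +
                                  rnorm(nrow(score_table), sd = 0.15),
                                ties.method = "first")
imp <- top_k_impact(qa$profiles, score_table, th, "long", k = 5)

summary <- data.frame(
  n_decoys = s$n_decoys,
  threshold = as.numeric(th),
  auc_long = aucs["long"], auc_short = aucs["short"], auc_all = aucs["all"],
  proportion_correct_before = s$proportion_correct_before,
  proportion_correct_after = s$proportion_correct_after,
  enrichment_factor = s$enrichment_factor,
  false_negatives = s$false_negatives,
  fn_rate = s$false_negatives / s$n_correct,
  best_tm_before = imp$best_tm_before, best_tm_after = imp$best_tm_after,
  top5_tm_before = imp$topk_tm_before, top5_tm_after = imp$topk_tm_after)
write_tsv_report(summary, file.path(out, "qa_ensemble_summary.tsv"))

cat(sprintf("\nEnsemble-level QA (n = %d, %.0f%% correct):\n",
            s$n_decoys, 100 * s$proportion_correct_before))
cat(sprintf("  ROC AUC  long %.3f | all %.3f | short %.3f  (long is best)\n",
            aucs["long"], aucs["all"], aucs["short"]))
cat(sprintf("  balanced threshold %.3f: correct %.1f%% -> %.1f%% (%.1fx), FN rate %.1f%%\n",
            as.numeric(th), 100 * s$proportion_correct_before,
            100 * s$proportion_correct_after, s$enrichment_factor,
            100 * s$false_negatives / s$n_correct))
cat(sprintf("  best TM %.3f -> %.3f; energy-top-5 TM %.3f -> %.3f\n",
            imp$best_tm_before, imp$best_tm_after,
            imp$topk_tm_before, imp$topk_tm_after))
cat("Wrote results/qa_per_target.tsv, qa_correlation.tsv, qa_ensemble_summary.tsv\n")
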