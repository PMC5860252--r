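qa_fixture <- function(seed = 1, n = 400, prop = 0.2) {
  make_qa_ensemble(generator_config(seed = seed, qa_n = n,
                                    qa_prop_correct = prop))
}

test_that("satisfaction profiles count satisfied pairs per range class", {
  nat <- make_native(generator_config(seed = 6, L = 60,
                                      topology = "beta_hairpin_stack"))
  truth <- extract_contacts(nat)
  sub <- truth[seq(1, nrow(truth), by = 3), ]
  preds <- prediction_list(sub$i, sub$j, seq_len(nrow(sub)),
                           target_id = nat$id)
  # native satisfies every predicted true contact
  prof <- satisfaction_profile(nat, preds)
  expect_equal(prof$sat_all, 1)
  expect_equal(prof$n_pred_all, min(nrow(sub), 60))
  # an extended chain has no long-range contact at all
  ext_ca <- cbind(3.8 * (0:59), 0, 0)
  ext <- structure_model("ext", nat$sequence, ext_ca, NULL)
  longp <- truth[truth$range == "long", ]
  prof2 <- satisfaction_profile(ext, prediction_list(longp$i, longp$j,
                                                     seq_len(nrow(longp))))
  expect_equal(prof2$sat_long, 0)
  expect_true(is.na(prof2$sat_short))  # no short predictions: undefined
})

test_that("planted satisfied subsets are recovered exactly", {
  # decoy = native, predictions = k true contacts + (n - k) far-apart pairs
  nat <- make_native(generator_config(seed = 26, L = 80,
                                      topology = "beta_hairpin_stack"))
  truth <- extract_contacts(nat)
  k <- 12; n <- 30
  rep <- representative_coords(nat, warn = FALSE)
  cand <- all_pairs <- expand.grid(i = 1:80, j = 1:80)
  cand <- cand[cand$j - cand$i >= 5, ]
  dd <- sqrt(rowSums((rep[cand$i, ] - rep[cand$j, ])^2))
  far <- cand[dd > 9, ][seq_len(n - k), ]
  pl <- prediction_list(c(truth$i[1:k], far$i), c(truth$j[1:k], far$j),
                        seq_len(n))
  prof <- satisfaction_profile(nat, pl, top_n = n)
  expect_equal(prof$sat_all, k / n)
})

test_that("classification keeps by threshold and flags undefined measures", {
  qa <- qa_fixture()
  dec0 <- classify_decoys(qa$profiles, 0, "long")
  expect_true(all(dec0$kept))
  over <- classify_decoys(qa$profiles, max(qa$profiles$sat_long) + 0.01, "long")
  expect_false(any(over$kept))
  # monotone: raising the threshold never adds kept decoys
  kept_at <- function(t) classify_decoys(qa$profiles, t, "long")$kept
  for (t in c(0.2, 0.4, 0.6)) {
    expect_true(all(kept_at(t + 0.2) <= kept_at(t)))
  }
  # undefined satisfaction is discarded with a flag
  p <- qa$profiles[1:3, ]
  p$sat_long[2] <- NA
  d <- classify_decoys(p, 0, "long")
  expect_false(d$kept[2])
  expect_true(d$undefined_measure[2])
})

test_that("optimal_threshold equals exhaustive scan on random ensembles", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(20:120, 1)
    sat <- round(runif(n), 2)           # ties on purpose
    lab <- runif(n) < 0.3
    if (!any(lab) || all(lab)) next
    prof <- data.frame(decoy_id = as.character(seq_len(n)), sat_long = sat)
    got <- optimal_threshold(prof, lab, "long")
    expect_equal(as.numeric(got), oracle_threshold(sat, lab))
    # reported confusion counts are consistent
    kept <- sat >= as.numeric(got)
    expect_equal(attr(got, "errors"), sum(kept & !lab) + sum(!kept & lab))
  }
})

test_that("optimal_threshold separates separable classes with zero errors", {
  prof <- data.frame(decoy_id = as.character(1:10),
                     sat_long = c(0.9, seq(0.05, 0.45, length.out = 9)))
  lab <- c(TRUE, rep(FALSE, 9))
  th <- optimal_threshold(prof, lab, "long")
  expect_equal(attr(th, "errors"), 0L)
  expect_lte(as.numeric(th), 0.9)
  expect_gt(as.numeric(th), 0.45)
  expect_error(optimal_threshold(prof, rep(TRUE, 10), "long"), "both")
})

test_that("ROC points match naive confusion counts and AUC behaves", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 60
    sat <- round(runif(n), 2)
    lab <- runif(n) < 0.4
    if (!any(lab) || all(lab)) next
    prof <- data.frame(decoy_id = as.character(1:n), sat_long = sat)
    roc <- decoy_roc(prof, lab, "long")
    for (r in sample(nrow(roc), 5)) {
      pt <- oracle_roc_point(sat, lab, roc$threshold[r])
      expect_equal(roc$sensitivity[r], unname(pt["sensitivity"]))
      expect_equal(roc$specificity[r], unname(pt["specificity"]))
    }
    expect_gte(roc_auc(roc), 0); expect_lte(roc_auc(roc), 1)
    # sensitivity is monotone as the threshold decreases
    expect_true(all(diff(roc$sensitivity) <= 0))
  }
})

test_that("AUC is 1 for separable data, 0.5-ish under permuted labels, and
          matches pROC", {
  prof <- data.frame(decoy_id = as.character(1:40),
                     sat_long = c(runif(20, 0.6, 1), runif(20, 0, 0.4)))
  lab <- rep(c(TRUE, FALSE), each = 20)
  expect_equal(roc_auc(decoy_roc(prof, lab, "long")), 1)
  rev <- decoy_roc(prof, !lab, "long")
  expect_equal(roc_auc(rev), 0)
  set.seed(77)
  qa <- qa_fixture(seed = 9, n = 4000, prop = 0.3)
  perm <- sample(qa$truth_labels)
  auc_perm <- roc_auc(decoy_roc(qa$profiles, perm, "long"))
  expect_lt(abs(auc_perm - 0.5), 0.03)
  skip_if_not_installed("pROC")
  auc_ref <- as.numeric(pROC::auc(pROC::roc(
    qa$truth_labels, qa$profiles$sat_long, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(decoy_roc(qa$profiles, qa$truth_labels, "long")),
               auc_ref, tolerance = 1e-9)
})

test_that("filtering summaries report enrichment and failure detection", {
  qa <- qa_fixture(seed = 4, n = 2000, prop = 0.07)
  # keep-all threshold: enrichment 1, no false negatives
  s0 <- summarize_filtering(qa$profiles, qa$truth_labels, 0, "long")
  expect_equal(s0$enrichment_factor, 1)
  expect_equal(s0$false_negatives, 0L)
  expect_false(s0$all_discarded)
  # realistic imbalanced ensemble at its balanced optimal threshold
  th <- optimal_threshold(qa$profiles, qa$truth_labels, "long", balance = TRUE)
  s1 <- summarize_filtering(qa$profiles, qa$truth_labels, th, "long")
  expect_gt(s1$enrichment_factor, 3)
  expect_lt(s1$false_negatives / s1$n_correct, 0.2)
  # zero correct decoys, all below threshold -> all discarded
  bad <- make_qa_ensemble(generator_config(seed = 5, qa_n = 200,
                                           qa_prop_correct = 0))
  thr_hi <- max(bad$profiles$sat_long) + 0.01
  s2 <- summarize_filtering(bad$profiles, bad$truth_labels, thr_hi, "long")
  expect_true(s2$all_discarded)
  expect_true(is.na(s2$enrichment_factor))
  # never all_discarded when any decoy clears the threshold
  s3 <- summarize_filtering(bad$profiles, bad$truth_labels,
                            max(bad$profiles$sat_long), "long")
  expect_false(s3$all_discarded)
})

test_that("top-k impact matches brute-force recomputation", {
  qa <- qa_fixture(seed = 6, n = 50, prop = 0.3)
  set.seed(6)
  st <- data.frame(decoy_id = qa$profiles$decoy_id,
                   tm_score = runif(50),
                   energy_rank = sample(50))
  th <- 0.4
  imp <- top_k_impact(qa$profiles, st, th, "long", k = 5)
  kept <- qa$profiles$sat_long >= th
  top5 <- st$decoy_id[order(st$energy_rank)][1:5]
  expect_equal(imp$best_tm_before, max(st$tm_score))
  expect_equal(imp$topk_tm_before, max(st$tm_score[st$decoy_id %in% top5]))
  expect_equal(imp$best_tm_after, max(st$tm_score[kept]))
  kept_ids <- st[st$decoy_id %in% qa$profiles$decoy_id[kept], ]
  top5k <- kept_ids$decoy_id[order(kept_ids$energy_rank)][seq_len(min(5, nrow(kept_ids)))]
  expect_equal(imp$topk_tm_after, max(st$tm_score[st$decoy_id %in% top5k]))
  # a filter that discards nothing changes nothing
  imp0 <- top_k_impact(qa$profiles, st, 0, "long")
  expect_equal(imp0$best_tm_after, imp0$best_tm_before)
  expect_equal(imp0$topk_tm_after, imp0$topk_tm_before)
  expect_false(imp0$best_discarded)
  # discarding exactly the best decoy is flagged
  best_id <- st$decoy_id[which.max(st$tm_score)]
  prof2 <- qa$profiles
  prof2$sat_long[prof2$decoy_id == best_id] <- 0
  prof2$sat_long[prof2$decoy_id != best_id] <- 0.9
  imp2 <- top_k_impact(prof2, st, 0.5, "long")
  expect_true(imp2$best_discarded)
  expect_lt(imp2$best_tm_after, imp2$best_tm_before)
})

test_that("rank correlations hit the sign cases and planted links", {
  prof <- data.frame(decoy_id = as.character(1:10),
                     sat_all = 1:10 / 10, sat_short = 10:1 / 10,
                     sat_long = 1:10 / 10)
  tm <- seq(0.1, 1, length.out = 10)
  cr <- correlation_report(prof, tm)
  expect_equal(cr$rho[cr$measure == "all"], 1)
  expect_equal(cr$rho[cr$measure == "short"], -1)
  # constant column flagged
  prof$sat_short <- 0.5
  cr2 <- correlation_report(prof, tm)
  expect_true(cr2$degenerate[cr2$measure == "short"])
  expect_true(is.na(cr2$rho[cr2$measure == "short"]))
  # planted monotone link with noise keeps a positive rho
  set.seed(8)
  n <- 300
  tm3 <- runif(n)
  prof3 <- data.frame(decoy_id = as.character(1:n),
                      sat_all = tm3, sat_short = tm3,
                      sat_long = plogis(3 * tm3 + rnorm(n, sd = 0.5)))
  cr3 <- correlation_report(prof3, tm3)
  expect_gt(cr3$rho[cr3$measure == "long"], 0.5)
  expect_error(correlation_report(prof3[1:2, ], tm3[1:2]), "at least 3")
})
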