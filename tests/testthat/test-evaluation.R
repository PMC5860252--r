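make_eval_fixture <- function(seed = 8, L = 80, p = 0.6) {
  nat <- make_native(generator_config(seed = seed, L = L,
                                      topology = "beta_hairpin_stack"))
  truth <- extract_contacts(nat)
  preds <- make_predictions(truth, generator_config(
    seed = seed, L = L, prediction_precision = p, prediction_count = L))
  list(nat = nat, truth = truth, preds = preds)
}

test_that("top_n truncates canonically and tolerates short lists", {
  pl <- prediction_list(c(1, 2, 3, 4), c(9, 9, 9, 9), c(0.5, 0.9, 0.5, 0.1))
  t2 <- top_n(pl, 2)
  expect_equal(t2$score, c(0.9, 0.5))
  expect_equal(t2$i, c(2L, 1L))           # tie at 0.5 broken by ascending i
  all3 <- top_n(pl, 10)[1:3, ]
  expect_equal(nrow(top_n(pl, 10)), 4L)   # fewer available: use all
  expect_equal(all3$i, c(2L, 1L, 3L))
})

test_that("precision counts truth membership and flags empty input", {
  fix <- make_eval_fixture()
  tr <- fix$truth
  five <- prediction_list(c(tr$i[1:3], 1, 1), c(tr$j[1:3], tr$j[1] + 200, 300),
                          5:1)
  expect_equal(as.numeric(contact_precision(five, tr)), 3 / 5)
  exact <- prediction_list(tr$i, tr$j, seq_len(nrow(tr)))
  expect_equal(as.numeric(contact_precision(exact, tr)), 1)
  none <- prediction_list(integer(0), integer(0), numeric(0))
  p0 <- contact_precision(none, tr)
  expect_true(is.na(p0))                  # undefined, not zero
  expect_equal(attr(p0, "n_considered"), 0L)
})

test_that("constructed precision is recovered exactly", {
  fix <- make_eval_fixture(seed = 21, L = 100, p = 0.7)
  expect_equal(as.numeric(contact_precision(fix$preds, fix$truth)), 0.7)
})

test_that("spread matches run enumeration on crafted and random cases", {
  nat <- make_native(generator_config(seed = 3, L = 100,
                                      topology = "beta_hairpin_stack"))
  truth <- extract_contacts(nat)
  L <- 100
  # single correct contact (10, 40): runs 1-9, 11-39, 41-100
  pair <- truth[truth$i == 10 & truth$j <= 40, ][1, ]
  skip_if(is.na(pair$i))  # topology guarantee, should always hold
  one <- prediction_list(pair$i, pair$j, 1)
  expect_equal(contact_spread(one, truth, L),
               max(pair$i - 1, pair$j - pair$i - 1, L - pair$j) / L)
  expect_equal(contact_spread(one, truth, L), oracle_spread(one, truth, L))
  # no correct predictions -> spread 1
  wrong <- prediction_list(1, 200, 1)
  expect_equal(contact_spread(wrong, truth, L), 1)
  # random prediction sets agree with the oracle; spread shrinks as
  # correct contacts accumulate
  prev <- 1
  for (k in c(1, 3, 10, 30)) {
    set.seed(k)
    sub <- truth[sample(nrow(truth), k), ]
    pl <- prediction_list(sub$i, sub$j, seq_len(k))
    s <- contact_spread(pl, truth, L)
    expect_equal(s, oracle_spread(pl, truth, L))
  }
  cum <- NULL
  set.seed(42)
  ord <- sample(nrow(truth))
  spreads <- vapply(c(1, 5, 20, 60), function(k) {
    sub <- truth[ord[seq_len(k)], ]
    contact_spread(prediction_list(sub$i, sub$j, seq_len(k)), truth, L)
  }, numeric(1))
  expect_true(all(diff(spreads) <= 0))    # weakly decreasing
})

test_that("endpoint runs count toward the spread", {
  nat <- make_native(generator_config(seed = 3, L = 100,
                                      topology = "beta_hairpin_stack"))
  truth <- extract_contacts(nat)
  # cover only residues near both termini: interior run dominates
  a <- truth[truth$i <= 2, ][1, ]
  b <- truth[truth$j >= 99, ][1, ]
  pl <- prediction_list(c(a$i, b$i), c(a$j, b$j), c(2, 1))
  expect_equal(contact_spread(pl, truth, 100),
               oracle_spread(pl, truth, 100))
})

test_that("evaluate_target mirrors a straight-line recomputation", {
  fix <- make_eval_fixture(seed = 13, L = 60, p = 0.5)
  rep <- evaluate_target(fix$preds, fix$nat)
  L <- 60
  # independent recomputation: sort, truncate, count
  ord <- order(-fix$preds$score, fix$preds$i, fix$preds$j)
  sorted <- fix$preds[ord, ]
  key <- paste(fix$truth$i, fix$truth$j)
  for (r in seq_len(nrow(rep$fractions))) {
    n <- max(1, ceiling(rep$fractions$fraction[r] * L))
    sub <- sorted[seq_len(min(n, nrow(sorted))), ]
    expect_equal(rep$fractions$precision[r],
                 mean(paste(sub$i, sub$j) %in% key))
  }
  topL <- sorted[seq_len(min(L, nrow(sorted))), ]
  sep <- topL$j - topL$i
  for (cls in c("short", "long")) {
    sel <- if (cls == "short") sep <= 23 else sep > 23
    want <- if (any(sel)) mean(paste(topL$i, topL$j)[sel] %in% key) else NA_real_
    got <- if (cls == "short") rep$short_precision else rep$long_precision
    expect_equal(got, want)
  }
})

test_that("perfect predictors score 1 everywhere; empty classes are flagged", {
  nat <- make_native(generator_config(seed = 9, L = 50))
  truth <- extract_contacts(nat)
  perfect <- prediction_list(truth$i, truth$j, rev(seq_len(nrow(truth))),
                             target_id = nat$id)
  rep <- evaluate_target(perfect, nat)
  expect_true(all(rep$fractions$precision == 1))
  expect_equal(rep$spread, contact_spread(top_n(perfect, 50), truth, 50))
  # short-range-only predictor: long precision undefined
  short_only <- truth[truth$range == "short", ]
  rep2 <- evaluate_target(
    prediction_list(short_only$i, short_only$j, seq_len(nrow(short_only))), nat)
  expect_true(is.na(rep2$long_precision))
  expect_equal(rep2$n_long_considered, 0L)
})

test_that("out-of-chain predictions are excluded or penalized as asked", {
  nat <- make_native(generator_config(seed = 9, L = 50))
  truth <- extract_contacts(nat)
  good <- truth[1:4, ]
  pl <- prediction_list(c(good$i, 10), c(good$j, 70), c(5:2, 1))
  ex <- evaluate_target(pl, nat)            # default: exclude
  pe <- evaluate_target(pl, nat, unresolved = "penalize")
  expect_equal(ex$fractions$precision[4], 1)
  expect_equal(pe$fractions$precision[4], 4 / 5)
})

test_that("ss breakdown proportions normalize and match hand counts", {
  nat <- make_native(generator_config(seed = 17, L = 60,
                                      topology = "beta_hairpin_stack"))
  set.seed(17)
  ss <- ss_string(paste(sample(c("H", "E", "C"), 60, replace = TRUE),
                        collapse = ""))
  truth <- extract_contacts(nat, ss = ss)
  preds <- make_predictions(truth, generator_config(
    seed = 18, L = 60, prediction_precision = 0.8, prediction_count = 40))
  bd <- ss_breakdown(preds, truth, ss)
  expect_equal(sum(bd$predicted_proportion), 1, tolerance = 1e-12)
  expect_equal(sum(bd$true_proportion), 1, tolerance = 1e-12)
  expect_equal(bd$category, ss_category_levels())
  expect_true(all(is.na(bd$precision) | (bd$precision >= 0 & bd$precision <= 1)))
  # one prediction per category -> each predicted proportion 1/6
  cats <- ss_category(truth$i, truth$j, ss)
  picks <- truth[match(ss_category_levels(), cats), ]
  skip_if(anyNA(picks$i))
  bd6 <- ss_breakdown(prediction_list(picks$i, picks$j, 6:1), truth, ss)
  expect_equal(bd6$predicted_proportion, rep(1 / 6, 6))
  expect_equal(bd6$precision, rep(1, 6))
  # all-helix string populates only the helix rows
  allh <- ss_string(paste(rep("H", 60), collapse = ""))
  truth_h <- extract_contacts(nat, ss = allh)
  bdh <- ss_breakdown(preds, truth_h, allh)
  expect_equal(bdh$predicted_proportion[bdh$category != "helix-helix"],
               rep(0, 5))
})
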