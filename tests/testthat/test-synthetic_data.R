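test_that("native generators respect geometry constraints per topology", {
  for (topo in c("helix_bundle", "beta_hairpin_stack", "random_coil")) {
    cfg <- generator_config(seed = 31, L = 60, topology = topo)
    nat <- make_native(cfg)
    steps <- sqrt(rowSums(diff(nat$ca)^2))
    expect_true(all(steps >= 3.75 & steps <= 3.85), info = topo)
    d <- as.matrix(dist(nat$ca))
    nonconsec <- abs(row(d) - col(d)) > 1
    expect_gt(min(d[nonconsec]), 2.5)
    # C-beta placement: 1.53 A from C-alpha except glycine
    has_cb <- !is.na(nat$cb[, 1])
    aa <- strsplit(nat$sequence, "")[[1]]
    expect_true(all(!has_cb[aa == "G"]))
    cblen <- sqrt(rowSums((nat$cb[has_cb, ] - nat$ca[has_cb, ])^2))
    expect_equal(cblen, rep(1.53, sum(has_cb)), tolerance = 1e-9)
  }
  # compact topologies guarantee long-range contacts
  for (topo in c("helix_bundle", "beta_hairpin_stack")) {
    cs <- extract_contacts(make_native(generator_config(seed = 32, L = 40,
                                                        topology = topo)))
    expect_gt(sum(cs$range == "long"), 0, label = topo)
  }
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- generator_config(seed = 33, L = 40, topology = "random_coil",
                          decoy_noise_sigmas = 1, n_decoys_per_sigma = 2L)
  a <- make_native(cfg); b <- make_native(cfg)
  expect_identical(a$ca, b$ca)
  expect_identical(a$sequence, b$sequence)
  expect_identical(make_decoys(a, cfg)[[2]]$ca, make_decoys(b, cfg)[[2]]$ca)
  m1 <- make_msa(cfg); m2 <- make_msa(cfg)
  expect_identical(m1$rows, m2$rows)
  q1 <- make_qa_ensemble(cfg); q2 <- make_qa_ensemble(cfg)
  expect_identical(q1$profiles$sat_long, q2$profiles$sat_long)
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(make_native(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("decoy ensembles degrade with noise and keep ideal bonds", {
  cfg <- generator_config(seed = 34, L = 40, decoy_noise_sigmas = c(0, 2, 8),
                          n_decoys_per_sigma = 4L)
  nat <- make_native(cfg)
  dec <- make_decoys(nat, cfg)
  sig <- vapply(dec, attr, numeric(1), "sigma")
  expect_identical(dec[[1]]$ca, nat$ca)          # sigma 0: exact copy
  tm <- vapply(dec, function(d) tm_score(d, nat)$tm, numeric(1))
  expect_true(all(tm[sig == 0] == 1))
  means <- tapply(tm, sig, mean)
  expect_true(all(diff(means) < 0))              # rank-ordered by sigma
  for (d in dec[sig == 2]) {
    steps <- sqrt(rowSums(diff(d$ca)^2))
    expect_equal(steps, rep(3.8, 39), tolerance = 1e-9)  # re-idealized
  }
})

test_that("high noise pushes decoys below the correctness cutoff", {
  cfg <- generator_config(seed = 35, L = 60, decoy_noise_sigmas = 10,
                          n_decoys_per_sigma = 10L)
  nat <- make_native(cfg)
  tm <- vapply(make_decoys(nat, cfg), function(d) tm_score(d, nat)$tm,
               numeric(1))
  expect_lt(mean(tm), 0.4)
})

test_that("prediction generator hits precision exactly and errors when
          infeasible", {
  nat <- make_native(generator_config(seed = 36, L = 80,
                                      topology = "beta_hairpin_stack"))
  truth <- extract_contacts(nat)
  for (p in c(0.1, 0.5, 0.9, 1)) {
    pl <- make_predictions(truth, generator_config(
      seed = 36, L = 80, prediction_precision = p, prediction_count = 50))
    expect_equal(as.numeric(contact_precision(pl, truth)), p)
  }
  # precision 1 with count == |truth| reproduces the truth set
  pl <- make_predictions(truth, generator_config(
    seed = 37, L = 80, prediction_precision = 1,
    prediction_count = nrow(truth)))
  expect_equal(nrow(pl), nrow(truth))
  expect_true(all(in_contact_set(pl$i, pl$j, truth)))
  expect_error(make_predictions(truth, generator_config(
    seed = 38, L = 80, prediction_precision = 1,
    prediction_count = nrow(truth) + 1)), "only")
})

test_that("the range mix of generated predictions is controllable", {
  nat <- make_native(generator_config(seed = 39, L = 80,
                                      topology = "beta_hairpin_stack"))
  truth <- extract_contacts(nat)
  pl <- make_predictions(truth, generator_config(
    seed = 39, L = 80, prediction_precision = 0.5, prediction_count = 40,
    long_range_fraction = 0.25))
  rng <- range_class(pl$i, pl$j)
  expect_equal(sum(rng == "long"), 10L)
})

test_that("spread targets are realized within one residue", {
  for (s in c(0.2, 0.5, 0.9)) {
    # wide uncovered windows leave few true contacts to pick from, so the
    # correct-entry budget shrinks with the spread target
    p <- if (s > 0.8) 0.1 else 0.4
    cfg <- generator_config(seed = 40, L = 100,
                            topology = "beta_hairpin_stack",
                            prediction_precision = p,
                            prediction_count = 60, spread_target = s)
    nat <- make_native(cfg)
    truth <- extract_contacts(nat)
    pl <- make_predictions(truth, cfg)
    expect_equal(as.numeric(contact_precision(pl, truth)), p)
    expect_lte(abs(contact_spread(pl, truth, 100) - s), 1 / 100)
  }
  expect_error(make_predictions(
    extract_contacts(make_native(generator_config(seed = 41, L = 100,
                                                  topology = "beta_hairpin_stack"))),
    generator_config(seed = 41, L = 100, prediction_precision = 0.4,
                     prediction_count = 60, spread_target = 0.97)),
    "spread_target")
})

test_that("msa generator honours cluster counts and rejects tiny alphabets", {
  m <- make_msa(generator_config(seed = 42, msa_n = 50L, msa_clusters = 5L))
  expect_equal(length(m$rows), 50L)
  expect_equal(compute_neff(m)$neff, 5)
  expect_error(make_msa(generator_config(seed = 42, msa_n = 5L,
                                         msa_clusters = 2L, msa_ncol = 4L)),
               "columns")
})

test_that("qa ensembles separate classes as configured", {
  qa <- make_qa_ensemble(generator_config(seed = 43, qa_n = 3000))
  expect_equal(sum(qa$truth_labels), round(0.07 * 3000))
  auc_l <- roc_auc(decoy_roc(qa$profiles, qa$truth_labels, "long"))
  expect_gt(auc_l, 0.85)
  # identical class distributions: no signal
  null_qa <- make_qa_ensemble(generator_config(
    seed = 44, qa_n = 3000, qa_prop_correct = 0.3,
    qa_beta_long_correct = c(2, 6), qa_beta_long_incorrect = c(2, 6)))
  auc_null <- roc_auc(decoy_roc(null_qa$profiles, null_qa$truth_labels, "long"))
  expect_lt(abs(auc_null - 0.5), 0.05)
})
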