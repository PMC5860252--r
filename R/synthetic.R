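#' Configuration for the synthetic-data generators
#'
#' One seeded configuration object drives every generator so that a fixed
#' seed reproduces a whole study end to end. Defaults define the standard
#' desk-scale test conditions: a 60-residue target, decoy noise levels of
#' 0.5/2/5 Angstrom with 20 decoys each, and a quality-assessment testbed
#' of 10 000 decoys of which 7% are correct, with correct decoys drawing
#' their long-range satisfaction from Beta(8, 4) against Beta(2, 6) for
#' incorrect ones and a deliberately weaker short-range separation
#' (Beta(5, 5) vs Beta(3, 6)), so that long-range satisfaction is the
#' more informative classifier.
#'
#' @param seed Integer seed; fixed seed implies identical output.
#' @param L Target length.
#' @param topology `"helix_bundle"`, `"beta_hairpin_stack"` or
#'   `"random_coil"`.
#' @param decoy_noise_sigmas Gaussian C-alpha noise levels (Angstrom).
#' @param n_decoys_per_sigma Decoys generated per noise level.
#' @param prediction_precision Fraction of generated predictions that are
#'   true contacts.
#' @param prediction_count Number of predictions (default L).
#' @param long_range_fraction Optional fraction of long-range pairs among
#'   both correct and incorrect predictions.
#' @param spread_target Optional spread the correct predictions should
#'   realize (see [make_predictions()]).
#' @param msa_n Number of alignment rows.
#' @param msa_clusters Number of mutually dissimilar sequence clusters.
#' @param msa_ncol Alignment columns.
#' @param qa_n,qa_prop_correct Size and correct fraction of the
#'   quality-assessment ensemble.
#' @param qa_beta_long_correct,qa_beta_long_incorrect,qa_beta_short_correct,qa_beta_short_incorrect
#'   Beta shape pairs for the satisfaction distributions.
#' @param qa_n_pred_long,qa_n_pred_short Predictions per range class
#'   underlying the simulated fractions.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, L = 60L,
                             topology = c("helix_bundle", "beta_hairpin_stack",
                                          "random_coil"),
                             decoy_noise_sigmas = c(0.5, 2, 5),
                             n_decoys_per_sigma = 20L,
                             prediction_precision = 0.7,
                             prediction_count = NULL,
                             long_range_fraction = NULL,
                             spread_target = NULL,
                             msa_n = 50L, msa_clusters = 5L, msa_ncol = 40L,
                             qa_n = 10000L, qa_prop_correct = 0.07,
                             qa_beta_long_correct = c(8, 4),
                             qa_beta_long_incorrect = c(2, 6),
                             qa_beta_short_correct = c(5, 5),
                             qa_beta_short_incorrect = c(3, 6),
                             qa_n_pred_long = 30L, qa_n_pred_short = 30L) {
  topology <- match.arg(topology)
  stopifnot(L >= 10, seed == round(seed),
            prediction_precision >= 0, prediction_precision <= 1,
            is.null(long_range_fraction) ||
              (long_range_fraction >= 0 && long_range_fraction <= 1),
            is.null(spread_target) || (spread_target >= 0 && spread_target <= 1),
            msa_clusters <= msa_n, msa_n >= 1,
            qa_prop_correct >= 0, qa_prop_correct <= 1)
  structure(as.list(environment()), class = "generator_config")
}

# evaluate code under a given seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  code
}

CA_STEP <- 3.8       # consecutive C-alpha spacing, Angstrom
CB_LENGTH <- 1.53    # C-alpha to C-beta bond length, Angstrom
CLASH_DIST <- 2.5    # forbidden non-consecutive C-alpha distance

unitv <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# pseudo-tetrahedral C-beta direction from the C-alpha trace
place_cb <- function(ca) {
  L <- nrow(ca)
  cb <- matrix(NA_real_, L, 3)
  for (k in seq_len(L)) {
    if (k == 1) {
      b <- unitv(ca[2, ] - ca[1, ])
      ref <- if (abs(b[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      dir <- unitv(cross3(b, ref))
    } else if (k == L) {
      b <- unitv(ca[L - 1, ] - ca[L, ])
      ref <- if (abs(b[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      dir <- unitv(cross3(b, ref))
    } else {
      b1 <- unitv(ca[k - 1, ] - ca[k, ])
      b2 <- unitv(ca[k + 1, ] - ca[k, ])
      d <- -(b1 + b2) + cross3(b1, b2)
      if (sum(d^2) < 1e-8) d <- cross3(b1, if (abs(b1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0))
      dir <- unitv(d)
    }
    cb[k, ] <- ca[k, ] + CB_LENGTH * dir
  }
  cb
}

random_sequence <- function(L) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, L, replace = TRUE), collapse = "")
}

# antiparallel bundle of coarse 4-residues-per-turn helices with exact
# step-length junctions (helix length 15 so the end phase faces the next axis)
helix_bundle_trace <- function(L) {
  rise <- 1.6
  r <- sqrt((CA_STEP^2 - rise^2) / 2)
  n_h <- 15L                     # 3 (mod 4): start phase 180, end phase 0;
                                 # facing inter-helix pairs reach separation
                                 # 2k+1 <= 25, so L >= 28 guarantees a
                                 # long-range contact
  axis_gap <- 2 * r + CA_STEP
  z_top <- rise * (n_h - 1)
  ca <- matrix(0, L, 3)
  for (t in seq_len(L)) {
    h <- (t - 1) %/% n_h        # 0-based helix index
    k <- (t - 1) %% n_h
    phase <- pi + (pi / 2) * k
    up <- h %% 2 == 0
    ca[t, ] <- c(h * axis_gap + r * cos(phase),
                 r * sin(phase),
                 if (up) rise * k else z_top - rise * k)
  }
  ca
}

# boustrophedon grid meander: rows of 4 along x, 4 rows per layer along y,
# layers stacked along z; every grid edge is one 3.8 A step, so short- and
# long-range contacts occur all along the chain
hairpin_stack_trace <- function(L) {
  nx <- 4L; ny <- 4L
  ca <- matrix(0, L, 3)
  for (t in seq_len(L)) {
    u <- t - 1L
    layer <- u %/% (nx * ny)
    rem <- u %% (nx * ny)
    row <- rem %/% nx
    col <- rem %% nx
    arow <- if (layer %% 2 == 0) row else ny - 1L - row
    acol <- if (row %% 2 == 0) col else nx - 1L - col
    ca[t, ] <- CA_STEP * c(acol, arow, layer)
  }
  ca
}

# self-avoiding random walk with fixed step length
random_coil_trace <- function(L, max_restart = 20L) {
  for (attempt in seq_len(max_restart)) {
    ca <- matrix(0, L, 3)
    dir <- unitv(stats::rnorm(3))
    ca[2, ] <- ca[1, ] + CA_STEP * dir
    ok <- TRUE
    for (k in 3:L) {
      placed <- FALSE
      for (try in 1:100) {
        cand_dir <- unitv(dir + 0.8 * stats::rnorm(3))
        cand <- ca[k - 1, ] + CA_STEP * cand_dir
        prev <- ca[seq_len(k - 2), , drop = FALSE]
        if (min(sqrt(rowSums((prev - matrix(cand, nrow(prev), 3,
                                            byrow = TRUE))^2))) > CLASH_DIST) {
          ca[k, ] <- cand; dir <- cand_dir; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(ca)
  }
  stop("could not grow a self-avoiding chain; infeasible configuration")
}

#' Generate a synthetic native structure
#'
#' Builds an idealized C-alpha trace for the requested topology
#' (consecutive spacing 3.8 Angstrom within 0.05, no non-consecutive
#' C-alpha pair closer than 2.5 Angstrom), places pseudo-tetrahedral
#' C-betas at 1.53 Angstrom, and assigns a random amino-acid sequence
#' (glycines keep no C-beta). The `helix_bundle` and
#' `beta_hairpin_stack` topologies are compact and guarantee at least one
#' long-range contact; `random_coil` is a self-avoiding walk with no
#' contact guarantee. Fully deterministic for a fixed config seed.
#'
#' @param config A [generator_config()].
#' @return A [structure_model()].
#' @export
make_native <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    L <- as.integer(config$L)
    ca <- switch(config$topology,
                 helix_bundle = helix_bundle_trace(L),
                 beta_hairpin_stack = hairpin_stack_trace(L),
                 random_coil = random_coil_trace(L))
    steps <- sqrt(rowSums(diff(ca)^2))
    if (any(steps < CA_STEP - 0.05 | steps > CA_STEP + 0.05)) {
      stop("internal error: irregular backbone spacing")
    }
    d <- as.matrix(stats::dist(ca))
    nonconsec <- abs(row(d) - col(d)) > 1
    if (any(d[nonconsec] < CLASH_DIST)) {
      stop("internal error: steric clash in generated trace")
    }
    seqc <- random_sequence(L)
    id <- sprintf("synth_%s_L%d_seed%d", config$topology, L, config$seed)
    mdl <- structure_model(id, seqc, ca, place_cb(ca))
    if (config$topology != "random_coil") {
      cs <- extract_contacts(mdl)
      if (!any(cs$range == "long")) {
        stop("generated topology produced no long-range contact; increase L")
      }
    }
    mdl
  })
}

#' Generate a graded decoy ensemble from a native structure
#'
#' For each noise level sigma, perturbs the native C-alpha trace with
#' isotropic Gaussian noise and re-idealizes bond lengths by walking the
#' chain with fixed 3.8 Angstrom steps toward the perturbed positions;
#' C-betas are rebuilt from the new trace. Larger sigma gives
#' stochastically lower TM-scores. `sigma = 0` returns exact copies of
#' the native.
#'
#' @param native A [structure_model()].
#' @param config A [generator_config()] (`decoy_noise_sigmas`,
#'   `n_decoys_per_sigma`, `seed`).
#' @return List of [structure_model()]s; each carries attributes `sigma`
#'   and inherits the native sequence.
#' @export
make_decoys <- function(native, config) {
  stopifnot(inherits(native, "structure_model"),
            inherits(config, "generator_config"))
  L <- model_length(native)
  with_seed(config$seed + 1L, {
    out <- list()
    for (sigma in config$decoy_noise_sigmas) {
      for (r in seq_len(config$n_decoys_per_sigma)) {
        id <- sprintf("%s_decoy_s%g_%03d", native$id, sigma, r)
        if (sigma == 0) {
          d <- native
          d$id <- id
        } else {
          noisy <- native$ca + matrix(stats::rnorm(L * 3, sd = sigma), L, 3)
          ca <- matrix(0, L, 3)
          ca[1, ] <- noisy[1, ]
          for (k in 2:L) {
            ca[k, ] <- ca[k - 1, ] + CA_STEP * unitv(noisy[k, ] - ca[k - 1, ])
          }
          d <- structure_model(id, native$sequence, ca, place_cb(ca))
        }
        attr(d, "sigma") <- sigma
        out[[length(out) + 1L]] <- d
      }
    }
    out
  })
}

all_candidate_pairs <- function(L, min_sep = 5L) {
  idx <- which(outer(seq_len(L), seq_len(L), function(i, j) j - i >= min_sep),
               arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2])
}

# greedy chain of truth pairs covering [start, L] with inter-anchor gaps
# of at most a few residues (relies on locally contact-rich topologies)
spread_cover_pairs <- function(truth, start, L, min_sep = 5L, max_jump = 9L) {
  pick <- function(a) {
    js <- truth$j[truth$i == a & truth$j <= a + max_jump]
    if (length(js)) min(js) else NA_integer_
  }
  first <- NA_integer_; anchor <- NA_integer_
  for (a in c(start, start + 1L)) {
    if (!is.na(pick(a))) { anchor <- a; first <- a; break }
  }
  if (is.na(anchor)) return(NULL)
  pairs <- list()
  while (anchor + max_jump <= L) {
    j <- pick(anchor)
    if (is.na(j)) break
    pairs[[length(pairs) + 1L]] <- c(anchor, j)
    anchor <- j
  }
  if (!length(pairs)) return(NULL)
  list(first = first, last = anchor, pairs = do.call(rbind, pairs))
}

#' Generate a prediction list with controlled precision, range mix and
#' spread
#'
#' Constructs exactly `round(precision * count)` entries drawn from the
#' true contacts and fills the remainder with non-contact pairs of
#' separation at least 5, so that the overall precision is recovered
#' exactly whenever `precision * count` is integral. Scores are random
#' uniforms, so correct and incorrect entries interleave and every top-N
#' truncation has approximately the overall precision. When
#' `long_range_fraction` is set it fixes the fraction of long-range pairs
#' among the correct and among the incorrect entries. When
#' `spread_target` is set, all correct entries are confined to the
#' trailing window of the chain so that the longest uncovered run -- the
#' spread -- equals the target within one residue (requires a locally
#' contact-rich native such as the `beta_hairpin_stack` topology, and
#' `spread_target * L >= 10`); infeasible requests raise an error.
#'
#' @param truth A `contact_set` from [extract_contacts()].
#' @param config A [generator_config()] (`prediction_precision`,
#'   `prediction_count`, `long_range_fraction`, `spread_target`, `seed`).
#' @return A [prediction_list()].
#' @export
make_predictions <- function(truth, config) {
  stopifnot(inherits(truth, "contact_set"), inherits(config, "generator_config"))
  L <- attr(truth, "L")
  crit <- attr(truth, "criteria")
  if (is.null(crit)) crit <- contact_criteria()
  with_seed(config$seed + 2L, {
    count <- if (is.null(config$prediction_count)) L else as.integer(config$prediction_count)
    n_true <- round(config$prediction_precision * count)
    if (n_true > nrow(truth)) {
      stop(sprintf("requested %d true entries but only %d true contacts exist",
                   n_true, nrow(truth)))
    }
    cand <- all_candidate_pairs(L, crit$min_separation)
    is_true <- in_contact_set(cand$i, cand$j, truth)
    false_pool <- cand[!is_true, , drop = FALSE]
    n_false <- count - n_true
    if (n_false > nrow(false_pool)) {
      stop("not enough non-contact pairs for the requested count")
    }

    pick_mix <- function(pool, n, what) {
      if (is.null(config$long_range_fraction) || n == 0) {
        return(pool[sample(nrow(pool), n), , drop = FALSE])
      }
      rng <- range_class(pool$i, pool$j, crit)
      n_long <- round(config$long_range_fraction * n)
      long_pool <- pool[rng == "long", , drop = FALSE]
      short_pool <- pool[rng == "short", , drop = FALSE]
      if (n_long > nrow(long_pool) || n - n_long > nrow(short_pool)) {
        stop("infeasible long_range_fraction for the ", what, " entries")
      }
      rbind(long_pool[sample(nrow(long_pool), n_long), , drop = FALSE],
            short_pool[sample(nrow(short_pool), n - n_long), , drop = FALSE])
    }

    if (!is.null(config$spread_target)) {
      g <- round(config$spread_target * L)
      if (L - g < 10) {
        stop("spread_target too large: fewer than 10 residues remain for coverage")
      }
      if (g < 10) {
        stop("spread_target too small: the uncovered run must span at least 10 residues")
      }
      truth_df <- as.data.frame(truth)
      window_truth <- truth_df[truth_df$i > g, , drop = FALSE]
      cov <- spread_cover_pairs(window_truth, g + 1L, L, crit$min_separation)
      if (is.null(cov)) {
        stop("spread_target infeasible: no coverage chain of true contacts in the window")
      }
      base <- unique(as.data.frame(cov$pairs) |> stats::setNames(c("i", "j")))
      if (nrow(base) > n_true) {
        stop(sprintf("spread_target needs %d true entries but precision*count allows %d",
                     nrow(base), n_true))
      }
      key_base <- paste(base$i, base$j)
      extra_pool <- window_truth[!(paste(window_truth$i, window_truth$j) %in% key_base),
                                 , drop = FALSE]
      n_extra <- n_true - nrow(base)
      if (n_extra > nrow(extra_pool)) {
        stop("spread_target infeasible: not enough true contacts inside the window")
      }
      extra <- extra_pool[sample(nrow(extra_pool), n_extra), c("i", "j"), drop = FALSE]
      true_pick <- rbind(base, extra)
      false_pick <- false_pool[sample(nrow(false_pool), n_false), , drop = FALSE]
    } else {
      truth_df <- as.data.frame(truth)[, c("i", "j")]
      true_pick <- pick_mix(truth_df, n_true, "correct")
      false_pick <- pick_mix(false_pool, n_false, "incorrect")
    }
    all_pick <- rbind(true_pick[, c("i", "j")], false_pick[, c("i", "j")])
    prediction_list(all_pick$i, all_pick$j, stats::runif(nrow(all_pick)),
                    target_id = attr(truth, "target_id"),
                    provenance = sprintf("synthetic_p%.2f", config$prediction_precision))
  })
}

#' Generate an alignment with an analytically known Neff
#'
#' Builds `msa_clusters` random centroid sequences that are mutually less
#' than 80% identical (verified, regenerated a bounded number of times)
#' and duplicates them to `msa_n` total rows, so hard-clustering Neff at
#' the 0.8 threshold equals the number of clusters exactly.
#'
#' @param config A [generator_config()] (`msa_n`, `msa_clusters`,
#'   `msa_ncol`, `seed`).
#' @return An [msa()].
#' @export
make_msa <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  k <- as.integer(config$msa_clusters)
  n <- as.integer(config$msa_n)
  nc <- as.integer(config$msa_ncol)
  if (nc < 10) stop("alphabet too small for the requested divergence: use >= 10 columns")
  with_seed(config$seed + 3L, {
    for (attempt in 1:50) {
      centroids <- vapply(seq_len(k), function(x) random_sequence(nc), character(1))
      ok <- TRUE
      if (k > 1) {
        m <- do.call(rbind, strsplit(centroids, ""))
        for (a in seq_len(k - 1)) {
          idents <- rowMeans(m[(a + 1):k, , drop = FALSE] ==
                               matrix(m[a, ], k - a, nc, byrow = TRUE))
          if (any(idents >= 0.8)) { ok <- FALSE; break }
        }
      }
      if (ok) break
      if (attempt == 50) stop("could not generate mutually dissimilar centroids")
    }
    sizes <- rep(n %/% k, k)
    if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    rows <- rep(centroids, times = sizes)
    msa(rows, ids = sprintf("cluster%d_copy%d",
                            rep(seq_len(k), times = sizes),
                            unlist(lapply(sizes, seq_len))))
  })
}

#' Generate an imbalanced decoy quality-assessment testbed
#'
#' Simulates satisfaction profiles for an ensemble in which a small
#' fraction of decoys is correct and correct decoys draw stochastically
#' higher satisfaction fractions than incorrect ones, with a larger
#' class separation for the long-range measure than for the short-range
#' one. This is the controlled substrate for threshold fitting, ROC
#' construction, enrichment and failure detection.
#'
#' @param config A [generator_config()] (`qa_*` fields, `seed`).
#' @return List with elements `profiles` (a satisfaction-profile data
#'   frame) and `truth_labels` (logical, `TRUE` = correct decoy).
#' @export
make_qa_ensemble <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 4L, {
    n <- as.integer(config$qa_n)
    n_correct <- round(config$qa_prop_correct * n)
    lab <- sample(c(rep(TRUE, n_correct), rep(FALSE, n - n_correct)))
    draw <- function(shapes_pos, shapes_neg) {
      x <- numeric(n)
      x[lab] <- stats::rbeta(sum(lab), shapes_pos[1], shapes_pos[2])
      x[!lab] <- stats::rbeta(sum(!lab), shapes_neg[1], shapes_neg[2])
      x
    }
    sat_long <- draw(config$qa_beta_long_correct, config$qa_beta_long_incorrect)
    sat_short <- draw(config$qa_beta_short_correct, config$qa_beta_short_incorrect)
    nl <- config$qa_n_pred_long; ns <- config$qa_n_pred_short
    profiles <- data.frame(
      decoy_id = sprintf("qa_decoy_%05d", seq_len(n)),
      sat_all = (nl * sat_long + ns * sat_short) / (nl + ns),
      sat_short = sat_short,
      sat_long = sat_long,
      n_pred_all = nl + ns,
      n_pred_short = ns,
      n_pred_long = nl,
      stringsAsFactors = FALSE)
    list(profiles = profiles, truth_labels = lab)
  })
}
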