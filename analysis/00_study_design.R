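# Shared design of the synthetic desk-scale study, sourced by the
# numbered drivers. Everything is derived from STUDY_SEED so each driver
# can regenerate its inputs independently and reproducibly.

library(contactqa)

STUDY_SEED <- 2016L

# target set: compact topologies across a range of lengths
study_targets <- function() {
  spec <- data.frame(
    id = sprintf("T%02d", 1:8),
    topology = rep(c("helix_bundle", "beta_hairpin_stack"), 4),
    L = c(45, 48, 60, 64, 75, 80, 90, 96),
    stringsAsFactors = FALSE)
  spec$seed <- STUDY_SEED + seq_len(nrow(spec))
  spec
}

build_native <- function(row) {
  make_native(generator_config(seed = row$seed, L = row$L,
                               topology = row$topology))
}

# idealized three-state string matching the generator geometry: helix
# bodies H with coil junctions; meander rows E with coil turns
build_ss <- function(row) {
  L <- row$L
  states <- if (row$topology == "helix_bundle") {
    k <- (seq_len(L) - 1) %% 15
    ifelse(k == 0 | k == 14, "C", "H")
  } else {
    col <- ((seq_len(L) - 1) %% 16) %% 4
    ifelse(col == 0 | col == 3, "C", "E")
  }
  ss_string(paste(states, collapse = ""), target_id = row$id)
}

# predictor panel: graded precision and long-range propensity, emulating
# a spectrum from sparse/precise to dense/noisy coevolution methods
predictor_panel <- function() {
  # long-range mixes stay below the ~25% long-range share of the most
  # helix-rich study targets so every request is feasible
  data.frame(
    predictor = c("precise_sparse", "precise_dense", "balanced",
                  "short_biased", "noisy"),
    precision = c(0.9, 0.75, 0.6, 0.5, 0.25),
    long_range_fraction = c(0.25, 0.22, 0.2, 0.05, 0.2),
    stringsAsFactors = FALSE)
}

build_predictions <- function(truth, row, panel_row, count = NULL) {
  make_predictions(truth, generator_config(
    seed = row$seed * 10L + match(panel_row$predictor,
                                  predictor_panel()$predictor),
    L = row$L,
    prediction_precision = panel_row$precision,
    prediction_count = if (is.null(count)) row$L else count,
    long_range_fraction = panel_row$long_range_fraction))
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}
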