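---
title: "Evaluating predicted contacts and filtering decoys by contact satisfaction"
author: "contactqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating predicted contacts and filtering decoys by contact satisfaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactqa)
```

## The problem

Coevolution-based contact predictors emit ranked lists of residue pairs
expected to be spatially close in a protein's native structure. Two
questions follow. First, how good is a prediction list, measured against
the native structure? Second, once predictions exist, can they judge
candidate 3-D models (*decoys*) without knowing the native structure --
in particular, can the fraction of predicted contacts a decoy *satisfies*
separate correct models from incorrect ones, enrich a decoy ensemble and
reveal targets where modelling failed outright?

`contactqa` implements both stages, plus seeded synthetic generators that
construct inputs with *known* precision, spread, Neff and class
separation, so every metric can be validated against an analytic ground
truth at desk scale.

## Contact definition

Two residues are in contact when their representative atoms -- the
C-beta, or the C-alpha for glycine -- are **strictly** less than 8
Angstrom apart and their sequence separation `|i - j|` is at least 5
(closer pairs are trivial). Contacts with separation 5..23 are *short
range*; separation strictly greater than 23 is *long range*. Both
strict inequalities are unit-tested at the boundary (7.99 vs 8.00 A,
separation 23 vs 24). All three thresholds live in one
`contact_criteria()` object. Residues are indexed 1..L over the observed
chain in order of appearance, the same index space a predictor's
alignment columns live in; author PDB numbering and insertion codes only
influence ordering. Pairs touching residues outside the observed chain
cannot be true contacts; by default they are excluded from precision
denominators (`unresolved = "penalize"` counts them as wrong instead),
so predictors are not punished for crystallographic gaps.

## Evaluation metrics

For a target of length L, `evaluate_target()` reports:

* **Precision (PPV)** of the top `ceiling(f * L)` predictions for
  f = 1/10, 1/5, 1/2, 1 (at least one prediction per fraction; when a
  sparse predictor supplies fewer, all available entries are scored).
  The ceiling avoids empty sets for short chains; the conventional
  evaluation caps consideration at L predictions. With zero assessable
  predictions the precision is `NA`, never 0.
* **Short-/long-range precision** over the top-L entries restricted to
  each separation class of the *predicted* pair.
* **Spread**: the longest run of consecutive residues in which no
  correctly predicted contact touches any residue, as a fraction of L.
  Runs include both termini (a correct-contact-free N-terminal third
  counts), and the metric is computed on the same top-L set as the
  headline precision; no correct prediction at all gives spread 1.
  Low spread means the correct information covers the chain evenly.
* **Secondary-structure breakdown** over the six categories formed by
  pairing helix (H), strand (E) and loop (C) states: per-category
  precision and the proportions of predicted and of true contacts per
  category (each proportion vector sums to 1).

Ranking everywhere is score-descending with ties broken by ascending
`i`, then `j`, so truncations are deterministic and precision is
invariant to permutations of equal-score entries.

## Neff and the inverse regression

The effective number of sequences of an alignment uses hard clustering:
each row is weighted by the reciprocal of the number of rows at least
80% identical to it (itself included), and Neff is the sum of weights.
Pairwise identity counts matching columns over the columns where both
sequences are non-gapped; non-overlapping rows are 0% identical and
every row is 100% identical to itself, so 1 <= Neff <= n with equality
exactly in the all-identical and all-dissimilar cases. The 80% threshold
and identity denominator follow the convention of the pseudo-likelihood
coevolution literature and sit behind a single parameter.

To estimate the alignment depth a predictor needs,
`neff_at_precision_ci()` fits ordinary least squares of Neff on
precision across targets -- deliberately that orientation, not a
calibration-style inversion -- and returns the t-based **mean-response**
confidence interval at a target precision (default 50%, the conventional
usefulness bar). The mean-response interval answers "what Neff does this
method typically need"; a prediction interval for a single new target is
available via `interval = "prediction"` and is necessarily wider.
Simulation with a planted linear mean verifies ~95% coverage over 500
replicates.

## Structural similarity and decoy correctness

Decoys model the full target sequence, so residue correspondence is
positional and no alignment is attempted. `tm_score()` computes the
length-normalized similarity with scale `d0 = max(0.5, 1.24 (L-15)^{1/3}
- 1.8)` (the 0.5 floor guards short chains), maximized over
superpositions found by the standard fragment-seeded search: windows of
lengths L, L/2 and L/4 (minimum 4) at every start, each refined by
re-fitting a Kabsch superposition on the residues currently within d0
until the inclusion set stabilizes (capped at 50 iterations, minimum 3
residues to fit). This is an approximation of the published TM-score
search protocol; the tests therefore assert invariants -- self-score 1,
rigid-motion invariance within 1e-6, never below the single global
superposition score, monotone decay with coordinate noise -- rather than
third-party score matching. A decoy is *correct* when its TM-score
against the native is strictly greater than 0.5. `kabsch()` itself is
the SVD solution restricted to proper rotations and is cross-checked
against an independent least-squares fit.

## Decoy quality assessment

A predicted contact is *satisfied* in a decoy when the decoy's
representative-atom distance for that pair is below the same strict 8 A
criterion that defines true contacts -- symmetry we choose so that a
perfect decoy satisfies exactly the predictions that are true contacts.
The range class of a predicted pair is fixed by `|i - j|`, never by
geometry, and satisfaction fractions are reported per class over the
top-L predictions (configurable). A class with no predictions yields an
*undefined* fraction, which propagates as `NA` and is never coerced to
0; decoys whose filtering measure is undefined are discarded with a
flag, because a quality score that cannot be computed should not pass
models.

The naive classifier keeps a decoy when its satisfaction is at least a
threshold, so the reported threshold is the minimal kept satisfaction.
`optimal_threshold()` scans all observed satisfaction values (plus 0 and
just above the maximum) and by default minimizes raw classification
errors, false positives plus false negatives, ties going to the smallest
cutoff -- this exactly matches an exhaustive oracle and is what the
module-level contract tests pin down. Realistic ensembles are heavily
imbalanced (a few percent correct), and there the raw count is dominated
by the majority class: the count-optimal cutoff climbs so high that a
large share of correct models is discarded. The filtering *workflow*
therefore uses `balance = TRUE`, minimizing the sum of error rates (the
Youden point of the ROC curve), which preserves sensitivity; on the
default testbed this recovers the expected regime of several-fold
enrichment with a single-digit false-negative rate, whereas the raw
count objective does not. `decoy_roc()` sweeps the same thresholds to
produce sensitivity (correct kept) and specificity (incorrect
discarded) with a trapezoidal AUC, verified against `pROC` on shared
inputs.

`summarize_filtering()` reports the proportion of correct decoys before
and after filtering, their ratio (the enrichment factor), the number of
correct models lost, and the `all_discarded` flag. Because the
satisfaction fraction is comparable across targets -- unlike energies
from a scoring function -- a pooled threshold can be applied case
independently, and an ensemble whose every decoy falls below it is a
*modelling failure* signal: no correct model is likely to exist in it.
`top_k_impact()` measures what filtering costs: the best TM-score and
the best TM-score among the k decoys the generator's own energy ranking
prefers, before and after. `correlation_report()` uses Spearman rank
correlation between satisfaction and TM-score, as the claimed
association is monotone, not linear.

## What the synthetic generators emulate

`generator_config()` fixes every condition behind one seed; outputs are
identical under a fixed seed and the generators restore the caller's RNG
state.

* **Natives** (`make_native()`): idealized C-alpha traces with 3.8 A
  consecutive spacing (within 0.05), no non-consecutive pair closer than
  2.5 A, pseudo-tetrahedral C-betas at 1.53 A, and random sequences
  (glycine keeps no C-beta). `helix_bundle` is an antiparallel bundle of
  coarse 4-residue-per-turn helices (15 residues each) whose junction
  steps are exactly 3.8 A; facing inter-helix pairs guarantee a
  long-range contact for L >= 28. `beta_hairpin_stack` is a boustrophedon
  grid meander (rows of 4, four rows per layer, stacked layers): every
  grid edge is one 3.8 A step, so the chain is contact-rich at *all*
  separations everywhere along its length -- the property that makes
  exact spread construction feasible -- with long-range contacts for
  L >= 25. `random_coil` is a self-avoiding walk with no contact
  guarantee. The geometry is deliberately idealized (no side chains
  beyond C-beta, no dihedral realism): every consumer in the pipeline
  sees only representative-atom distances, so this is sufficient --
  and it is also why passing tests certify the *metrics*, not the
  behaviour of the pipeline on real crystallographic quirks (altLoc
  disorder, chain breaks, non-standard residues beyond what
  `read_pdb()` normalizes).
* **Decoys** (`make_decoys()`): per noise level, isotropic Gaussian
  perturbation of the C-alphas followed by a chain walk that restores
  exact 3.8 A bonds while tracking the perturbed shape; sigma 0 returns
  exact copies, larger sigma yields stochastically lower TM-scores.
  These decoys sample geometric degradation, not the energetics of a
  fragment assembler.
* **Predictions** (`make_predictions()`): exactly `round(precision *
  count)` entries drawn from the true contacts, the rest from
  non-contact pairs of separation >= 5, with uniform random scores so
  correctness is independent of rank. The long-range fraction of both
  groups is controllable. A spread target confines all correct picks to
  the trailing window of the chain and greedily chains window-local true
  contacts (gaps of at most ~8 residues) so the realized spread lands
  within one residue of the target; wide windows hold few true
  contacts, so large spread targets are only feasible with small
  correct-entry budgets, and infeasible requests error rather than
  degrade.
* **Alignments** (`make_msa()`): k mutually <80%-identical random
  centroids (verified, bounded retries) duplicated to n rows, so
  hard-clustering Neff equals k exactly.
* **QA testbed** (`make_qa_ensemble()`): simulated satisfaction profiles
  with 7% correct decoys; correct decoys draw long-range satisfaction
  from Beta(8, 4) against Beta(2, 6) for incorrect ones, and the
  short-range pair Beta(5, 5) vs Beta(3, 6) is deliberately weaker, so
  long-range satisfaction is the most informative measure -- the
  qualitative ordering the structure-level analysis also shows. The
  Beta shapes are configuration, not constants, so the effect size is a
  test dial.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1, L = 60, topology = "beta_hairpin_stack",
                        prediction_precision = 0.7, prediction_count = 60)
native <- make_native(cfg)
truth <- extract_contacts(native)
preds <- make_predictions(truth, cfg)
evaluate_target(preds, native)   # top-L/k precision, range split, spread

decoys <- make_decoys(native, cfg)
profiles <- satisfaction_profiles(decoys, preds)
labels <- vapply(decoys, is_correct_decoy, logical(1), native = native)
th <- optimal_threshold(profiles, labels, "long", balance = TRUE)
summarize_filtering(profiles, labels, th, "long")
```

## Numerical choices and degenerate inputs

* Distances are double-precision Angstrom; no symmetry or periodicity
  (single chains only).
* Equal scores everywhere break ties by ascending `i`, then `j`.
* Asymmetric score matrices are symmetrized by averaging the two cells.
* Duplicate predicted pairs collapse to their maximum score.
* Zero assessable predictions, empty range classes, constant
  correlation columns and one-class label vectors are all surfaced as
  `NA`-with-flag or errors, never silently coerced.
* `optimal_threshold` and `decoy_roc` use value-sorted suffix counts,
  so 10^4-decoy sweeps stay O(n log n) and equal the naive scan exactly.
* Glycine never carries a C-beta; any other residue lacking one falls
  back to its C-alpha with a warning.
* A non-glycine Kabsch fit needs >= 3 points; TM refinement stops when
  the within-d0 set has fewer than 3 residues or repeats.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen so the whole suite completes in well under a
minute of compute per stage: 200 random structures (L <= 80) for the
contact oracle, 50 seeded replicates for precision/spread recovery,
500 regression replicates for interval coverage, 60 decoys (L = 60) for
TM monotonicity, 100 random ensembles (n <= 500) plus one 10 000-decoy
testbed for the classifier, ROC and enrichment checks. These sizes are
the package's validation conditions, not statements about the scale the
methods support; all metric code is vectorized and comfortably handles
ensembles orders of magnitude larger.

## Known limitations

* TM-score assumes positional correspondence; it is not a structural
  aligner and will not score models of a different sequence length.
* The synthetic decoys and satisfaction testbed validate the metrics'
  arithmetic and the classifier's behaviour under known separations;
  they do not certify how well contact satisfaction separates correct
  from incorrect models produced by any particular real decoy
  generator.
* SCOP-style fold-class labels are consumed as user-supplied metadata
  for grouping only; the package never infers structural classes.
* mmCIF, multi-model handling beyond the first model, SEQRES/ATOM
  reconciliation and inter-chain contacts are out of scope.
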