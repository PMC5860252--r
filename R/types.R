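#' contactqa: contact-prediction evaluation and decoy quality assessment
#'
#' Evaluate predicted residue-residue contacts against native structures
#' (precision, spread, secondary-structure breakdowns, Neff regression) and
#' use satisfied predicted contacts to classify decoys as correct/incorrect,
#' enrich decoy ensembles and detect modelling failures.
#'
#' @section Contact definition:
#' Two residues are in contact when their representative atoms (C-beta,
#' C-alpha for glycine) are strictly less than 8 Angstrom apart and their
#' sequence separation is at least 5. Contacts with separation 5..23 are
#' short range, separation > 23 long range.
#'
#' @keywords internal
"_PACKAGE"

#' Contact definition parameters
#'
#' Bundles the geometric and sequence-separation thresholds that define a
#' residue-residue contact: representative-atom distance strictly below
#' `distance_cutoff`, sequence separation `|i - j| >= min_separation`, and
#' the short/long boundary (separation `> short_long_boundary` is long
#' range).
#'
#' @param distance_cutoff Distance threshold in Angstrom (strict `<`).
#' @param min_separation Minimum sequence separation; pairs closer in
#'   sequence are trivial and ignored.
#' @param short_long_boundary Largest separation still counted as short
#'   range.
#' @return An object of class `contact_criteria`.
#' @examples
#' contact_criteria()
#' @export
contact_criteria <- function(distance_cutoff = 8.0, min_separation = 5L,
                             short_long_boundary = 23L) {
  stopifnot(distance_cutoff > 0, min_separation >= 1,
            short_long_boundary >= min_separation)
  structure(list(distance_cutoff = as.numeric(distance_cutoff),
                 min_separation = as.integer(min_separation),
                 short_long_boundary = as.integer(short_long_boundary)),
            class = "contact_criteria")
}

#' @export
print.contact_criteria <- function(x, ...) {
  cat(sprintf("Contact criteria: d < %g A, separation >= %d, short <= %d < long\n",
              x$distance_cutoff, x$min_separation, x$short_long_boundary))
  invisible(x)
}

#' Construct a structure model
#'
#' An ordered single-chain residue list with representative-atom
#' coordinates. Residues are indexed 1..L in order of appearance in the
#' observed chain; author residue numbers are deliberately not kept so
#' that contact indices live in the same space as alignment columns.
#'
#' @param id Identifier.
#' @param sequence One-letter amino-acid string of length L.
#' @param ca L x 3 matrix of C-alpha coordinates (Angstrom).
#' @param cb L x 3 matrix of C-beta coordinates; rows of `NA` where the
#'   residue has no C-beta (glycine).
#' @return An object of class `structure_model` with fields `id`,
#'   `sequence`, `seq_index`, `ca`, `cb`.
#' @export
structure_model <- function(id, sequence, ca, cb = NULL) {
  ca <- as.matrix(ca)
  L <- nrow(ca)
  stopifnot(L >= 1, ncol(ca) == 3, nchar(sequence) == L,
            !anyNA(ca))
  if (is.null(cb)) cb <- matrix(NA_real_, L, 3) else cb <- as.matrix(cb)
  stopifnot(nrow(cb) == L, ncol(cb) == 3)
  aa <- strsplit(sequence, "")[[1]]
  # glycine carries no C-beta by definition
  cb[aa == "G", ] <- NA_real_
  dimnames(ca) <- dimnames(cb) <- NULL
  structure(list(id = as.character(id), sequence = sequence,
                 seq_index = seq_len(L), ca = ca, cb = cb),
            class = "structure_model")
}

#' Number of residues in a structure model
#' @param x A `structure_model`.
#' @return Integer length L.
#' @export
model_length <- function(x) {
  stopifnot(inherits(x, "structure_model"))
  length(x$seq_index)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model '%s': %d residues, %d with C-beta\n",
              x$id, model_length(x), sum(!is.na(x$cb[, 1]))))
  invisible(x)
}

#' Construct a canonical prediction list
#'
#' A scored, ranked list of candidate contacts. Entries are canonicalized
#' to `i < j`, duplicates collapsed keeping the maximum score, and sorted
#' by score descending with ties broken by ascending `i` then `j` so that
#' every downstream truncation is deterministic.
#'
#' @param i,j 1-based residue indices.
#' @param score Numeric scores (higher = more confident).
#' @param target_id Target identifier.
#' @param provenance Free-text tag, e.g. the predictor name.
#' @return A data frame of class `prediction_list` with columns
#'   `i`, `j`, `score` and attributes `target_id`, `provenance`.
#' @export
prediction_list <- function(i, j, score, target_id = "", provenance = "") {
  i <- as.integer(i); j <- as.integer(j); score <- as.numeric(score)
  stopifnot(length(i) == length(j), length(j) == length(score))
  if (length(i)) {
    if (any(i < 1L | j < 1L)) stop("indices must be positive")
    if (any(i == j)) stop("self-contact (i == j) is not a valid prediction")
    swap <- i > j
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    # collapse duplicates, keeping the best score
    key <- paste(i, j)
    if (anyDuplicated(key)) {
      best <- tapply(score, key, max)
      keep <- !duplicated(key)
      i <- i[keep]; j <- j[keep]
      score <- as.numeric(best[paste(i, j)])
    }
    ord <- order(-score, i, j)
    i <- i[ord]; j <- j[ord]; score <- score[ord]
  }
  out <- data.frame(i = i, j = j, score = score)
  attr(out, "target_id") <- as.character(target_id)
  attr(out, "provenance") <- as.character(provenance)
  class(out) <- c("prediction_list", "data.frame")
  out
}

#' @export
print.prediction_list <- function(x, ...) {
  cat(sprintf("Prediction list '%s' (%s): %d entries\n",
              attr(x, "target_id"), attr(x, "provenance"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Construct a multiple sequence alignment object
#'
#' @param rows Character vector of aligned sequences (equal lengths, gaps
#'   as `-` or `.`); the first row is the query.
#' @param ids Sequence identifiers (defaults to `seq1`, `seq2`, ...).
#' @return An object of class `msa` with fields `ids`, `rows`, `ncol`.
#' @export
msa <- function(rows, ids = NULL) {
  rows <- toupper(as.character(rows))
  if (!length(rows)) stop("an alignment needs at least one sequence")
  nc <- unique(nchar(rows))
  if (length(nc) != 1) stop("all alignment rows must have equal length")
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  stopifnot(length(ids) == length(rows))
  structure(list(ids = as.character(ids), rows = rows, ncol = nc),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns\n", length(x$rows), x$ncol))
  invisible(x)
}

#' Three-state secondary structure string
#'
#' @param states String over `{H, E, C}` (helix, strand, coil/loop).
#' @param target_id Target identifier.
#' @return An object of class `ss_string`.
#' @export
ss_string <- function(states, target_id = "") {
  states <- toupper(states)
  if (grepl("[^HEC]", states)) stop("secondary structure must use only H, E, C")
  structure(list(target_id = as.character(target_id), states = states),
            class = "ss_string")
}

ss_states <- function(ss) {
  if (inherits(ss, "ss_string")) ss$states else as.character(ss)
}
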