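#' Representative-atom coordinates of a structure
#'
#' Returns the per-residue coordinates used for the contact definition:
#' the C-beta when present, otherwise the C-alpha. Glycine never has a
#' C-beta; for any other residue with a missing C-beta the C-alpha is used
#' as a documented fallback and a warning is emitted.
#'
#' @param structure A [structure_model()].
#' @param warn Warn when a non-glycine residue falls back to C-alpha.
#' @return L x 3 numeric matrix.
#' @export
representative_coords <- function(structure, warn = TRUE) {
  stopifnot(inherits(structure, "structure_model"))
  rep <- structure$cb
  missing_cb <- is.na(rep[, 1])
  aa <- strsplit(structure$sequence, "")[[1]]
  odd <- which(missing_cb & aa != "G")
  if (warn && length(odd)) {
    warning(sprintf("%d non-glycine residue(s) without C-beta; using C-alpha (e.g. residue %d)",
                    length(odd), odd[1]))
  }
  rep[missing_cb, ] <- structure$ca[missing_cb, , drop = FALSE]
  rep
}

#' Secondary-structure category of a residue pair
#'
#' Maps the unordered pair of three-state assignments of residues `i` and
#' `j` to one of the six contact categories: loop-loop, loop-helix,
#' loop-strand, helix-helix, helix-strand, strand-strand (C = loop,
#' H = helix, E = strand). Symmetric in its two residues.
#'
#' @param i,j 1-based residue indices.
#' @param ss An [ss_string()] or plain `HEC` string.
#' @return Category label (factor level of [ss_category_levels()]).
#' @export
ss_category <- function(i, j, ss) {
  states <- ss_states(ss)
  n <- nchar(states)
  if (any(i < 1 | i > n | j < 1 | j > n)) {
    stop("residue index out of range of the secondary-structure string")
  }
  si <- substring(states, i, i)
  sj <- substring(states, j, j)
  ss_pair_category(si, sj)
}

#' The six secondary-structure contact categories
#' @return Character vector of the category labels in canonical order.
#' @export
ss_category_levels <- function() {
  c("loop-loop", "loop-helix", "loop-strand",
    "helix-helix", "helix-strand", "strand-strand")
}

# vectorized category of state pairs; order-invariant
ss_pair_category <- function(si, sj) {
  word <- c(C = "loop", H = "helix", E = "strand")
  rank <- c(loop = 1L, helix = 2L, strand = 3L)
  a <- word[si]; b <- word[sj]
  first <- ifelse(rank[a] <= rank[b], a, b)
  second <- ifelse(rank[a] <= rank[b], b, a)
  unname(paste(first, second, sep = "-"))
}

#' Extract the true contacts of a structure
#'
#' A pair (i, j) is a contact when the representative atoms (C-beta,
#' C-alpha for glycine) are strictly closer than the distance cutoff and
#' the sequence separation `j - i` is at least the minimum separation.
#' Contacts are labelled `short` (separation up to the short/long
#' boundary) or `long` (beyond it), and by secondary-structure category
#' when `ss` is supplied.
#'
#' @param structure A [structure_model()].
#' @param criteria A [contact_criteria()].
#' @param ss Optional [ss_string()] of the same length as the structure.
#' @return A data frame of class `contact_set` with columns `i`, `j`,
#'   `sep`, `range` and (optionally) `ss_category`; attributes `L` and
#'   `target_id`.
#' @examples
#' nat <- make_native(generator_config(seed = 1, L = 40))
#' extract_contacts(nat, contact_criteria())
#' @export
extract_contacts <- function(structure, criteria = contact_criteria(), ss = NULL) {
  stopifnot(inherits(structure, "structure_model"),
            inherits(criteria, "contact_criteria"))
  L <- model_length(structure)
  if (!is.null(ss)) {
    states <- ss_states(ss)
    if (nchar(states) != L) {
      stop(sprintf("secondary-structure length (%d) does not match structure length (%d)",
                   nchar(states), L))
    }
  }
  rep <- representative_coords(structure, warn = FALSE)
  d <- as.matrix(stats::dist(rep))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  sep <- j - i
  hit <- sep >= criteria$min_separation & d[idx] < criteria$distance_cutoff
  i <- i[hit]; j <- j[hit]; sep <- sep[hit]
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]; sep <- sep[ord]
  out <- data.frame(i = i, j = j, sep = sep,
                    range = ifelse(sep > criteria$short_long_boundary, "long", "short"),
                    stringsAsFactors = FALSE)
  if (!is.null(ss) && nrow(out)) {
    out$ss_category <- ss_category(out$i, out$j, ss)
  } else if (!is.null(ss)) {
    out$ss_category <- character(0)
  }
  attr(out, "L") <- L
  attr(out, "target_id") <- structure$id
  attr(out, "criteria") <- criteria
  class(out) <- c("contact_set", "data.frame")
  out
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("Contact set '%s' (L = %d): %d contacts (%d short, %d long)\n",
              attr(x, "target_id"), attr(x, "L"), nrow(x),
              sum(x$range == "short"), sum(x$range == "long")))
  invisible(x)
}

#' Sequence-separation range class of residue pairs
#'
#' @param i,j Residue indices (any order).
#' @param criteria A [contact_criteria()].
#' @return `"trivial"`, `"short"` or `"long"` per pair.
#' @export
range_class <- function(i, j, criteria = contact_criteria()) {
  sep <- abs(j - i)
  ifelse(sep < criteria$min_separation, "trivial",
         ifelse(sep > criteria$short_long_boundary, "long", "short"))
}

# fast membership of prediction pairs in a contact set
contact_key <- function(i, j, L) (pmin(i, j) - 1) * as.double(L) + pmax(i, j)

#' Test predictions for membership in a contact set
#'
#' Membership ignores the range class: a predicted pair is correct when
#' the unordered pair (i, j) is a true contact of any range.
#'
#' @param i,j Residue index vectors.
#' @param truth A `contact_set`.
#' @return Logical vector.
#' @export
in_contact_set <- function(i, j, truth) {
  stopifnot(inherits(truth, "contact_set"))
  L <- attr(truth, "L")
  out <- logical(length(i))
  ok <- i >= 1 & j >= 1 & i <= L & j <= L  # out-of-chain pairs are never true
  out[ok] <- contact_key(i[ok], j[ok], L) %in% contact_key(truth$i, truth$j, L)
  out
}
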