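#' Read a single protein chain from a PDB file
#'
#' Parses ATOM records (HETATM ignored) of one chain and returns a
#' [structure_model()] indexed 1..L in order of appearance of the observed
#' residues. Author residue numbering and insertion codes are honoured
#' only for ordering/grouping (file order is kept); alternate locations
#' are resolved by highest occupancy, ties going to the first record.
#' Residues without a C-alpha are skipped with a warning. C-beta
#' coordinates are taken from the file when present; glycine is always
#' recorded without a C-beta.
#'
#' @param path PDB file.
#' @param chain Chain identifier; by default the first chain in the file.
#' @return A [structure_model()].
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  at$chain[is.na(at$chain)] <- " "
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop(sprintf("chain '%s' not found in %s", chain, path))
  at <- at[at$elety %in% c("CA", "CB"), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  if (!("o" %in% names(at)) || all(is.na(at$o))) at$o <- 1
  at$o[is.na(at$o)] <- 1
  # residues in file order; insertion-coded residues kept where they appear
  rkey <- paste(at$resno, at$insert)
  rlev <- unique(rkey)
  getter <- function(elety) {
    sub <- at[at$elety == elety, , drop = FALSE]
    # altLoc: highest occupancy wins, ties -> first encountered
    sub <- sub[order(match(paste(sub$resno, sub$insert), rlev), -sub$o), , drop = FALSE]
    sub[!duplicated(paste(sub$resno, sub$insert)), , drop = FALSE]
  }
  ca <- getter("CA")
  if (!nrow(ca)) stop("selected chain has no residue with a CA atom")
  n_res <- length(rlev)
  if (nrow(ca) < n_res) {
    warning(sprintf("%d residue(s) without a CA atom skipped", n_res - nrow(ca)))
  }
  cb <- getter("CB")
  cbmap <- match(paste(ca$resno, ca$insert), paste(cb$resno, cb$insert))
  L <- nrow(ca)
  camat <- cbind(ca$x, ca$y, ca$z)
  cbmat <- matrix(NA_real_, L, 3)
  has <- !is.na(cbmap)
  cbmat[has, ] <- cbind(cb$x, cb$y, cb$z)[cbmap[has], , drop = FALSE]
  aa1 <- bio3d::aa321(ca$resid)
  aa1[is.na(aa1) | nchar(aa1) != 1] <- "X"
  id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  structure_model(id = id, sequence = paste(aa1, collapse = ""),
                  ca = camat, cb = cbmat)
}

rr_headers <- c("PFRMAT", "TARGET", "AUTHOR", "METHOD", "MODEL", "REMARK",
                "RMODE", "END")

#' Read a CASP RR contact prediction file
#'
#' Accepts optional header lines (PFRMAT, TARGET, MODEL, ..., plus
#' sequence lines) followed by records `i j d1 d2 p` with 1-based residue
#' indices. Entries are canonicalized to `i < j`, duplicates collapsed to
#' the maximum score, and ranked by score descending (ties by ascending
#' `i`, then `j`).
#'
#' @param path RR file.
#' @param target_id Overrides the TARGET header / file stem.
#' @return A [prediction_list()].
#' @export
read_rr <- function(path, target_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  tid <- sub("\\.rr$", "", basename(path))
  i <- integer(0); j <- integer(0); p <- numeric(0)
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (!nzchar(line)) next
    tok <- strsplit(line, "\\s+")[[1]]
    if (toupper(tok[1]) %in% rr_headers) {
      if (toupper(tok[1]) == "TARGET" && length(tok) > 1) tid <- tok[2]
      next
    }
    if (length(tok) == 1 && grepl("^[A-Za-z-]+$", tok[1])) next  # sequence line
    if (length(tok) < 5) {
      stop(sprintf("line %d of %s: expected 'i j d1 d2 p'", k, path))
    }
    vals <- suppressWarnings(as.numeric(tok[1:5]))
    if (anyNA(vals)) {
      stop(sprintf("line %d of %s: non-numeric field in '%s'", k, path, line))
    }
    if (vals[1] != round(vals[1]) || vals[2] != round(vals[2])) {
      stop(sprintf("line %d of %s: residue indices must be integers", k, path))
    }
    if (vals[1] == vals[2]) {
      stop(sprintf("line %d of %s: self-contact i == j", k, path))
    }
    i <- c(i, as.integer(vals[1])); j <- c(j, as.integer(vals[2]))
    p <- c(p, vals[5])
  }
  if (!is.null(target_id)) tid <- target_id
  prediction_list(i, j, p, target_id = tid, provenance = "rr")
}

#' Write a prediction list in CASP RR format
#'
#' The canonical ordering and full-precision scores are preserved so that
#' `read_rr(write_rr(x))` reproduces `x` entry for entry.
#'
#' @param predictions A [prediction_list()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rr <- function(predictions, path) {
  stopifnot(inherits(predictions, "prediction_list"))
  lines <- c("PFRMAT RR", paste("TARGET", attr(predictions, "target_id")))
  if (nrow(predictions)) {
    lines <- c(lines, sprintf("%d %d 0 8 %.17g",
                              predictions$i, predictions$j, predictions$score))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a square residue-residue score matrix
#'
#' Reads a whitespace-delimited L x L numeric matrix (CCMPred-style
#' output). Upper-triangle cells with sequence separation of at least
#' `min_separation` become prediction entries ranked by score. Asymmetric
#' matrices are symmetrized by averaging cells (i, j) and (j, i); such
#' matrices are symmetric up to float noise in practice.
#'
#' @param path Matrix file.
#' @param target_id Target identifier.
#' @param min_separation Smallest sequence separation kept.
#' @return A [prediction_list()].
#' @export
read_contact_matrix <- function(path, target_id = "", min_separation = 5L) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (nrow(m) != ncol(m)) {
    stop(sprintf("score matrix must be square, got %d x %d", nrow(m), ncol(m)))
  }
  if (!is.numeric(m)) stop("score matrix must be numeric")
  m <- (m + t(m)) / 2
  idx <- which(upper.tri(m), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1]) >= min_separation
  idx <- idx[keep, , drop = FALSE]
  prediction_list(idx[, 1], idx[, 2], m[idx],
                  target_id = target_id, provenance = "matrix")
}

#' Read an aligned FASTA or A3M alignment
#'
#' For A3M input, lowercase letters and `.` are insertions relative to the
#' query and are removed, leaving match columns only.
#'
#' @param path Alignment file.
#' @param format `"fasta"` (aligned) or `"a3m"`.
#' @return An [msa()].
#' @export
read_msa <- function(path, format = c("fasta", "a3m")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  if (!length(seqs)) stop("no sequences in ", path)
  rows <- vapply(seqs, function(s) s[[1]], character(1))
  if (format == "a3m") rows <- gsub("[a-z.]", "", rows)
  msa(rows, ids = names(seqs))
}

#' Read a three-state secondary-structure string
#'
#' Accepts a single-line `HEC` string, optionally wrapped and/or preceded
#' by a FASTA-style `>` header.
#'
#' @param path Text file.
#' @param target_id Target identifier (defaults to the file stem).
#' @return An [ss_string()].
#' @export
read_ss <- function(path, target_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (is.null(target_id)) target_id <- sub("\\.[^.]*$", "", basename(path))
  hdr <- grepl("^>", lines)
  if (any(hdr) && nzchar(sub("^>\\s*", "", lines[which(hdr)[1]]))) {
    target_id <- sub("^>\\s*", "", lines[which(hdr)[1]])
  }
  states <- paste(trimws(lines[!hdr]), collapse = "")
  ss_string(states, target_id = target_id)
}

#' Read a per-decoy score table
#'
#' Tab-separated file with a header and columns `decoy_id`, optionally
#' `tm_score` (in `[0, 1]`) and `energy_rank` (1 = ranked best by the
#' decoy generator's scoring function).
#'
#' @param path TSV file.
#' @return A data frame of class `decoy_score_table`.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!("decoy_id" %in% names(d))) stop("score table needs a 'decoy_id' column")
  if (anyDuplicated(d$decoy_id)) stop("decoy_ids must be unique")
  if ("tm_score" %in% names(d) &&
      any(d$tm_score < 0 | d$tm_score > 1, na.rm = TRUE)) {
    stop("tm_score values must lie in [0, 1]")
  }
  class(d) <- c("decoy_score_table", "data.frame")
  d
}

#' Write a structure model as a minimal PDB file
#'
#' Emits CA (and CB where present) ATOM records for a single chain,
#' sufficient for round-tripping synthetic structures through
#' [read_pdb()].
#'
#' @param structure A [structure_model()].
#' @param path Output file.
#' @param chain Chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, chain = "A") {
  stopifnot(inherits(structure, "structure_model"))
  aa <- strsplit(structure$sequence, "")[[1]]
  aa3 <- vapply(aa, function(a) {
    r <- bio3d::aa123(a)
    if (is.na(r)) "UNK" else r
  }, character(1))
  lines <- character(0)
  serial <- 0L
  for (k in seq_along(aa)) {
    for (atom in c("CA", "CB")) {
      xyz <- if (atom == "CA") structure$ca[k, ] else structure$cb[k, ]
      if (anyNA(xyz)) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, atom, aa3[k], chain, k, xyz[1], xyz[2], xyz[3],
        substr(atom, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
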