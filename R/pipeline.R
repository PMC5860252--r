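#' Assemble a target for batch runs
#'
#' Fields may be in-memory objects or file paths; paths are read with the
#' package readers at run time.
#'
#' @param id Target identifier.
#' @param structure A [structure_model()] or PDB path.
#' @param predictions A [prediction_list()], RR path, or named list of
#'   several prediction lists/paths (one per predictor).
#' @param ss Optional [ss_string()] or path.
#' @param decoys Optional list of [structure_model()]s or a directory of
#'   PDB decoys.
#' @param score_table Optional `decoy_score_table` or TSV path.
#' @param label Optional grouping label (e.g. a user-supplied fold
#'   class); consumed as metadata, never computed.
#' @return An object of class `qa_target`.
#' @export
qa_target <- function(id, structure, predictions, ss = NULL, decoys = NULL,
                      score_table = NULL, label = NA_character_) {
  structure(list(id = id, structure = structure, predictions = predictions,
                 ss = ss, decoys = decoys, score_table = score_table,
                 label = label),
            class = "qa_target")
}

load_structure <- function(x) {
  if (inherits(x, "structure_model")) x else read_pdb(x)
}
load_predictions <- function(x) {
  if (inherits(x, "prediction_list")) x else read_rr(x)
}
load_ss <- function(x) {
  if (is.null(x) || inherits(x, "ss_string")) x else read_ss(x)
}
load_decoys <- function(x) {
  if (is.null(x) || is.list(x)) return(x)
  paths <- sort(list.files(x, pattern = "\\.(pdb|ent)$", full.names = TRUE))
  lapply(paths, read_pdb)
}
load_scores <- function(x) {
  if (is.null(x) || inherits(x, "data.frame")) x else read_score_table(x)
}

#' Run the contact-prediction evaluation over a set of targets
#'
#' Evaluates every target with [evaluate_target()] and aggregates mean
#' and median precisions/spread overall and per user-supplied label.
#' Per-target failures are caught, reported in the `errors` element and
#' do not stop the run. Output ordering is deterministic (input order
#' for per-target rows, sorted labels in the aggregate).
#'
#' @param targets List of [qa_target()]s.
#' @param criteria A [contact_criteria()].
#' @param fractions Fractions of L to evaluate.
#' @return List of class `eval_run`: `per_target` (one row per target),
#'   `aggregate`, `errors`.
#' @export
run_eval <- function(targets, criteria = contact_criteria(),
                     fractions = c(0.1, 0.2, 0.5, 1)) {
  rows <- list(); errors <- character(0)
  for (tg in targets) {
    res <- tryCatch({
      st <- load_structure(tg$structure)
      pr <- load_predictions(tg$predictions)
      rep <- evaluate_target(pr, st, ss = load_ss(tg$ss), criteria = criteria,
                             fractions = fractions, scop_class = tg$label)
      row <- report_row(rep)
      row$target_id <- tg$id
      row
    }, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", tg$id, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  per_target <- if (length(rows)) do.call(rbind, rows) else NULL
  aggregate <- NULL
  if (!is.null(per_target)) {
    num_cols <- setdiff(names(per_target)[vapply(per_target, is.numeric, TRUE)],
                        c("L", "n_true_contacts"))
    agg_one <- function(d, label) {
      data.frame(label = label, n_targets = nrow(d),
                 t(colMeans(d[num_cols], na.rm = TRUE)),
                 stringsAsFactors = FALSE)
    }
    aggregate <- agg_one(per_target, "all")
    labs <- sort(unique(stats::na.omit(per_target$scop_class)))
    for (lb in labs) {
      aggregate <- rbind(aggregate,
                         agg_one(per_target[per_target$scop_class %in% lb, ,
                                            drop = FALSE], lb))
    }
  }
  structure(list(per_target = per_target, aggregate = aggregate,
                 errors = errors),
            class = "eval_run")
}

#' @export
print.eval_run <- function(x, ...) {
  n <- if (is.null(x$per_target)) 0 else nrow(x$per_target)
  cat(sprintf("Evaluation run: %d target(s), %d error(s)\n", n, length(x$errors)))
  if (!is.null(x$aggregate)) print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Run satisfied-contact quality assessment over decoy ensembles
#'
#' For every target, computes per-decoy satisfaction profiles, labels
#' decoys correct/incorrect by TM-score (from the score table, computed
#' against the native when absent), fits a pooled error-minimizing
#' threshold across all labelled targets (the classifier is meant to be
#' applied in a case-independent fashion), filters each ensemble at that
#' threshold and reports per-target summaries plus the list of targets
#' whose whole ensemble was discarded (modelling failures).
#'
#' @param targets List of [qa_target()]s with `decoys`.
#' @param criteria A [contact_criteria()].
#' @param measure Satisfaction measure used for filtering.
#' @param threshold `"auto"` (pooled optimal; requires labels) or a
#'   numeric cutoff.
#' @param tm_cutoff Correctness cutoff on TM-score (strict `>`).
#' @return List of class `qa_run`: `profiles` (pooled, with target ids
#'   and labels), `threshold`, `per_target` summaries, `failed_targets`,
#'   `errors`.
#' @export
run_qa <- function(targets, criteria = contact_criteria(), measure = "long",
                   threshold = "auto", tm_cutoff = 0.5) {
  prof_all <- list(); errors <- character(0)
  for (tg in targets) {
    res <- tryCatch({
      native <- load_structure(tg$structure)
      preds <- load_predictions(tg$predictions)
      decoys <- load_decoys(tg$decoys)
      if (is.null(decoys) || !length(decoys)) stop("no decoys")
      prof <- satisfaction_profiles(decoys, preds, criteria)
      st <- load_scores(tg$score_table)
      tm <- if (!is.null(st) && "tm_score" %in% names(st)) {
        st$tm_score[match(prof$decoy_id, st$decoy_id)]
      } else {
        vapply(decoys, function(d) tm_score(d, native)$tm, numeric(1))
      }
      prof$tm_score <- tm
      prof$correct <- tm > tm_cutoff
      prof$target_id <- tg$id
      prof
    }, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", tg$id, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) prof_all[[length(prof_all) + 1L]] <- res
  }
  if (!length(prof_all)) {
    return(structure(list(profiles = NULL, threshold = NA_real_,
                          per_target = NULL, failed_targets = character(0),
                          errors = errors), class = "qa_run"))
  }
  pooled <- do.call(rbind, prof_all)
  thr <- if (identical(threshold, "auto")) {
    as.numeric(optimal_threshold(pooled, pooled$correct, measure, balance = TRUE))
  } else as.numeric(threshold)
  per_target <- lapply(prof_all, function(p) {
    s <- summarize_filtering(p, p$correct, thr, measure)
    data.frame(target_id = p$target_id[1], n_decoys = s$n_decoys,
               n_correct = s$n_correct, n_kept = s$n_kept,
               proportion_correct_before = s$proportion_correct_before,
               proportion_correct_after = s$proportion_correct_after,
               enrichment_factor = s$enrichment_factor,
               false_negatives = s$false_negatives,
               all_discarded = s$all_discarded,
               stringsAsFactors = FALSE)
  })
  per_target <- do.call(rbind, per_target)
  structure(list(profiles = pooled, threshold = thr, measure = measure,
                 per_target = per_target,
                 failed_targets = per_target$target_id[per_target$all_discarded],
                 errors = errors),
            class = "qa_run")
}

#' @export
print.qa_run <- function(x, ...) {
  cat(sprintf("QA run (%s-range, threshold %.3f): %d target(s)\n",
              x$measure, x$threshold,
              if (is.null(x$per_target)) 0 else nrow(x$per_target)))
  if (!is.null(x$per_target)) print(x$per_target, row.names = FALSE)
  if (length(x$failed_targets)) {
    cat("Modelling failures (all decoys discarded):",
        paste(x$failed_targets, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a data frame as a stable TSV report
#'
#' Fixed column order, no row names, full-precision numbers: reruns of a
#' fixed configuration produce byte-identical files.
#'
#' @param d Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(d, path) {
  out <- as.data.frame(d)
  for (k in seq_along(out)) {
    if (is.numeric(out[[k]])) out[[k]] <- sprintf("%.10g", out[[k]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
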