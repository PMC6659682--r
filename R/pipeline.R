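# End-to-end convenience wrapper and simulation-recovery metrics.

#' Run the full effector-classification pipeline
#'
#' Chains class I filtering, proteome normalization, the moderated test,
#' threshold calls and effector classification.
#'
#' @param sites phosphosite table.
#' @param proteins protein table.
#' @param thresholds a [threshold_set()]; default the calibrated study
#'   thresholds (down: log2FC < -0.7, FDR < 0.1; specific: FDR < 0.05).
#' @param min_reps minimum non-missing replicates per condition to test a
#'   site.
#' @param global_fdr passed to [moderated_test()].
#' @return list: `class1` (filter partition), `normalized`, `results`,
#'   `calls`, `classes`, `counts`.
#' @export
run_pipeline <- function(sites, proteins, thresholds = threshold_set(),
                         min_reps = 2L, global_fdr = FALSE) {
  class1 <- filter_class1(sites)
  normalized <- normalize_sites(class1$kept, proteins)
  results <- moderated_test(normalized, min_reps = min_reps,
                            global_fdr = global_fdr)
  calls <- call_modulation(results, thresholds)
  classes <- classify_effectors(calls, thresholds)
  list(class1 = class1, normalized = normalized, results = results,
       calls = calls, classes = classes, counts = count_calls(calls))
}

#' Compare recovered effector classes with simulation ground truth
#'
#' Metrics are computed over the analyzed site universe (sites that entered
#' classification, i.e. passed the class I filter): planted sites removed by
#' input filtering measure detection, not classification, and are excluded
#' from the denominator.
#'
#' @param classes output of [classify_effectors()] (or
#'   `run_pipeline()$classes`).
#' @param truth ground-truth table from [simulate_experiment()].
#' @return list: `recall_shared`, `precision_shared`, `fpr_null` (fraction
#'   of planted-null sites classified as any effector), `recall_specific`,
#'   and the confusion table `by_class`.
#' @export
evaluate_recovery <- function(classes, truth) {
  tr <- truth[match(classes$site_id, truth$site_id), ]
  stopifnot(!anyNA(tr$class))
  called <- classes$class
  planted <- tr$class
  is_shared_t <- planted == "shared_effector"
  is_shared_c <- called == "shared_effector"
  is_spec_t <- startsWith(planted, "specific:")
  is_spec_c <- startsWith(called, "specific:")
  recall_shared <- if (any(is_shared_t)) mean(is_shared_c[is_shared_t]) else NA_real_
  precision_shared <- if (any(is_shared_c)) mean(is_shared_t[is_shared_c]) else NA_real_
  recall_specific <- if (any(is_spec_t)) {
    mean((called == planted)[is_spec_t])
  } else NA_real_
  fpr_null <- if (any(planted == "null")) {
    mean((is_shared_c | is_spec_c)[planted == "null"])
  } else NA_real_
  list(recall_shared = recall_shared, precision_shared = precision_shared,
       fpr_null = fpr_null, recall_specific = recall_specific,
       by_class = table(planted = planted, called = called))
}
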