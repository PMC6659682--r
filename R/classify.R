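# Control-calibrated modulation thresholds, per-condition calls, and
# shared vs inhibitor-specific effector classification.

#' Modulation thresholds
#'
#' Holds the log2 fold-change and FDR cutoffs used to call modulated sites.
#' Defaults reproduce the calibrated values used throughout: a site is
#' down-modulated when `fdr < 0.1` and `log2FC < -0.7` (strict
#' inequalities); inhibitor-specific effectors additionally require the
#' stricter `fdr < 0.05`.
#'
#' @param log2fc_down negative real, down-modulation log2FC cutoff.
#' @param log2fc_up positive real, up-modulation log2FC cutoff.
#' @param fdr_call FDR cutoff for modulation calls.
#' @param fdr_specific stricter FDR cutoff for specific-effector selection.
#' @return object of class `threshold_set`.
#' @export
threshold_set <- function(log2fc_down = -0.7, log2fc_up = 0.7,
                          fdr_call = 0.1, fdr_specific = 0.05) {
  if (!(log2fc_down < 0 && log2fc_up > 0)) {
    .stop_phosfx("phosfx_input_error", "need log2fc_down < 0 < log2fc_up")
  }
  if (!(fdr_specific > 0 && fdr_specific <= fdr_call && fdr_call < 1)) {
    .stop_phosfx("phosfx_input_error", "need 0 < fdr_specific <= fdr_call < 1")
  }
  structure(list(log2fc_down = log2fc_down, log2fc_up = log2fc_up,
                 fdr_call = fdr_call, fdr_specific = fdr_specific),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "Modulation thresholds: down log2FC < %g, up log2FC > %g, FDR < %g (specific: FDR < %g)\n",
    x$log2fc_down, x$log2fc_up, x$fdr_call, x$fdr_specific))
  invisible(x)
}

# round |x| up to the next 0.1 (ceiling on a 0.1 grid)
.ceil_grid <- function(x) ceiling(x * 10 - 1e-9) / 10

#' Calibrate modulation thresholds from known-effector control sites
#'
#' Reproduces the threshold-setting procedure: the observed behaviour of
#' positive-control sites (sites known a priori to respond to pathway
#' inhibition) defines how lenient the cutoffs must be to admit them all.
#' The down log2FC cutoff is the maximum (least negative) control summary
#' log2FC, rounded outward (toward 0) to one decimal; the FDR cutoff is the
#' maximum control FDR rounded up to one decimal. Because the calls use
#' strict inequalities, a control sitting exactly on the rounded cutoff (a
#' boundary coincidence that cannot arise from continuous data) is not
#' admitted. The unrounded calibration values are returned alongside.
#'
#' @param results output of [moderated_test()] for all conditions.
#' @param control_site_ids character vector of known-effector site ids;
#'   every id must be quantified (non-NA result) in at least one condition.
#' @return `threshold_set` with attributes `raw_log2fc` and `raw_fdr` (the
#'   unrounded maxima) and `fdr_specific = fdr_call / 2`,
#'   `log2fc_up = -log2fc_down`.
#' @export
calibrate_thresholds <- function(results, control_site_ids) {
  if (!length(control_site_ids)) {
    .stop_phosfx("phosfx_calibration_error", "empty control site list")
  }
  ctrl <- results[results$site_id %in% control_site_ids & !is.na(results$fdr), ]
  seen <- unique(ctrl$site_id)
  absent <- setdiff(control_site_ids, seen)
  if (length(absent)) {
    .stop_phosfx("phosfx_calibration_error",
                 "control site(s) absent from results: %s",
                 paste(absent, collapse = ", "))
  }
  raw_fc <- max(ctrl$summary_log2fc)
  raw_fdr <- max(ctrl$fdr)
  if (raw_fc >= 0) {
    .stop_phosfx("phosfx_calibration_error",
                 "control sites include non-negative log2FC (%g); cannot calibrate a down threshold",
                 raw_fc)
  }
  fc_cut <- .ceil_grid(raw_fc)
  fdr_cut <- .ceil_grid(raw_fdr)
  ts <- threshold_set(log2fc_down = fc_cut, log2fc_up = -fc_cut,
                      fdr_call = fdr_cut, fdr_specific = fdr_cut / 2)
  attr(ts, "raw_log2fc") <- raw_fc
  attr(ts, "raw_fdr") <- raw_fdr
  ts
}

#' Call per-condition modulation
#'
#' A site is called `down` when `fdr < fdr_call` and
#' `summary_log2fc < log2fc_down`; `up` when `fdr < fdr_call` and
#' `summary_log2fc > log2fc_up`; otherwise `unchanged`. All inequalities are
#' strict. Sites with an `NA` test result (too few replicates) are called
#' `NA`.
#'
#' @param results output of [moderated_test()].
#' @param thresholds a [threshold_set()].
#' @return `results` with an added `call` column
#'   (`down` / `up` / `unchanged` / `NA`).
#' @export
call_modulation <- function(results, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  call <- rep(NA_character_, nrow(results))
  ok <- !is.na(results$fdr) & !is.na(results$summary_log2fc)
  call[ok] <- "unchanged"
  call[ok & results$fdr < thresholds$fdr_call &
         results$summary_log2fc < thresholds$log2fc_down] <- "down"
  call[ok & results$fdr < thresholds$fdr_call &
         results$summary_log2fc > thresholds$log2fc_up] <- "up"
  results$call <- call
  results
}

#' Classify sites into shared and inhibitor-specific effectors
#'
#' Combines per-condition modulation calls across all inhibitor conditions:
#' * `shared_effector` — called `down` in every condition (a site with an
#'   `NA` call in any condition is excluded, never imputed);
#' * `specific:<condition>` — passes the stricter cut
#'   (`fdr < fdr_specific` and `summary_log2fc < log2fc_down`) in one
#'   condition while not being down-called in any other;
#' * `partial` — down in at least one but not all conditions, and not
#'   specific;
#' * `none` — everything else.
#' The four classes partition the tested site universe.
#'
#' @param calls output of [call_modulation()] covering all conditions.
#' @param thresholds the [threshold_set()] used for the calls.
#' @param strict_other_condition if `TRUE`, a specific effector additionally
#'   requires `summary_log2fc >= log2fc_down` (not merely "not down-called")
#'   in every other condition.
#' @return data.frame: `site_id`, `class`.
#' @export
classify_effectors <- function(calls, thresholds, strict_other_condition = FALSE) {
  stopifnot(inherits(thresholds, "threshold_set"))
  conds <- unique(calls$condition)
  ids <- unique(calls$site_id)
  per_cond <- table(calls$site_id, calls$condition)
  if (any(per_cond != 1L)) {
    .stop_phosfx("phosfx_input_error",
                 "every site must appear exactly once per condition")
  }
  wide <- function(col) {
    m <- matrix(NA, nrow = length(ids), ncol = length(conds),
                dimnames = list(ids, conds))
    m[cbind(match(calls$site_id, ids), match(calls$condition, conds))] <- calls[[col]]
    m
  }
  call_m <- wide("call")
  fdr_m <- wide("fdr")
  fc_m <- wide("summary_log2fc")

  down_m <- !is.na(call_m) & call_m == "down"
  shared <- rowSums(down_m) == length(conds)  # NA call => not down => excluded
  cls <- rep("none", length(ids))
  cls[shared] <- "shared_effector"

  strict_m <- !is.na(fdr_m) & fdr_m < thresholds$fdr_specific &
    !is.na(fc_m) & fc_m < thresholds$log2fc_down
  for (j in seq_along(conds)) {
    others <- setdiff(seq_along(conds), j)
    other_ok <- rowSums(down_m[, others, drop = FALSE]) == 0L
    if (strict_other_condition) {
      above <- is.na(fc_m[, others, drop = FALSE]) |
        fc_m[, others, drop = FALSE] >= thresholds$log2fc_down
      other_ok <- other_ok & rowSums(above) == length(others)
    }
    spec <- strict_m[, j] & other_ok & !shared
    cls[spec] <- paste0("specific:", conds[j])
  }
  partial <- cls == "none" & rowSums(down_m) > 0L
  cls[partial] <- "partial"
  data.frame(site_id = ids, class = cls, stringsAsFactors = FALSE)
}

#' Per-condition modulation counts
#'
#' @param calls output of [call_modulation()].
#' @return data.frame of counts of down / up / unchanged / NA calls per
#'   condition.
#' @export
count_calls <- function(calls) {
  tab <- table(calls$condition, factor(ifelse(is.na(calls$call), "NA", calls$call),
                                       levels = c("down", "up", "unchanged", "NA")))
  df <- as.data.frame.matrix(tab)
  df <- cbind(condition = rownames(df), df)
  rownames(df) <- NULL
  df
}
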