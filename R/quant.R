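# SILAC quantification: class I filtering, H/L ratios, proteome
# normalization, labelling QC.

#' Partition phosphosites into class I and rejected sites
#'
#' Class I sites have a confidently localized phosphate: localization
#' probability >= 0.75 and localization score difference >= 5. Both cutoffs
#' are inclusive. Records with a missing probability or score difference are
#' rejected.
#'
#' @param sites phosphosite table ([read_phosphosite_table()]).
#' @return list with data.frames `kept` and `rejected`; the partition is
#'   exhaustive and disjoint.
#' @export
filter_class1 <- function(sites) {
  ok <- !is.na(sites$localization_prob) & !is.na(sites$score_diff) &
    sites$localization_prob >= 0.75 & sites$score_diff >= 5
  n_na <- sum(is.na(sites$localization_prob) | is.na(sites$score_diff))
  if (n_na > 0L) {
    message(sprintf("filter_class1: %d site(s) rejected for missing localization evidence", n_na))
  }
  list(kept = sites[ok, , drop = FALSE], rejected = sites[!ok, , drop = FALSE])
}

#' Heavy/light SILAC ratio
#'
#' Elementwise H/L; missing whenever either channel is missing or the
#' denominator is zero.
#'
#' @param h,l numeric vectors of heavy and light intensities (`NA` = missing).
#' @return numeric vector of ratios.
#' @export
silac_ratio <- function(h, l) {
  r <- ifelse(is.na(h) | is.na(l) | l <= 0, NA_real_, h / l)
  as.numeric(r)
}

#' Per-site H/L ratio for one condition and replicate
#'
#' @param sites site or protein table.
#' @param condition condition label.
#' @param replicate replicate number.
#' @return numeric vector, one ratio per row of `sites`.
#' @export
site_ratio <- function(sites, condition, replicate) {
  hc <- intensity_col("H", condition, replicate)
  lc <- intensity_col("L", condition, replicate)
  .check_required(sites, c(hc, lc), "intensity table")
  silac_ratio(sites[[hc]], sites[[lc]])
}

#' Normalize a phosphosite ratio to the proteome
#'
#' log2 of the phosphosite H/L ratio divided by the matching protein H/L
#' ratio; a value of -1 corresponds to a fold-change of 0.5, i.e. a 50%
#' reduction in phosphorylation relative to the vehicle control.
#'
#' @param site_ratio,protein_ratio positive numeric vectors (`NA` = missing).
#' @return numeric vector of log2 fold-changes.
#' @export
normalize_to_proteome <- function(site_ratio, protein_ratio) {
  bad <- (!is.na(site_ratio) & site_ratio <= 0) |
    (!is.na(protein_ratio) & protein_ratio <= 0)
  if (any(bad)) .stop_phosfx("phosfx_input_error", "ratios must be positive")
  log2(site_ratio / protein_ratio)
}

#' Proteome-normalized log2 ratios for all sites, conditions and replicates
#'
#' For every site, condition and replicate, computes
#' `log2((site H/L) / (protein H/L))`. The result is missing whenever either
#' the phosphosite or the matching protein ratio is missing. Sites whose
#' protein is absent from the protein table are normalized against a protein
#' ratio of 1.0 and flagged (`protein_normalized = FALSE`) rather than
#' dropped, so that phospho-only proteins remain visible downstream.
#'
#' @param sites phosphosite table (typically the `kept` part of
#'   [filter_class1()]).
#' @param proteins protein table.
#' @return long data.frame: `site_id`, `condition`, `replicate`, `log2fc`,
#'   `protein_normalized`.
#' @export
normalize_sites <- function(sites, proteins) {
  conds <- table_conditions(sites)
  reps <- table_replicates(sites)
  prot_idx <- match(sites$protein_id, proteins$protein_id)
  out <- vector("list", length(conds) * length(reps))
  k <- 0L
  for (cond in conds) {
    for (r in reps) {
      sr <- site_ratio(sites, cond, r)
      pr <- rep(1.0, nrow(sites))
      has_prot <- !is.na(prot_idx)
      if (any(has_prot)) {
        pr_all <- site_ratio(proteins, cond, r)[prot_idx[has_prot]]
        pr[has_prot] <- pr_all
      }
      # protein present in the table but not quantified in this replicate
      # => normalized ratio is missing (invariant); orphan proteins keep 1.0
      k <- k + 1L
      out[[k]] <- data.frame(
        site_id = sites$site_id, condition = cond, replicate = r,
        log2fc = normalize_to_proteome(sr, pr),
        protein_normalized = has_prot, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$site_id, sites$site_id),
                   match(res$condition, conds), res$replicate), ]
  rownames(res) <- NULL
  res
}

#' Per-site, per-condition replicate summary
#'
#' The replicate summary is the median of the non-missing replicate log2
#' ratios (robust; the statistical test consumes the per-replicate values,
#' not this summary).
#'
#' @param normalized output of [normalize_sites()].
#' @return data.frame: `site_id`, `condition`, `summary_log2fc`, `n_obs`,
#'   `protein_normalized`.
#' @export
summarize_sites <- function(normalized) {
  key <- interaction(normalized$site_id, normalized$condition, drop = TRUE, lex.order = FALSE)
  split_fc <- split(normalized$log2fc, key)
  split_id <- split(normalized$site_id, key)
  split_cond <- split(normalized$condition, key)
  split_flag <- split(normalized$protein_normalized, key)
  res <- data.frame(
    site_id = vapply(split_id, `[`, "", 1L),
    condition = vapply(split_cond, `[`, "", 1L),
    summary_log2fc = vapply(split_fc, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else stats::median(v)
    }, 0),
    n_obs = vapply(split_fc, function(v) sum(!is.na(v)), 0L),
    protein_normalized = vapply(split_flag, `[`, NA, 1L),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' SILAC label incorporation
#'
#' Percent of labelled peptide signal: `100 * labelled / (labelled +
#' unlabelled)`. Used to monitor heavy amino-acid incorporation (and, with
#' the roles swapped, proline conversion) before trusting SILAC ratios.
#'
#' @param labelled,unlabelled non-negative counts or intensities, not both 0.
#' @return percentage in `[0, 100]`.
#' @export
label_incorporation <- function(labelled, unlabelled) {
  if (any(labelled < 0 | unlabelled < 0, na.rm = TRUE)) {
    .stop_phosfx("phosfx_input_error", "inputs must be non-negative")
  }
  if (any(labelled + unlabelled == 0, na.rm = TRUE)) {
    .stop_phosfx("phosfx_input_error", "labelled and unlabelled both zero")
  }
  100 * labelled / (labelled + unlabelled)
}
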