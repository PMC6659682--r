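# Kinase specificity from positional-scanning peptide arrays: library
# enumeration, PSSM construction, additive log2 scoring of phosphosite
# flanks, kinase ranking.

#' Enumerate a positional-scanning peptide library
#'
#' Parses a library template such as
#' `"Y-A-x-x-x-x-x-S/T-x-x-x-x-A-G-K-K"` (tokens separated by `-`;
#' parenthesized modifications such as `K(biotin)` are ignored) and
#' enumerates the peptide mixtures: one mixture per (variable position,
#' fixed residue) pair, where each `x` position is fixed in turn to each of
#' the 20 standard amino acids while the remaining `x` positions hold an
#' equimolar mixture of the 17 amino acids excluding Cys, Ser and Thr.
#' Positions are reported relative to the central `S/T` phospho-acceptor.
#'
#' @param template template string; must contain at least one `x` and one
#'   acceptor token (`S/T`).
#' @return data.frame with one row per mixture: `position` (e.g. `"-3"`),
#'   `fixed_residue`; attribute `degenerate_alphabet` holds the 17-residue
#'   mixture alphabet.
#' @export
enumerate_library <- function(template) {
  tokens <- if (grepl("-", template, fixed = TRUE)) {
    strsplit(template, "-", fixed = TRUE)[[1]]
  } else {
    strsplit(template, "", fixed = TRUE)[[1]]
  }
  tokens <- sub("\\(.*\\)$", "", trimws(tokens))  # strip e.g. "(biotin)"
  acceptor <- which(tokens %in% c("S/T", "s/t"))
  if (length(acceptor) != 1L) {
    .stop_phosfx("phosfx_template_error",
                 "template must contain exactly one S/T acceptor token")
  }
  variable <- which(tokens == "x")
  if (!length(variable)) {
    .stop_phosfx("phosfx_template_error", "template has no variable 'x' position")
  }
  rel <- variable - acceptor
  pos_label <- ifelse(rel > 0, paste0("+", rel), as.character(rel))
  out <- data.frame(
    position = rep(pos_label, each = 20L),
    fixed_residue = rep(AA_ALPHABET20, times = length(variable)),
    stringsAsFactors = FALSE
  )
  attr(out, "degenerate_alphabet") <- DEGENERATE_ALPHABET
  out
}

#' Build a specificity matrix from raw peptide-array quantifications
#'
#' Normalizes each position column to an average value of unity over the 20
#' residues, then log2-transforms:
#' `value[r, p] = log2(raw[r, p] / mean_r'(raw[r', p]))`.
#'
#' @param array positive 20 x 9 raw quantification matrix (rows
#'   [AA_ALPHABET20], columns [PSSM_POSITIONS]).
#' @return 20 x 9 log2-scale specificity matrix; exponentiated, each
#'   position column has mean exactly 1.
#' @export
build_pssm <- function(array) {
  if (!is.matrix(array) || any(dim(array) != c(20L, 9L))) {
    .stop_phosfx("phosfx_input_error", "array must be a 20 x 9 matrix")
  }
  if (any(!is.finite(array)) || any(array <= 0)) {
    .stop_phosfx("phosfx_input_error", "raw quantifications must be positive and finite")
  }
  m <- log2(sweep(array, 2L, colMeans(array), "/"))
  dimnames(m) <- list(AA_ALPHABET20, PSSM_POSITIONS)
  m
}

#' Average replicate specificity matrices
#'
#' Replicate assays are normalized individually ([build_pssm()]) and then
#' averaged on the log2 scale (elementwise mean). Set
#' `order = "average_first"` to average the raw matrices before
#' normalization instead.
#'
#' @param arrays list of raw 20 x 9 quantification matrices.
#' @param order `"normalize_first"` (default) or `"average_first"`.
#' @return 20 x 9 log2-scale specificity matrix.
#' @export
average_pssms <- function(arrays, order = c("normalize_first", "average_first")) {
  order <- match.arg(order)
  stopifnot(length(arrays) >= 1L)
  if (order == "average_first") {
    build_pssm(Reduce(`+`, arrays) / length(arrays))
  } else {
    Reduce(`+`, lapply(arrays, build_pssm)) / length(arrays)
  }
}

#' Score a phosphosite flank against a specificity matrix
#'
#' Additive log2 scoring: the score is the sum, over the flank positions
#' -5..-1 and +1..+4 relative to the central phospho-acceptor, of the
#' matrix value for the residue observed at that position. Terminal padding
#' (`_`) and residues absent from the matrix contribute 0; position 0 (the
#' acceptor) never contributes, and S and T acceptors are treated equally.
#'
#' @param flank 15-character sequence window, acceptor at position 8; the
#'   acceptor must be S or T for an S/T-directed matrix.
#' @param pssm log2-scale specificity matrix ([build_pssm()]).
#' @return numeric score.
#' @export
score_flank <- function(flank, pssm) {
  if (nchar(flank) != 15L) {
    .stop_phosfx("phosfx_input_error", "flank must be a 15-mer, got %d characters", nchar(flank))
  }
  center <- substr(flank, 8L, 8L)
  if (!center %in% c("S", "T")) {
    .stop_phosfx("phosfx_acceptor_error",
                 "flank center '%s' is not an S/T acceptor", center)
  }
  offsets <- c(-5L:-1L, 1L:4L)
  residues <- substring(flank, 8L + offsets, 8L + offsets)
  score <- 0
  for (k in seq_along(offsets)) {
    r <- residues[k]
    if (r %in% rownames(pssm)) score <- score + pssm[r, PSSM_POSITIONS[k]]
  }
  score
}

#' Rank kinases for a phosphosite flank
#'
#' Scores the flank against each specificity matrix and ranks kinases by
#' descending score; ties are broken lexicographically by kinase name.
#' Matrices incompatible with the flank's acceptor are skipped.
#'
#' @param flank 15-mer flank window.
#' @param matrices named list of log2-scale specificity matrices.
#' @return data.frame `kinase`, `score`, `rank` (1 = best), sorted by rank;
#'   zero rows (with a warning) when no matrix is compatible.
#' @export
rank_kinases <- function(flank, matrices) {
  stopifnot(length(matrices) >= 1L, !is.null(names(matrices)))
  scores <- vapply(names(matrices), function(k) {
    tryCatch(score_flank(flank, matrices[[k]]),
             phosfx_acceptor_error = function(e) NA_real_)
  }, 0)
  ok <- !is.na(scores)
  if (!any(ok)) {
    warning("no specificity matrix is compatible with this flank")
    return(data.frame(kinase = character(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  res <- data.frame(kinase = names(scores)[ok], score = scores[ok],
                    stringsAsFactors = FALSE)
  res <- res[order(-res$score, res$kinase), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}
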