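# Tabular and sequence I/O: MaxQuant-style site/protein tables (TSV),
# FASTA flank extraction, PSSM matrices, control-site lists.

#' Name of an intensity column
#'
#' Intensity columns follow the pattern `intensity_<channel>_<condition>_r<rep>`
#' with channel one of H (heavy, drug treated), M (medium, super-SILAC
#' internal standard) or L (light, vehicle control).
#'
#' @param channel "H", "M" or "L".
#' @param condition condition label, e.g. "BRAFi".
#' @param replicate integer replicate number.
#' @return character column name.
#' @export
intensity_col <- function(channel, condition, replicate) {
  sprintf("intensity_%s_%s_r%d", channel, condition, as.integer(replicate))
}

.intensity_layout <- function(nms) {
  m <- regmatches(nms, regexec("^intensity_([HML])_(.+)_r([0-9]+)$", nms))
  hit <- lengths(m) == 4L
  if (!any(hit)) return(NULL)
  parts <- do.call(rbind, m[hit])
  data.frame(
    column = parts[, 1L], channel = parts[, 2L], condition = parts[, 3L],
    replicate = as.integer(parts[, 4L]), stringsAsFactors = FALSE
  )
}

#' Conditions / replicates present in a site or protein table
#'
#' @param x a table read by [read_phosphosite_table()] or
#'   [read_protein_table()] (or produced by [simulate_experiment()]).
#' @return character vector of condition labels (in column order) or sorted
#'   integer vector of replicate numbers.
#' @export
table_conditions <- function(x) {
  lay <- .intensity_layout(names(x))
  if (is.null(lay)) .stop_phosfx("phosfx_schema_error", "no intensity columns found")
  unique(lay$condition)
}

#' @rdname table_conditions
#' @export
table_replicates <- function(x) {
  lay <- .intensity_layout(names(x))
  if (is.null(lay)) .stop_phosfx("phosfx_schema_error", "no intensity columns found")
  sort(unique(lay$replicate))
}

.num_or_die <- function(x, col) {
  if (is.numeric(x)) return(x)
  blank <- is.na(x) | x == "" | x == "NA"
  x2 <- suppressWarnings(as.numeric(x))
  bad <- which(!blank & is.na(x2))
  if (length(bad)) {
    .stop_phosfx("phosfx_parse_error",
                 "column '%s': malformed number '%s' at line %d",
                 col, x[bad[1L]], bad[1L] + 1L)  # +1 for the header line
  }
  x2
}

.apply_column_map <- function(df, column_map) {
  if (is.null(column_map)) return(df)
  stopifnot(is.character(column_map), !is.null(names(column_map)))
  for (canonical in names(column_map)) {
    src <- column_map[[canonical]]
    if (!src %in% names(df)) {
      .stop_phosfx("phosfx_schema_error",
                   "column map names '%s' for '%s' but the file has no such column",
                   src, canonical)
    }
    names(df)[names(df) == src] <- canonical
  }
  df
}

.read_tsv <- function(path) {
  if (!file.exists(path)) .stop_phosfx("phosfx_io_error", "file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

.check_required <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    .stop_phosfx("phosfx_schema_error", "%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", "))
  }
}

#' Read a phosphosite quantification table
#'
#' Reads a tab-separated table with one row per phosphosite. Required columns:
#' `site_id`, `protein_id`, `position` (1-based residue index), `residue`
#' (S/T/Y), `localization_prob`, `score_diff`, `flank` (15-mer sequence
#' window, `_`-padded), plus per-channel intensity columns named as in
#' [intensity_col()]. Intensities recorded as 0 or left empty are treated as
#' missing (MaxQuant writes 0 for non-quantified channels). Files in other
#' dialects (e.g. MaxQuant "Phospho (STY)Sites" exports) are supported by
#' passing `column_map`, a named character vector mapping canonical names to
#' the names used in the file.
#'
#' @param path path to a TSV file.
#' @param column_map optional named character vector, e.g.
#'   `c(localization_prob = "Localization prob")`.
#' @return data.frame of site records with numeric intensity columns
#'   (missing = `NA`).
#' @export
read_phosphosite_table <- function(path, column_map = NULL) {
  df <- .apply_column_map(.read_tsv(path), column_map)
  .check_required(df, c("site_id", "protein_id", "position", "residue",
                        "localization_prob", "score_diff", "flank"),
                  "phosphosite table")
  df$site_id <- as.character(df$site_id)
  df$protein_id <- as.character(df$protein_id)
  df$position <- .num_or_die(df$position, "position")
  df$localization_prob <- .num_or_die(df$localization_prob, "localization_prob")
  df$score_diff <- .num_or_die(df$score_diff, "score_diff")
  .finish_intensity_table(df, "phosphosite table")
}

#' Read a protein-group quantification table
#'
#' Tab-separated, one row per protein group; requires `protein_id` plus
#' intensity columns as in [read_phosphosite_table()]. Zero intensities are
#' treated as missing.
#'
#' @inheritParams read_phosphosite_table
#' @return data.frame of protein records.
#' @export
read_protein_table <- function(path, column_map = NULL) {
  df <- .apply_column_map(.read_tsv(path), column_map)
  .check_required(df, "protein_id", "protein table")
  df$protein_id <- as.character(df$protein_id)
  .finish_intensity_table(df, "protein table")
}

.finish_intensity_table <- function(df, what) {
  lay <- .intensity_layout(names(df))
  if (is.null(lay)) .stop_phosfx("phosfx_schema_error", "%s has no intensity columns", what)
  for (col in lay$column) {
    v <- .num_or_die(df[[col]], col)
    v[!is.na(v) & v <= 0] <- NA_real_  # 0 means "not quantified", never ratio 0
    df[[col]] <- v
  }
  df
}

#' Write site / protein tables
#'
#' Writes the TSV dialect that [read_phosphosite_table()] and
#' [read_protein_table()] read; missing intensities are written as 0
#' (round-tripping to `NA` on read).
#'
#' @param df table to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(df, path) {
  lay <- .intensity_layout(names(df))
  if (!is.null(lay)) {
    for (col in lay$column) {
      v <- df[[col]]
      v[is.na(v)] <- 0
      df[[col]] <- v
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract 15-mer flanking windows around phosphosites from a FASTA file
#'
#' The window spans seven residues either side of the phospho-acceptor
#' (center, index 8 of 15); positions beyond the protein termini are padded
#' with `_`.
#'
#' @param fasta_path path to a protein FASTA file; record names are the first
#'   whitespace-delimited word of each header.
#' @param sites data.frame with columns `protein_id` and `position` (1-based).
#' @return character vector of 15-mers, one per row of `sites`.
#' @export
extract_flanks <- function(fasta_path, sites) {
  stopifnot(all(c("protein_id", "position") %in% names(sites)))
  seqs <- Biostrings::readAAStringSet(fasta_path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  missing <- setdiff(unique(sites$protein_id), names(seqs))
  if (length(missing)) {
    .stop_phosfx("phosfx_lookup_error", "protein(s) absent from FASTA: %s",
                 paste(missing, collapse = ", "))
  }
  vapply(seq_len(nrow(sites)), function(i) {
    s <- as.character(seqs[[sites$protein_id[i]]])
    pos <- sites$position[i]
    if (pos < 1L || pos > nchar(s)) {
      .stop_phosfx("phosfx_bounds_error",
                   "position %d outside protein %s (length %d)",
                   pos, sites$protein_id[i], nchar(s))
    }
    padded <- paste0(strrep("_", 7L), s, strrep("_", 7L))
    substr(padded, pos, pos + 14L)  # pos in padded coords = pos + 7 - 7
  }, character(1L))
}

#' Read / write a specificity matrix (PSSM) as TSV
#'
#' The on-disk layout is a 20 x 9 matrix: rows are the 20 standard amino
#' acids in alphabetical order (first column `residue`), columns are the
#' flank positions `-5`..`-1`, `+1`..`+4`.
#'
#' @param path file path.
#' @return `read_pssm`: numeric 20 x 9 matrix with residue rownames and
#'   position colnames.
#' @export
read_pssm <- function(path) {
  df <- .read_tsv(path)
  .check_required(df, "residue", "PSSM file")
  m <- as.matrix(df[, setdiff(names(df), "residue"), drop = FALSE])
  rownames(m) <- df$residue
  if (!identical(rownames(m), AA_ALPHABET20) ||
      !identical(colnames(m), PSSM_POSITIONS)) {
    .stop_phosfx("phosfx_schema_error",
                 "PSSM must have the 20 residues (alphabetical) x positions %s",
                 paste(PSSM_POSITIONS, collapse = ","))
  }
  storage.mode(m) <- "double"
  m
}

#' @rdname read_pssm
#' @param pssm 20 x 9 numeric matrix.
#' @export
write_pssm <- function(pssm, path) {
  df <- data.frame(residue = rownames(pssm), pssm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a positive-control site list (one site_id per line)
#'
#' @param path text file; blank lines and lines starting with `#` are skipped.
#' @return character vector of site ids.
#' @export
read_site_list <- function(path) {
  if (!file.exists(path)) .stop_phosfx("phosfx_io_error", "file not found: %s", path)
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
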