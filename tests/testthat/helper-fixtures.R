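# Fixture builders shared across the test files. All fixtures are built in
# code; nothing is read from disk except files the helpers write themselves.

# A minimal three-site phosphosite table with one condition x two replicates.
tiny_site_table <- function() {
  df <- data.frame(
    site_id = c("A_S10", "B_T20", "C_S5"),
    protein_id = c("A", "B", "C"),
    position = c(10L, 20L, 5L),
    residue = c("S", "T", "S"),
    localization_prob = c(0.99, 0.80, 0.60),
    score_diff = c(30, 6, 80),
    flank = c("AAAAAAASAAAAAAA", "LLLLLLLTLLLLLLL", "GGGGGGGSGGGGGGG"),
    stringsAsFactors = FALSE
  )
  df[[intensity_col("H", "BRAFi", 1)]] <- c(2000, 1500, NA)
  df[[intensity_col("L", "BRAFi", 1)]] <- c(1000, 3000, 500)
  df[[intensity_col("H", "BRAFi", 2)]] <- c(900, 400, 800)
  df[[intensity_col("L", "BRAFi", 2)]] <- c(1000, 800, 800)
  df
}

tiny_protein_table <- function() {
  df <- data.frame(protein_id = c("A", "B"), stringsAsFactors = FALSE)
  df[[intensity_col("H", "BRAFi", 1)]] <- c(1000, 2000)
  df[[intensity_col("L", "BRAFi", 1)]] <- c(1000, 1000)
  df[[intensity_col("H", "BRAFi", 2)]] <- c(500, NA)
  df[[intensity_col("L", "BRAFi", 2)]] <- c(1000, 1000)
  df
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_fasta_fixture <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}

# O(n^2) brute-force Benjamini-Hochberg step-up, independent of bh_fdr():
# adj_i = min over all j with p_j >= p_i of n * p_j / rank(p_j), capped at 1.
brute_force_bh <- function(p) {
  n <- length(p)
  rk <- rank(p, ties.method = "max")
  vapply(seq_len(n), function(i) {
    cand <- vapply(which(p >= p[i]), function(j) n * p[j] / rk[j], 0)
    min(1, cand)
  }, 0)
}

# Straight-line transcription of the moderated one-sample t equations,
# kept deliberately independent of moderated_t().
transcribed_moderated_t <- function(v, d0, s02) {
  v <- v[!is.na(v)]
  n <- length(v)
  d <- n - 1
  s2 <- sum((v - mean(v))^2) / d
  s2p <- if (is.infinite(d0)) s02 else (d0 * s02 + d * s2) / (d0 + d)
  tm <- mean(v) / sqrt(s2p / n)
  df <- d0 + d
  p <- if (is.infinite(df)) 2 * pnorm(-abs(tm)) else 2 * pt(-abs(tm), df)
  list(t = tm, df = df, p = p, s2_post = s2p)
}

# Per-site transcription of the effector classification rules, written as
# plain if/else over one site's three-condition calls (oracle for the
# vectorized classify_effectors()).
oracle_classify_one <- function(call, fdr, fc, th) {
  is_down <- !is.na(call) & call == "down"
  if (all(is_down)) return("shared_effector")
  for (j in seq_along(call)) {
    strict <- !is.na(fdr[j]) && fdr[j] < th$fdr_specific &&
      !is.na(fc[j]) && fc[j] < th$log2fc_down
    if (strict && !any(is_down[-j])) return(paste0("specific:", names(call)[j]))
  }
  if (any(is_down)) return("partial")
  "none"
}
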