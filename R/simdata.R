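# Synthetic SILAC phosphoproteomics experiments and peptide-array data with
# known ground truth.

#' Simulation configuration
#'
#' Describes a synthetic triple-inhibitor SILAC phosphoproteomics
#' experiment. The defaults emulate the study design the package targets:
#' three inhibitor conditions (BRAFi, MEKi, ERKi) in biological triplicate,
#' a small set of down-modulated effector sites shared across all
#' conditions, smaller sets specific to one condition each, and a majority
#' of null sites.
#'
#' @param n_sites number of phosphosites.
#' @param n_proteins number of proteins carrying the sites.
#' @param n_replicates biological replicates per condition.
#' @param conditions ordered condition labels.
#' @param frac_shared fraction of sites planted as shared effectors.
#' @param frac_specific fraction planted as condition-specific effectors,
#'   per condition (scalar or one value per condition).
#' @param effect_log2fc planted effect, log2 units (negative =
#'   down-modulated).
#' @param noise_sd replicate noise sd of the normalized log2 ratio, log2
#'   units.
#' @param missing_rate probability that a phosphosite replicate measurement
#'   (its H and L intensities together) is missing, completely at random.
#' @param frac_class2 fraction of sites generated with localization evidence
#'   that fails the class I filter.
#' @param protein_ratio_sd sd of per-protein log2 H/L drift (absorbed by
#'   proteome normalization).
#' @param frac_orphan fraction of sites whose protein is withheld from the
#'   protein table (exercising the normalize-against-1 path).
#' @param base_intensity_meanlog,base_intensity_sdlog lognormal parameters
#'   of light-channel intensities.
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 2000L, n_proteins = 800L, n_replicates = 3L,
                       conditions = c("BRAFi", "MEKi", "ERKi"),
                       frac_shared = 0.02, frac_specific = 0.01,
                       effect_log2fc = -1.5, noise_sd = 0.25,
                       missing_rate = 0.1, frac_class2 = 0.1,
                       protein_ratio_sd = 0.3, frac_orphan = 0.02,
                       base_intensity_meanlog = log(1e6),
                       base_intensity_sdlog = 1,
                       seed = 1L) {
  frac_specific <- rep_len(frac_specific, length(conditions))
  cfg <- list(n_sites = as.integer(n_sites), n_proteins = as.integer(n_proteins),
              n_replicates = as.integer(n_replicates), conditions = conditions,
              frac_shared = frac_shared, frac_specific = frac_specific,
              effect_log2fc = effect_log2fc, noise_sd = noise_sd,
              missing_rate = missing_rate, frac_class2 = frac_class2,
              protein_ratio_sd = protein_ratio_sd, frac_orphan = frac_orphan,
              base_intensity_meanlog = base_intensity_meanlog,
              base_intensity_sdlog = base_intensity_sdlog,
              seed = as.integer(seed))
  bad_frac <- function(x) any(x < 0 | x > 1)
  if (bad_frac(cfg$frac_shared) || bad_frac(cfg$frac_specific) ||
      bad_frac(cfg$missing_rate) || bad_frac(cfg$frac_class2) ||
      bad_frac(cfg$frac_orphan)) {
    .stop_phosfx("phosfx_config_error", "fractions must lie in [0, 1]")
  }
  if (cfg$frac_shared + sum(cfg$frac_specific) > 1) {
    .stop_phosfx("phosfx_config_error",
                 "frac_shared + sum(frac_specific) must not exceed 1")
  }
  if (cfg$noise_sd < 0 || cfg$protein_ratio_sd <= 0 || cfg$base_intensity_sdlog <= 0) {
    .stop_phosfx("phosfx_config_error", "sd parameters must be positive")
  }
  if (cfg$n_sites < 1L || cfg$n_proteins < 1L || cfg$n_replicates < 1L) {
    .stop_phosfx("phosfx_config_error", "counts must be positive")
  }
  structure(cfg, class = "sim_config")
}

.random_flank <- function(n, residue) {
  left <- replicate(n, paste(sample(AA_ALPHABET20, 7, replace = TRUE), collapse = ""))
  right <- replicate(n, paste(sample(AA_ALPHABET20, 7, replace = TRUE), collapse = ""))
  paste0(left, residue, right)
}

#' Simulate a triple-inhibitor SILAC phosphoproteomics experiment
#'
#' Generates channel-level intensities (not ratios): each protein's light
#' intensity is lognormal and its heavy channel carries a per-protein,
#' per-condition, per-replicate log2 drift; each phosphosite inherits its
#' protein's drift plus the planted effect and replicate noise, so that the
#' proteome-normalized log2 ratio is distributed
#' `Normal(true effect, noise_sd)`. Shared effectors carry `effect_log2fc`
#' in every condition, specific effectors only in theirs, null sites 0.
#' The medium (super-SILAC internal standard) channel is generated as the
#' geometric mean of heavy and light but is not used by any statistic.
#' Localization evidence is drawn so that `frac_class2` of sites fail the
#' class I filter; phosphosite replicate measurements are removed completely
#' at random at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return list with `sites` (phosphosite table), `proteins` (protein
#'   table) and `truth` (data.frame: `site_id`, `class`, one `true_<cond>`
#'   effect column per condition).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_sites; np <- config$n_proteins
  conds <- config$conditions; nr <- config$n_replicates

  protein_id <- sprintf("P%04d", seq_len(np))
  site_id <- sprintf("site%05d", seq_len(ns))
  site_protein <- sample(protein_id, ns, replace = TRUE)

  # planted classes
  n_shared <- round(config$frac_shared * ns)
  n_spec <- round(config$frac_specific * ns)
  lab <- rep("null", ns)
  pool <- sample.int(ns)
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  if (n_shared > 0) lab[take(n_shared)] <- "shared_effector"
  for (j in seq_along(conds)) {
    if (n_spec[j] > 0) lab[take(n_spec[j])] <- paste0("specific:", conds[j])
  }
  effect <- matrix(0, ns, length(conds), dimnames = list(site_id, conds))
  effect[lab == "shared_effector", ] <- config$effect_log2fc
  for (j in seq_along(conds)) {
    effect[lab == paste0("specific:", conds[j]), j] <- config$effect_log2fc
  }

  # localization evidence
  fails <- stats::runif(ns) < config$frac_class2
  loc_prob <- ifelse(fails,
                     stats::runif(ns, 0, 0.749),
                     stats::runif(ns, 0.75, 1))
  score_diff <- ifelse(fails & stats::runif(ns) < 0.5,
                       stats::runif(ns, 0, 4.99),
                       5 + stats::rexp(ns, rate = 1 / 20))

  residue <- sample(c("S", "T", "Y"), ns, replace = TRUE, prob = c(0.86, 0.12, 0.02))
  position <- sample.int(600L, ns, replace = TRUE)

  sites <- data.frame(
    site_id = site_id, protein_id = site_protein, position = position,
    residue = residue, localization_prob = loc_prob, score_diff = score_diff,
    flank = .random_flank(ns, residue), stringsAsFactors = FALSE
  )
  proteins <- data.frame(protein_id = protein_id, stringsAsFactors = FALSE)

  prot_row <- match(site_protein, protein_id)
  for (j in seq_along(conds)) {
    for (r in seq_len(nr)) {
      drift <- stats::rnorm(np, 0, config$protein_ratio_sd)
      pL <- stats::rlnorm(np, config$base_intensity_meanlog, config$base_intensity_sdlog)
      pH <- pL * 2^drift
      proteins[[intensity_col("L", conds[j], r)]] <- pL
      proteins[[intensity_col("H", conds[j], r)]] <- pH
      proteins[[intensity_col("M", conds[j], r)]] <- sqrt(pL * pH)

      obs <- drift[prot_row] + effect[, j] + stats::rnorm(ns, 0, config$noise_sd)
      sL <- stats::rlnorm(ns, config$base_intensity_meanlog, config$base_intensity_sdlog)
      sH <- sL * 2^obs
      gone <- stats::runif(ns) < config$missing_rate  # MCAR, replicate level
      sL[gone] <- NA_real_; sH[gone] <- NA_real_
      sites[[intensity_col("L", conds[j], r)]] <- sL
      sites[[intensity_col("H", conds[j], r)]] <- sH
      sites[[intensity_col("M", conds[j], r)]] <- ifelse(gone, NA_real_, sqrt(sL * sH))
    }
  }

  # withhold some proteins from the proteome table (phospho-only proteins)
  n_orphan <- round(config$frac_orphan * np)
  if (n_orphan > 0) {
    orphan <- sample(protein_id, n_orphan)
    proteins <- proteins[!proteins$protein_id %in% orphan, , drop = FALSE]
    rownames(proteins) <- NULL
  }

  truth <- data.frame(site_id = site_id, class = lab, stringsAsFactors = FALSE)
  for (j in seq_along(conds)) truth[[paste0("true_", conds[j])]] <- effect[, j]

  list(sites = sites, proteins = proteins, truth = truth)
}

#' Write simulation ground truth as TSV
#'
#' @param truth the `truth` component of [simulate_experiment()].
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' A deterministic "BRAF-like" linear-scale specificity truth matrix
#'
#' Linear-scale (positive) 20 x 9 preference matrix used as ground truth for
#' peptide-array simulations: preference for Leu/Met at the -3 position,
#' hydrophobic residues at +1, aromatic residues at +2, mild disfavoring of
#' acidic residues, neutral elsewhere.
#'
#' @param jitter_sd optional lognormal jitter (sdlog) applied cell-wise with
#'   `seed` to roughen the matrix; 0 = fully deterministic.
#' @param seed RNG seed used when `jitter_sd > 0`.
#' @return positive 20 x 9 matrix (rows [AA_ALPHABET20], columns
#'   [PSSM_POSITIONS]).
#' @export
example_specificity_truth <- function(jitter_sd = 0, seed = 1L) {
  m <- matrix(1, 20, 9, dimnames = list(AA_ALPHABET20, PSSM_POSITIONS))
  m[c("L", "M"), "-3"] <- 6
  m[c("L", "I", "V", "F", "M"), "+1"] <- 4
  m[c("F", "W", "Y"), "+2"] <- 5
  m[c("D", "E"), ] <- 0.5
  m["P", "+1"] <- 0.3
  if (jitter_sd > 0) {
    set.seed(seed)
    m <- m * stats::rlnorm(180, 0, jitter_sd)
  }
  m
}

#' Simulate a positional-scanning peptide-array quantification
#'
#' Generates the raw radiolabel-incorporation matrix an arrayed
#' positional-scanning peptide library would produce for a kinase with known
#' specificity: within each position, counts proportional to the truth
#' preferences (scaled so each position column sums to `total_counts`), with
#' multiplicative lognormal noise of coefficient of variation `noise_cv`.
#'
#' @param pssm_truth positive linear-scale 20 x 9 truth matrix.
#' @param total_counts expected total signal per position column.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer RNG seed.
#' @return 20 x 9 positive matrix of raw quantifications.
#' @export
simulate_peptide_array <- function(pssm_truth, total_counts = 1e5,
                                   noise_cv = 0.1, seed = 1L) {
  if (!is.matrix(pssm_truth) || any(dim(pssm_truth) != c(20L, 9L))) {
    .stop_phosfx("phosfx_input_error", "truth matrix must be 20 x 9")
  }
  if (any(!is.finite(pssm_truth)) || any(pssm_truth <= 0)) {
    .stop_phosfx("phosfx_input_error", "truth preferences must be positive and finite")
  }
  if (total_counts <= 0 || noise_cv < 0) {
    .stop_phosfx("phosfx_input_error", "total_counts must be > 0 and noise_cv >= 0")
  }
  set.seed(seed)
  scaled <- sweep(pssm_truth, 2L, colSums(pssm_truth), "/") * total_counts
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(stats::rlnorm(180, -sdlog^2 / 2, sdlog), 20L, 9L)
    scaled <- scaled * noise
  }
  dimnames(scaled) <- list(AA_ALPHABET20, PSSM_POSITIONS)
  scaled
}
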