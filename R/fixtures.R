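#' Derive a deterministic sub-seed
#'
#' One top-level seed controls an entire fixture tree; each generator draws
#' its own sub-seed from it so that any failing test names a single integer.
#'
#' @param seed Integer top-level seed.
#' @param idx Integer index of the component.
#' @return An integer seed below 2^31.
#' @export
sub_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(idx) * 9176) %% 2147483587)
}

#' Generate a ground-truth eluting peptide population
#'
#' Emits peptide-like features with log-normal maximum intensities, Gaussian
#' elution profiles, and a per-run retention-time drift, together with
#' inclusion-list candidates (predicted apexes are the undrifted truth) and
#' a ground-truth table joining every downstream metric back to the
#' generator.
#'
#' @param n_peptides Number of peptides.
#' @param intensity_meanlog,intensity_sdlog Log-normal parameters of the
#'   maximum elution intensity.
#' @param sigma_range Range (minutes) of the Gaussian elution width, drawn
#'   uniformly.
#' @param drift Drift model: `list(type = "constant", value, jitter_sd)` or
#'   `list(type = "linear", slope, jitter_sd)` (slope in min of drift per min
#'   of apex time). Jitter is additive Gaussian per peptide.
#' @param gradient_min Gradient span; apexes are uniform over
#'   `[0.05, 0.95] * gradient_min`.
#' @param seed Integer seed (mandatory).
#' @return A list with `peptides` (tibble: `id`, `mz`, `charge`, `apex_rt`,
#'   `peak_sigma`, `max_intensity`, `rt_drift`), `candidates` (tibble: `id`,
#'   `mz`, `charge`, `apex_rt_min`), and `truth` (the peptide tibble plus
#'   the drift model).
#' @export
make_lcms_population <- function(n_peptides = 300,
                                 intensity_meanlog = log(1e4),
                                 intensity_sdlog = 1,
                                 sigma_range = c(0.15, 0.35),
                                 drift = list(type = "constant", value = 0,
                                              jitter_sd = 0),
                                 gradient_min = 60,
                                 seed) {
  stopifnot(!missing(seed), n_peptides > 0)
  set.seed(seed)
  apex <- stats::runif(n_peptides, 0.05 * gradient_min, 0.95 * gradient_min)
  drift_base <- switch(drift$type,
    constant = rep(drift$value, n_peptides),
    linear = drift$slope * apex,
    stop("unknown drift model: ", drift$type, call. = FALSE))
  jit <- if (isTRUE(drift$jitter_sd > 0)) {
    stats::rnorm(n_peptides, 0, drift$jitter_sd)
  } else 0
  peptides <- tibble::tibble(
    id = sprintf("pep%05d", seq_len(n_peptides)),
    mz = stats::runif(n_peptides, 400, 1200),
    charge = sample(2:3, n_peptides, replace = TRUE),
    apex_rt = apex,
    peak_sigma = stats::runif(n_peptides, sigma_range[1], sigma_range[2]),
    max_intensity = stats::rlnorm(n_peptides, intensity_meanlog,
                                  intensity_sdlog),
    rt_drift = drift_base + jit
  )
  candidates <- tibble::tibble(id = peptides$id, mz = peptides$mz,
                               charge = peptides$charge,
                               apex_rt_min = peptides$apex_rt)
  list(peptides = peptides, candidates = candidates,
       truth = dplyr::mutate(peptides, drift_type = drift$type))
}

#' Build an inclusion list over population candidates
#'
#' Convenience constructor pairing [make_lcms_population()] candidates with
#' priorities and fill times.
#'
#' @param candidates Candidate tibble (`id`, `mz`, `charge`, `apex_rt_min`).
#' @param priority Integer vector (recycled) of initial priorities.
#' @param ms2_enabled Logical vector (recycled); calibration-only entries are
#'   `FALSE`.
#' @param max_fill_ms Numeric vector (recycled) of maximum fill times.
#' @return An inclusion-list tibble.
#' @export
inclusion_list <- function(candidates, priority = 0L, ms2_enabled = TRUE,
                           max_fill_ms = 500) {
  tibble::tibble(
    id = candidates$id, mz = candidates$mz, charge = candidates$charge,
    apex_rt_min = candidates$apex_rt_min,
    priority = as.integer(rep_len(priority, nrow(candidates))),
    ms2_enabled = rep_len(ms2_enabled, nrow(candidates)),
    max_fill_ms = rep_len(max_fill_ms, nrow(candidates))
  )
}

random_sequences <- function(n, min_len = 7, max_len = 18) {
  aas <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]  # no K/R inside
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    paste0(paste(sample(aas, len - 1, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1))
}

#' Generate a synthetic PSM (evidence-style) table
#'
#' Target PEPs are drawn near zero and decoy PEPs stochastically larger, so
#' that a 1% decoy FDR threshold is informative. Reporter-ion intensities
#' include a carrier channel scaled `carrier_scale` times the mean
#' single-cell signal and a reference channel at `reference_scale` times,
#' mirroring the isobaric carrier design.
#'
#' @param n_psms Number of rows.
#' @param n_proteins Number of distinct leading proteins.
#' @param n_runs Number of runs (run ids `run1..runN`, assigned uniformly).
#' @param decoy_fraction Fraction of decoy rows.
#' @param contaminant_fraction Fraction of contaminant rows (targets only).
#' @param n_cell_channels Number of single-cell reporter channels.
#' @param carrier_scale,reference_scale Carrier/reference intensity scale
#'   relative to the mean single-cell channel (defaults 200 and 5).
#' @param multi_charge_fraction Fraction of sequences also emitted at a
#'   second charge state (for charge-state condensation).
#' @param gradient_min Retention-time span.
#' @param seed Integer seed (mandatory).
#' @return A PSM tibble with columns `sequence`, `modified_sequence`,
#'   `charge`, `mz`, `rt`, `pep`, `pif`, `precursor_intensity`,
#'   `leading_protein`, `decoy`, `contaminant`, `run_id`, and reporter
#'   columns `carrier`, `reference`, `cell01..`.
#' @export
make_psm_table <- function(n_psms = 2000, n_proteins = 100, n_runs = 6,
                           decoy_fraction = 0.3,
                           contaminant_fraction = 0.02,
                           n_cell_channels = 8, carrier_scale = 200,
                           reference_scale = 5,
                           multi_charge_fraction = 0.2,
                           gradient_min = 60, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  n_decoy <- round(n_psms * decoy_fraction)
  n_target <- n_psms - n_decoy
  n_base <- ceiling(n_target / (1 + multi_charge_fraction))
  seqs <- random_sequences(n_base)
  extra <- sample(seqs, n_target - n_base, replace = FALSE)
  sequence <- c(seqs, extra)
  charge <- c(sample(2:3, n_base, replace = TRUE),
              rep(4L, n_target - n_base))
  decoy <- c(rep(FALSE, n_target), rep(TRUE, n_decoy))
  sequence <- c(sequence, random_sequences(n_decoy))
  charge <- c(charge, sample(2:3, n_decoy, replace = TRUE))
  pep <- c(stats::rbeta(n_target, 0.3, 12),
           stats::rbeta(n_decoy, 4, 1.5))
  n <- n_psms
  cell_base <- stats::rlnorm(n, log(50), 0.8)
  cells <- matrix(cell_base * stats::rlnorm(n * n_cell_channels, 0, 0.4),
                  nrow = n, ncol = n_cell_channels,
                  dimnames = list(NULL, sprintf("cell%02d",
                                                seq_len(n_cell_channels))))
  out <- tibble::tibble(
    sequence = sequence,
    modified_sequence = paste0("_", sequence, "_"),
    charge = charge,
    mz = stats::runif(n, 400, 1200),
    rt = stats::runif(n, 0, gradient_min),
    pep = pmin(pep, 1),
    pif = stats::rbeta(n, 8, 2),
    precursor_intensity = stats::rlnorm(n, log(1e5), 1.2),
    leading_protein = sample(sprintf("prot%04d", seq_len(n_proteins)),
                             n, replace = TRUE),
    decoy = decoy,
    contaminant = !decoy &
      stats::runif(n) < contaminant_fraction / (1 - decoy_fraction),
    run_id = sample(sprintf("run%d", seq_len(n_runs)), n, replace = TRUE),
    carrier = rowMeans(cells) * carrier_scale *
      stats::rlnorm(n, 0, 0.05),
    reference = rowMeans(cells) * reference_scale *
      stats::rlnorm(n, 0, 0.05)
  )
  dplyr::bind_cols(out, tibble::as_tibble(cells))
}

#' Generate a single-cell quantification matrix with planted structure
#'
#' Proteins are grouped into modules sharing a latent per-cell factor, so
#' within-module protein profiles correlate at the requested level across
#' cells. Selected proteins carry a planted log2 condition shift. Each
#' protein contributes several peptides whose relative abundances agree up
#' to multiplicative log-normal noise, giving real cells low per-protein
#' CVs; control columns are pure peptide-level noise with no shared protein
#' signal, so they fail the CV filter. Missing values are masked completely
#' at random.
#'
#' @param n_cells Cells per condition (two conditions, `A` and `B`).
#' @param n_controls Negative-control columns.
#' @param n_modules Number of protein modules.
#' @param module_size Proteins per module.
#' @param module_cor Target within-module correlation of protein profiles.
#' @param peptides_per_protein Peptides per protein.
#' @param effect_log2 Planted log2 shift (condition B vs A).
#' @param n_effect_proteins Number of proteins carrying the shift (0 for a
#'   null matrix).
#' @param peptide_noise_sd Log2-scale s.d. of peptide-level noise in cells.
#' @param control_noise_sd Log2-scale s.d. of control-column noise.
#' @param missing_fraction Fraction of entries masked to `NA`.
#' @param seed Integer seed (mandatory).
#' @return A list with `qm` (a [quant_matrix()]) and `truth` (tibble of
#'   protein, module, effect_log2).
#' @export
make_singlecell_matrix <- function(n_cells = 60, n_controls = 8,
                                   n_modules = 4, module_size = 10,
                                   module_cor = 0.6,
                                   peptides_per_protein = 4,
                                   effect_log2 = 1,
                                   n_effect_proteins = 0,
                                   peptide_noise_sd = 0.25,
                                   control_noise_sd = 1.5,
                                   missing_fraction = 0.2, seed) {
  stopifnot(!missing(seed), module_cor >= -1, module_cor <= 1)
  set.seed(seed)
  n_prot <- n_modules * module_size
  proteins <- sprintf("prot%03d", seq_len(n_prot))
  module <- rep(seq_len(n_modules), each = module_size)
  n_tot_cells <- 2 * n_cells
  condition <- rep(c("A", "B"), each = n_cells)
  # latent module factors per cell; protein level mixes shared + private
  fac <- matrix(stats::rnorm(n_modules * n_tot_cells), n_modules)
  priv <- matrix(stats::rnorm(n_prot * n_tot_cells), n_prot)
  prot_level <- sqrt(module_cor) * fac[module, , drop = FALSE] +
    sqrt(1 - module_cor) * priv
  eff_prot <- proteins[seq_len(min(n_effect_proteins, n_prot))]
  shift <- matrix(0, n_prot, n_tot_cells)
  shift[proteins %in% eff_prot, condition == "B"] <- effect_log2
  prot_level <- prot_level + shift
  feats <- tibble::tibble(
    feature = sprintf("%s_pep%d", rep(proteins, each = peptides_per_protein),
                      rep(seq_len(peptides_per_protein), n_prot)),
    protein = rep(proteins, each = peptides_per_protein),
    # first half of the modules plays the high-priority tier
    tier = ifelse(rep(module, each = peptides_per_protein) <=
                    ceiling(n_modules / 2), "high", "low")
  )
  n_feat <- nrow(feats)
  cell_vals <- 2^(prot_level[rep(seq_len(n_prot),
                                 each = peptides_per_protein), ] +
                    matrix(stats::rnorm(n_feat * n_tot_cells, 0,
                                        peptide_noise_sd), n_feat))
  ctrl_vals <- 2^matrix(stats::rnorm(n_feat * n_controls, 0,
                                     control_noise_sd), n_feat)
  values <- cbind(cell_vals, ctrl_vals)
  cell_names <- c(sprintf("cell%03d", seq_len(n_tot_cells)),
                  sprintf("ctrl%02d", seq_len(n_controls)))
  dimnames(values) <- list(feats$feature, cell_names)
  mask <- matrix(stats::runif(length(values)) < missing_fraction,
                 nrow(values))
  values[mask] <- NA_real_
  cells <- tibble::tibble(
    cell = cell_names,
    condition = c(condition, rep("control", n_controls)),
    control = c(rep(FALSE, n_tot_cells), rep(TRUE, n_controls)),
    run_id = sprintf("run%d", 1 + (seq_along(cell_names) - 1) %% 4)
  )
  truth <- tibble::tibble(protein = proteins, module = module,
                          effect_log2 = ifelse(proteins %in% eff_prot,
                                               effect_log2, 0))
  list(qm = quant_matrix(values, cells, feats), truth = truth)
}

#' Generate a replicate-injection pair with intensity-dependent noise
#'
#' Emulates two injections of the same sample: precursor intensities are
#' log-normal, and the second replicate differs by multiplicative log-normal
#' noise whose log2 s.d. decreases linearly with the intensity percentile
#' (high-abundance precursors are measured more precisely), the structure
#' the intensity-binned null model is designed to absorb.
#'
#' @param n_precursors Number of shared precursors.
#' @param meanlog,sdlog Log-normal parameters of the base intensities.
#' @param noise_sd_low,noise_sd_high Log2 noise s.d. at the lowest/highest
#'   intensity percentile.
#' @param seed Integer seed (mandatory).
#' @return A list with named vectors `a`, `b`, and the true per-precursor
#'   `noise_sd`.
#' @export
make_replicate_pair <- function(n_precursors = 1500, meanlog = log(1e5),
                                sdlog = 1.2, noise_sd_low = 0.6,
                                noise_sd_high = 0.15, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  base <- stats::rlnorm(n_precursors, meanlog, sdlog)
  prank <- (rank(base) - 0.5) / n_precursors
  sdv <- noise_sd_low + (noise_sd_high - noise_sd_low) * prank
  ids <- sprintf("prec%05d", seq_len(n_precursors))
  a <- base * 2^stats::rnorm(n_precursors, 0, sdv / sqrt(2))
  b <- base * 2^stats::rnorm(n_precursors, 0, sdv / sqrt(2))
  list(a = stats::setNames(a, ids), b = stats::setNames(b, ids),
       noise_sd = stats::setNames(sdv, ids))
}

#' Generate spike-in PSMs under a known design
#'
#' Reporter intensities proportional to the spike-in level with optional
#' multiplicative log-normal noise; used to validate the spike-in
#' regression's recovery of a unit slope.
#'
#' @param design A [spikein_design()].
#' @param n_runs Number of experiments.
#' @param sequences Spike-in peptide sequences.
#' @param noise_sd Log2-scale multiplicative noise s.d. (0 = noise free).
#' @param base_intensity Base reporter intensity at the 1x level.
#' @param seed Integer seed (mandatory).
#' @return A PSM tibble compatible with [spikein_regression()].
#' @export
make_spikein_psms <- function(design, n_runs = 8,
                              sequences = c("AYFTAPSSER", "VEVDSFSGAK",
                                            "TSIIGTIGPK", "ELYEVDVLK"),
                              noise_sd = 0, base_intensity = 1000, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  grid <- tidyr::expand_grid(run_id = sprintf("run%d", seq_len(n_runs)),
                             sequence = sequences,
                             charge = 2:3)
  reps <- matrix(rep(design$level, nrow(grid)), nrow(grid), byrow = TRUE,
                 dimnames = list(NULL, design$sample))
  eff <- stats::rlnorm(nrow(grid), log(base_intensity), 0.3)
  vals <- reps * eff
  if (noise_sd > 0) {
    vals <- vals * 2^matrix(stats::rnorm(length(vals), 0, noise_sd),
                            nrow(vals))
  }
  dplyr::bind_cols(grid, tibble::as_tibble(vals))
}
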