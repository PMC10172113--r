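#' Single-cell reporter-ion quantification container
#'
#' Couples a features-by-cells matrix of relative reporter-ion abundances
#' (with `NA` for missing values) to its cell and feature metadata. Values
#' are on the raw (pre-log) relative scale, so they must be non-negative.
#'
#' @param values Numeric matrix, features in rows, cells in columns; row and
#'   column names required.
#' @param cells Tibble of cell metadata with columns `cell` (matching the
#'   matrix columns), `condition`, `control` (logical: negative-control
#'   channel), and optionally `run_id`.
#' @param features Tibble of feature metadata with columns `feature`
#'   (matching the matrix rows), `protein`, and optionally `tier`.
#' @return A list of class `quant_matrix`.
#' @export
quant_matrix <- function(values, cells, features) {
  stopifnot(is.matrix(values),
            !is.null(rownames(values)), !is.null(colnames(values)),
            setequal(colnames(values), cells$cell),
            setequal(rownames(values), features$feature))
  if (any(values < 0, na.rm = TRUE)) {
    stop("pre-log relative abundances must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(features$feature)) {
    stop("feature ids must be unique", call. = FALSE)
  }
  cells <- cells[match(colnames(values), cells$cell), , drop = FALSE]
  features <- features[match(rownames(values), features$feature), ,
                       drop = FALSE]
  structure(list(values = values, cells = tibble::as_tibble(cells),
                 features = tibble::as_tibble(features)),
            class = "quant_matrix")
}

subset_quant <- function(qm, keep_features = NULL, keep_cells = NULL) {
  v <- qm$values
  if (!is.null(keep_features)) v <- v[keep_features, , drop = FALSE]
  if (!is.null(keep_cells)) v <- v[, keep_cells, drop = FALSE]
  quant_matrix(v,
               qm$cells[qm$cells$cell %in% colnames(v), , drop = FALSE],
               qm$features[qm$features$feature %in% rownames(v), ,
                           drop = FALSE])
}

# per-cell aggregate protein CV (sd/mean over >=2 observed peptides/protein)
cell_protein_cvs <- function(qm, aggregator) {
  agg_fun <- if (aggregator == "mean") mean else stats::median
  proteins <- split(qm$features$feature, qm$features$protein)
  vapply(colnames(qm$values), function(cl) {
    col <- qm$values[, cl]
    cvs <- vapply(proteins, function(feats) {
      x <- col[feats]
      x <- x[!is.na(x)]
      if (length(x) < 2) return(NA_real_)
      stats::sd(x) / mean(x)
    }, numeric(1))
    cvs <- cvs[!is.na(cvs)]
    if (length(cvs) == 0) NA_real_ else agg_fun(cvs)
  }, numeric(1))
}

#' Quality-control filter on per-cell protein CVs
#'
#' For every cell and every protein with at least two observed peptides, the
#' coefficient of variation (standard deviation scaled by the mean) of the
#' protein's peptide relative abundances is computed; the cell's aggregate
#' (mean by default, median optionally) over protein CVs summarizes its
#' quantification reliability. Cells whose aggregate CV exceeds the
#' threshold, or for which no protein has two observed peptides, are removed.
#' Control channels are reported alongside the cells but never enter the
#' filtered matrix.
#'
#' @param qm A [quant_matrix()] of pre-log relative abundances.
#' @param cv_threshold Maximum aggregate CV; the conventional cut is 0.4.
#' @param aggregator `"mean"` (default) or `"median"` over protein CVs.
#' @return A list with `report` (tibble: `cell`, `control`, `n_proteins`,
#'   `cv`, `pass`, `reason`) and `filtered` (the matrix restricted to
#'   non-control cells that pass).
#' @export
qc_cells <- function(qm, cv_threshold = 0.4,
                     aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  cv <- cell_protein_cvs(qm, aggregator)
  n_prot <- vapply(colnames(qm$values), function(cl) {
    obs <- !is.na(qm$values[, cl])
    dplyr::n_distinct(qm$features$protein[obs])
  }, integer(1))
  is_control <- qm$cells$control[match(names(cv), qm$cells$cell)]
  pass <- !is.na(cv) & cv <= cv_threshold
  report <- tibble::tibble(
    cell = names(cv), control = is_control, n_proteins = n_prot,
    cv = unname(cv), pass = unname(pass),
    reason = dplyr::case_when(
      is.na(cv) ~ "no_multi_peptide_protein",
      cv > cv_threshold ~ "cv_above_threshold",
      TRUE ~ "pass")
  )
  keep <- report$cell[report$pass & !report$control]
  list(report = report, filtered = subset_quant(qm, keep_cells = keep))
}

#' Normalize precursors and aggregate to protein level
#'
#' Runs the normalization chain in a fixed order: (1) optional division of
#' each precursor by a reference-channel column; (2) each cell column divided
#' by its median over observed entries; (3) each precursor row divided by its
#' mean over observed entries; (4) log2 transform; (5) protein abundance per
#' cell as the median over that protein's observed peptide values.
#' Missingness propagates throughout — no imputation. The `impute` and
#' `batch_correct` arguments are pass-through hooks (identity by default)
#' applied to the protein-level matrix for pipelines that supply their own.
#'
#' @param qm A [quant_matrix()].
#' @param reference Optional column (cell) name of a reference channel; when
#'   given, step (1) divides every column by it and drops it from the output.
#' @param impute,batch_correct Functions `matrix -> matrix` applied, in that
#'   order, to the protein-level log2 matrix; defaults are identity.
#' @return A list with `protein_log2` (proteins x cells), `precursor_norm`
#'   (normalized precursor matrix, pre-log), `precursor_log2`, and
#'   `dropped_cells` (columns with no observed entries, removed with
#'   reason).
#' @export
normalize_and_aggregate <- function(qm, reference = NULL,
                                    impute = identity,
                                    batch_correct = identity) {
  v <- qm$values
  if (!is.null(reference)) {
    stopifnot(reference %in% colnames(v))
    ref <- v[, reference]
    v <- v[, setdiff(colnames(v), reference), drop = FALSE] / ref
  }
  dropped <- colnames(v)[colSums(!is.na(v)) == 0]
  v <- v[, setdiff(colnames(v), dropped), drop = FALSE]
  col_med <- apply(v, 2, stats::median, na.rm = TRUE)
  v <- sweep(v, 2, col_med, "/")
  row_mean <- rowMeans(v, na.rm = TRUE)
  v <- sweep(v, 1, row_mean, "/")
  lv <- log2(v)
  prot_of <- qm$features$protein[match(rownames(lv), qm$features$feature)]
  groups <- split(seq_len(nrow(lv)), prot_of)
  prot <- do.call(rbind, lapply(groups, function(idx) {
    apply(lv[idx, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  }))
  prot[!is.finite(prot)] <- NA_real_
  prot <- batch_correct(impute(prot))
  list(protein_log2 = prot, precursor_norm = v, precursor_log2 = lv,
       dropped_cells = dropped)
}

#' Filter cells and features by missingness
#'
#' Drops cells, then features, whose fraction of missing values is at or
#' above `max_missing_fraction` (the conventional filter keeps entries with
#' less than 99% missing data). The order — cells first, then features — is
#' fixed so results are reproducible.
#'
#' @param qm A [quant_matrix()].
#' @param max_missing_fraction Strict upper bound on the missing fraction.
#' @return The filtered [quant_matrix()].
#' @export
missingness_filter <- function(qm, max_missing_fraction = 0.99) {
  v <- qm$values
  cell_miss <- colMeans(is.na(v))
  keep_cells <- colnames(v)[cell_miss < max_missing_fraction]
  v <- v[, keep_cells, drop = FALSE]
  feat_miss <- rowMeans(is.na(v))
  keep_feats <- rownames(v)[feat_miss < max_missing_fraction]
  subset_quant(qm, keep_features = keep_feats, keep_cells = keep_cells)
}

#' Data completeness per cell and priority tier
#'
#' Computes, for each cell and each feature tier, the percentage of that
#' tier's features with observed (non-missing) values — the per-cell data
#' completeness. When the cell metadata carries `run_id`, per-feature
#' across-run identification rates are also reported: the number of runs in
#' which the feature is observed in at least one cell, divided by the total
#' number of runs, times 100.
#'
#' @param qm A [quant_matrix()] whose feature metadata has a `tier` column.
#' @return A list with `per_cell` (tibble: `cell`, `tier`, `n_observed`,
#'   `n_total`, `completeness_pct`) and `per_feature` (tibble: `feature`,
#'   `tier`, `n_runs_identified`, `n_runs`, `id_rate_pct`; `NULL` without
#'   `run_id`).
#' @export
completeness <- function(qm) {
  stopifnot("tier" %in% names(qm$features))
  obs <- !is.na(qm$values)
  tiers <- split(qm$features$feature, qm$features$tier)
  per_cell <- purrr::map_dfr(names(tiers), function(tn) {
    feats <- tiers[[tn]]
    tibble::tibble(
      cell = colnames(obs), tier = tn,
      n_observed = unname(colSums(obs[feats, , drop = FALSE])),
      n_total = length(feats)
    )
  }) |>
    dplyr::mutate(completeness_pct = 100 * .data$n_observed / .data$n_total)
  per_feature <- NULL
  if ("run_id" %in% names(qm$cells)) {
    runs <- split(qm$cells$cell, qm$cells$run_id)
    ident <- vapply(runs, function(cls) {
      rowSums(obs[, cls, drop = FALSE]) > 0
    }, logical(nrow(obs)))
    per_feature <- tibble::tibble(
      feature = rownames(obs),
      tier = qm$features$tier[match(rownames(obs), qm$features$feature)],
      n_runs_identified = unname(rowSums(ident)),
      n_runs = length(runs),
      id_rate_pct = unname(100 * rowSums(ident) / length(runs))
    )
  }
  list(per_cell = per_cell, per_feature = per_feature)
}

#' Per-bin identification counts across intensity bins
#'
#' Splits each run's log10 precursor-intensity range into `n_bins`
#' equal-width bins, counts identifications per bin, and summarizes counts
#' per platform (e.g. shotgun vs prioritized) by the cross-run median and
#' standard deviation per bin index.
#'
#' @param psms Tibble with columns `run_id`, `platform`,
#'   `precursor_intensity` (> 0).
#' @param n_bins Number of intensity bins per run (default 30).
#' @return Tibble (`platform`, `bin`, `median_n`, `sd_n`, `n_runs`); for a
#'   platform with a single run the s.d. is reported as 0 and the
#'   `single_run_platforms` attribute names it.
#' @export
intensity_distribution <- function(psms, n_bins = 30) {
  stopifnot(all(psms$precursor_intensity > 0))
  per_run <- psms |>
    dplyr::group_by(.data$platform, .data$run_id) |>
    dplyr::group_modify(function(d, key) {
      lx <- log10(d$precursor_intensity)
      rng <- range(lx)
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      bin_of <- pmin(pmax(ceiling((lx - rng[1]) / diff(rng) * n_bins), 1L),
                     n_bins)
      counts <- tabulate(bin_of, nbins = n_bins)
      tibble::tibble(bin = seq_len(n_bins), n = counts)
    }) |>
    dplyr::ungroup()
  singles <- per_run |>
    dplyr::distinct(.data$platform, .data$run_id) |>
    dplyr::count(.data$platform) |>
    dplyr::filter(.data$n == 1) |>
    dplyr::pull(.data$platform)
  out <- per_run |>
    dplyr::group_by(.data$platform, .data$bin) |>
    dplyr::summarise(
      median_n = stats::median(.data$n),
      sd_n = if (dplyr::n() > 1) stats::sd(.data$n) else 0,
      n_runs = dplyr::n(), .groups = "drop")
  attr(out, "single_run_platforms") <- singles
  out
}
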