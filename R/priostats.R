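#' Fit an intensity-binned null fold-change model from replicate injections
#'
#' Two injections of the same sample should give precursor fold changes
#' clustered around 1:1; deviations reflect measurement noise. Because
#' quantitation is more accurate at higher intensity, the log2 fold changes
#' of the shared precursors are split into equal-count bins with respect to
#' the average precursor intensity of the pair, and each bin stores the mean
#' and standard deviation of its fold changes.
#'
#' @param replicate_a,replicate_b Named numeric intensity vectors (names are
#'   precursor ids); only shared precursors are used.
#' @param n_bins Number of equal-count intensity bins (default 15).
#' @param zero_sd_action `"error"` (default) refuses bins with zero
#'   fold-change dispersion, which arise from identical or exactly
#'   proportional replicates and would make downstream z scores degenerate;
#'   `"allow"` keeps them (useful only for inspecting bin means).
#' @return An object of class `null_fc_model`: a list with `bins` (tibble:
#'   `bin`, `n`, `intensity_min`, `intensity_max`, `mean_lfc`, `sd_lfc`) and
#'   `breaks` used for later bin lookup.
#' @export
fit_null_model <- function(replicate_a, replicate_b, n_bins = 15,
                           zero_sd_action = c("error", "allow")) {
  zero_sd_action <- match.arg(zero_sd_action)
  shared <- intersect(names(replicate_a), names(replicate_b))
  if (length(shared) < n_bins) {
    stop("need at least one shared precursor per bin (",
         length(shared), " shared, ", n_bins, " bins)", call. = FALSE)
  }
  a <- replicate_a[shared]
  b <- replicate_b[shared]
  lfc <- log2(a / b)
  avg <- (a + b) / 2
  bin <- equal_count_bins(avg, n_bins)
  bins <- tibble::tibble(avg = avg, lfc = lfc, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     intensity_min = min(.data$avg),
                     intensity_max = max(.data$avg),
                     mean_lfc = mean(.data$lfc),
                     sd_lfc = stats::sd(.data$lfc), .groups = "drop")
  zero_sd <- bins$sd_lfc == 0 | is.na(bins$sd_lfc)
  if (any(zero_sd) && zero_sd_action == "error") {
    stop("a null bin has zero fold-change dispersion; replicate injections ",
         "appear identical or exactly proportional - add measurement noise, ",
         "an epsilon, or more precursors", call. = FALSE)
  }
  # breaks at midpoints between adjacent bins' intensity ranges
  breaks <- c(-Inf,
              (bins$intensity_max[-n_bins] + bins$intensity_min[-1]) / 2,
              Inf)
  structure(list(bins = bins, breaks = breaks, n_bins = n_bins),
            class = "null_fc_model")
}

# equal-count bin assignment by rank; bin sizes differ by at most one,
# larger bins at the low-intensity end
equal_count_bins <- function(x, n_bins) {
  n <- length(x)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  out <- integer(n)
  out[order(x)] <- rep.int(seq_len(n_bins), sizes)
  out
}

# bin index of new intensities under a fitted model
lookup_bin <- function(model, avg_intensity) {
  findInterval(avg_intensity, model$breaks, rightmost.closed = TRUE)
}

#' Z-score condition fold changes through a null model
#'
#' Converts per-precursor log2 fold changes between two conditions into z
#' scores using the mean and s.d. of the intensity bin each precursor falls
#' into (bins looked up by the average intensity of the pair).
#'
#' @param null A [fit_null_model()] object.
#' @param cond1,cond2 Named numeric precursor intensity vectors; only shared
#'   precursors are scored.
#' @return Tibble (`precursor`, `lfc`, `avg_intensity`, `bin`, `z`).
#' @export
null_zscores <- function(null, cond1, cond2) {
  shared <- intersect(names(cond1), names(cond2))
  if (length(shared) == 0) stop("no shared precursors", call. = FALSE)
  lfc <- log2(cond1[shared] / cond2[shared])
  avg <- (cond1[shared] + cond2[shared]) / 2
  bin <- lookup_bin(null, avg)
  tibble::tibble(
    precursor = shared, lfc = unname(lfc), avg_intensity = unname(avg),
    bin = bin,
    z = unname((lfc - null$bins$mean_lfc[bin]) / null$bins$sd_lfc[bin]))
}

#' Differential protein abundance against an intensity-binned null
#'
#' Per shared precursor, the condition log2 fold change is converted to a z
#' score using the mean and s.d. of its intensity bin in the null model.
#' Each protein's precursor z scores are then t-tested (Welch) against a
#' seeded draw of `null_sample_n` standard-normal values, and p values are
#' adjusted with Benjamini-Hochberg across proteins.
#'
#' @param cond1,cond2 Named numeric precursor intensity vectors for the two
#'   conditions.
#' @param null A [fit_null_model()] object.
#' @param protein_map Tibble mapping `precursor` to `protein`.
#' @param null_sample_n Size of the standard-normal null sample (default
#'   10000).
#' @param seed Integer seed for the null draw.
#' @return Tibble (`protein`, `n_precursors`, `log2_fc` — median precursor
#'   log2 fold change, `mean_z`, `p`, `q`, `single_precursor` flag),
#'   BH-adjusted.
#' @export
differential_proteins <- function(cond1, cond2, null, protein_map,
                                  null_sample_n = 10000, seed = 1L) {
  prec <- null_zscores(null, cond1, cond2) |>
    dplyr::inner_join(protein_map, by = "precursor")
  set.seed(seed)
  null_draw <- stats::rnorm(null_sample_n)
  # Welch test of the protein's z's against the null sample; a protein with
  # a single precursor has no within-group variance, so its z is scored by
  # its empirical two-sided tail probability in the same null draw
  test_p <- function(z) {
    if (length(z) >= 2) {
      stats::t.test(z, null_draw)$p.value
    } else {
      max(mean(abs(null_draw) >= abs(z)), 1 / length(null_draw))
    }
  }
  out <- prec |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      n_precursors = dplyr::n(),
      log2_fc = stats::median(.data$lfc),
      mean_z = mean(.data$z),
      p = test_p(.data$z),
      .groups = "drop") |>
    dplyr::mutate(q = stats::p.adjust(.data$p, method = "BH"),
                  single_precursor = .data$n_precursors == 1)
  out
}

#' Select marker proteins from a differential result
#'
#' Applies the conventional marker gate: significant at the q-value cutoff
#' and an absolute log2 fold change at or above the effect-size floor.
#'
#' @param diff Result of [differential_proteins()].
#' @param q_max Maximum q value (default 0.01).
#' @param min_abs_lfc Minimum `|log2 fold change|` (default 1).
#' @return The qualifying rows.
#' @export
marker_proteins <- function(diff, q_max = 0.01, min_abs_lfc = 1) {
  dplyr::filter(diff, .data$q <= q_max, abs(.data$log2_fc) >= min_abs_lfc)
}

#' Protein-set enrichment on principal-component loadings
#'
#' For each protein set, the loadings (PC weights) of member proteins are
#' compared against the background of all non-member loadings with a
#' two-tailed Wilcoxon rank-sum test. A set is tested only when at least
#' `min_n` of its proteins are present in the loading vector, at least
#' `min_fraction` of its members are present, and the set has fewer than
#' `max_size` entries in total. Per-set median loadings are standardized to
#' z scores across the tested sets for interpretability, p values are
#' BH-adjusted, and the result is filtered at the requested FDR.
#'
#' @param loadings Named numeric vector: protein -> PC weight.
#' @param sets Named list of character vectors (set -> member protein ids),
#'   e.g. from [read_gmt()].
#' @param min_n Minimum number of member proteins present (default 5).
#' @param min_fraction Minimum fraction of members present (default 0.10).
#' @param max_size Sets with this many entries or more are excluded
#'   (default 200, i.e. tested sets have < 200 members).
#' @param fdr FDR cutoff for the returned rows (default 0.05); `NULL`
#'   returns every tested set.
#' @return Tibble (`set`, `n_present`, `n_set`, `median_loading`, `z`, `p`,
#'   `q`) of class `psea_result`, with all tested sets in the
#'   `tested` attribute.
#' @export
psea <- function(loadings, sets, min_n = 5, min_fraction = 0.10,
                 max_size = 200, fdr = 0.05) {
  stopifnot(all(is.finite(loadings)), !is.null(names(loadings)))
  eligible <- purrr::keep(sets, function(members) {
    present <- sum(members %in% names(loadings))
    length(members) < max_size &&
      present >= min_n &&
      present / length(members) >= min_fraction
  })
  if (length(eligible) == 0) {
    out <- tibble::tibble(set = character(0), n_present = integer(0),
                          n_set = integer(0), median_loading = numeric(0),
                          z = numeric(0), p = numeric(0), q = numeric(0))
    attr(out, "reason") <- "no sets passed the size filters"
    class(out) <- c("psea_result", class(out))
    return(out)
  }
  rows <- purrr::imap_dfr(eligible, function(members, nm) {
    inset <- names(loadings) %in% members
    tibble::tibble(
      set = nm,
      n_present = sum(inset),
      n_set = length(members),
      median_loading = stats::median(loadings[inset]),
      p = stats::wilcox.test(loadings[inset], loadings[!inset],
                             alternative = "two.sided")$p.value)
  })
  med <- rows$median_loading
  rows$z <- if (nrow(rows) > 1) as.numeric(scale(med)) else 0
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows <- rows[, c("set", "n_present", "n_set", "median_loading",
                   "z", "p", "q")]
  out <- if (is.null(fdr)) rows else rows[rows$q <= fdr, , drop = FALSE]
  attr(out, "tested") <- rows
  class(out) <- c("psea_result", class(out))
  out
}

#' Permutation test of marker-panel association
#'
#' For each target feature, computes the observed statistic: the median
#' Pearson correlation between the target and panel A members minus the
#' median correlation between the target and panel B members, across cells.
#' The null is built by permuting the protein-column labels of the matrix
#' `n_perm` times and recomputing the statistic; the p value is the fraction
#' of permutations with `|null| >= |observed|`. P values are BH-adjusted
#' across targets; when a target's p is exactly zero (no permutation as
#' extreme), its q value is set to the floor 1e-5.
#'
#' @param mat Cells-by-proteins numeric matrix (column names are protein or
#'   target ids); pairwise-complete Pearson correlations are used.
#' @param targets Character vector of target column names (not in a panel).
#' @param panel_a,panel_b Disjoint character vectors of panel column names.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param scheme `"proteins"` permutes protein-column labels (default);
#'   `"cells"` permutes cell rows, the more common null.
#' @return Tibble (`target`, `n_a`, `n_b`, `observed`, `p`, `q`) of class
#'   `perm_test_result`; targets whose panels have fewer than two quantified
#'   members are skipped with a `skipped` attribute.
#' @export
marker_permutation_test <- function(mat, targets, panel_a, panel_b,
                                    n_perm = 10000, seed = 1L,
                                    scheme = c("proteins", "cells")) {
  scheme <- match.arg(scheme)
  stopifnot(nrow(mat) >= 3, length(intersect(panel_a, panel_b)) == 0,
            !any(targets %in% c(panel_a, panel_b)))
  cols <- colnames(mat)
  panel_a <- intersect(panel_a, cols)
  panel_b <- intersect(panel_b, cols)
  skipped <- character(0)
  if (length(panel_a) < 2 || length(panel_b) < 2) {
    skipped <- targets
    targets <- character(0)
  }
  cmat <- stats::cor(mat, use = "pairwise.complete.obs")
  stat_for <- function(C, tgt, a, b) {
    stats::median(C[tgt, a], na.rm = TRUE) -
      stats::median(C[tgt, b], na.rm = TRUE)
  }
  set.seed(seed)
  rows <- purrr::map_dfr(targets, function(tgt) {
    if (!tgt %in% cols) {
      return(tibble::tibble(target = tgt, n_a = NA_integer_,
                            n_b = NA_integer_, observed = NA_real_,
                            p = NA_real_))
    }
    obs <- stat_for(cmat, tgt, panel_a, panel_b)
    null <- vapply(seq_len(n_perm), function(i) {
      if (scheme == "proteins") {
        perm <- sample(cols)
        names(perm) <- cols
        stat_for(cmat, perm[[tgt]], unname(perm[panel_a]),
                 unname(perm[panel_b]))
      } else {
        m2 <- mat
        m2[, tgt] <- mat[sample(nrow(mat)), tgt]
        stat_for(stats::cor(m2, use = "pairwise.complete.obs"),
                 tgt, panel_a, panel_b)
      }
    }, numeric(1))
    tibble::tibble(target = tgt, n_a = length(panel_a),
                   n_b = length(panel_b), observed = obs,
                   p = mean(abs(null) >= abs(obs)))
  })
  if (nrow(rows)) {
    rows$q <- stats::p.adjust(rows$p, method = "BH")
    rows$q[rows$p == 0] <- 1e-5
  } else {
    rows <- tibble::tibble(target = character(0), n_a = integer(0),
                           n_b = integer(0), observed = numeric(0),
                           p = numeric(0), q = numeric(0))
  }
  attr(rows, "skipped") <- skipped
  class(rows) <- c("perm_test_result", class(rows))
  rows
}

#' Spike-in design
#'
#' Describes which samples (channels) received which spike-in concentration.
#' The canonical design spans a 16-fold dynamic range across five levels
#' (1x, 2x, 4x, 8x, 16x); 1x samples are required because they anchor the
#' normalization.
#'
#' @param samples Character vector of sample/channel names.
#' @param levels Numeric vector of relative spike-in levels, one per sample.
#' @return Tibble (`sample`, `level`) of class `spikein_design`.
#' @export
#' @examples
#' spikein_design(paste0("s", 1:14),
#'                rep(c(1, 2, 4, 8, 16), c(2, 3, 3, 3, 3)))
spikein_design <- function(samples, levels) {
  stopifnot(length(samples) == length(levels), all(levels > 0))
  if (!any(levels == 1)) {
    stop("the design must contain 1x samples (normalization anchors)",
         call. = FALSE)
  }
  structure(tibble::tibble(sample = samples, level = levels),
            class = c("spikein_design", class(tibble::tibble())))
}

#' Regression of normalized reporter intensities on spike-in levels
#'
#' Per experiment and precursor, reporter-ion intensities are divided by the
#' median intensity of that experiment's 1x samples; charge states of the
#' same sequence are collapsed by the median per sample. The pooled log2
#' normalized intensities are then regressed on log2 relative spike-in
#' level through the origin (for a single predictor with no intercept this
#' least-squares fit coincides with the one-component partial-least-squares
#' projection). Experiments with no observed 1x anchor for a precursor are
#' excluded with a reason.
#'
#' @param psms Tibble with columns `run_id`, `sequence`, `charge`, and one
#'   reporter column per design sample (named as in `design$sample`).
#' @param design A [spikein_design()].
#' @return A list of class `spikein_fit`: `slope`, `r_squared`, `fit` (the
#'   `lm` object), `points` (tibble of `log2_level`, `log2_intensity`),
#'   `per_level` (median and s.d. of normalized intensity per level), and
#'   `excluded` (run/precursor combinations without 1x anchors).
#' @export
spikein_regression <- function(psms, design) {
  anchors <- design$sample[design$level == 1]
  long <- psms |>
    tidyr::pivot_longer(dplyr::all_of(design$sample), names_to = "sample",
                        values_to = "intensity") |>
    dplyr::left_join(design, by = "sample")
  normed <- long |>
    dplyr::group_by(.data$run_id, .data$sequence, .data$charge) |>
    dplyr::mutate(anchor = stats::median(
      .data$intensity[.data$sample %in% anchors], na.rm = TRUE)) |>
    dplyr::ungroup()
  excluded <- normed |>
    dplyr::filter(!is.finite(.data$anchor) | .data$anchor <= 0) |>
    dplyr::distinct(.data$run_id, .data$sequence, .data$charge) |>
    dplyr::mutate(reason = "no 1x anchor")
  pts <- normed |>
    dplyr::filter(is.finite(.data$anchor), .data$anchor > 0) |>
    dplyr::mutate(rel = .data$intensity / .data$anchor) |>
    # collapse charge states: median per sequence and sample
    dplyr::group_by(.data$run_id, .data$sequence, .data$sample,
                    .data$level) |>
    dplyr::summarise(rel = stats::median(.data$rel, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::filter(is.finite(.data$rel), .data$rel > 0) |>
    dplyr::transmute(run_id = .data$run_id, sequence = .data$sequence,
                     level = .data$level,
                     log2_level = log2(.data$level),
                     log2_intensity = log2(.data$rel))
  if (nrow(pts) == 0) stop("no usable spike-in observations", call. = FALSE)
  fit <- stats::lm(log2_intensity ~ 0 + log2_level, data = pts)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum(pts$log2_intensity^2)  # through-origin total sum of squares
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  per_level <- pts |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(n = dplyr::n(),
                     median_log2 = stats::median(.data$log2_intensity),
                     sd_log2 = stats::sd(.data$log2_intensity),
                     .groups = "drop")
  structure(list(slope = unname(stats::coef(fit)[1]), r_squared = r2,
                 fit = fit, points = pts, per_level = per_level,
                 excluded = excluded),
            class = "spikein_fit")
}
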