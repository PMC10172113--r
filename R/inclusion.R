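#' Decoy-based FDR threshold on posterior error probabilities
#'
#' Finds the largest PEP cutoff such that, among entries with PEP at or below
#' the cutoff, the fraction of decoy (reverse) matches does not exceed the
#' target FDR. This mirrors the standard practice of filtering search results
#' by determining the PEP threshold at which the chosen percentage of entries
#' are reverse matches.
#'
#' @param peps Numeric vector of posterior error probabilities in `[0, 1]`.
#' @param decoys Logical vector, `TRUE` for decoy/reverse entries.
#' @param target_fdr Target decoy fraction, in `(0, 1)`; default 0.01.
#' @return A list with `cutoff` (the PEP threshold, `-Inf` when no candidate
#'   cutoff achieves the target) and `keep` (logical index of retained
#'   entries: non-decoys with `pep <= cutoff`).
#' @export
#' @examples
#' compute_fdr_threshold(c(.001, .002, .5, .9), c(FALSE, FALSE, TRUE, TRUE))
compute_fdr_threshold <- function(peps, decoys, target_fdr = 0.01) {
  stopifnot(length(peps) == length(decoys),
            target_fdr > 0, target_fdr < 1)
  if (length(peps) == 0) return(list(cutoff = -Inf, keep = logical(0)))
  ord <- order(peps)
  dec_cum <- cumsum(decoys[ord])
  frac <- dec_cum / seq_along(ord)
  # candidate cutoffs are the observed PEPs; a cutoff is admissible when the
  # decoy fraction at the *last* entry with that PEP meets the target
  pep_sorted <- peps[ord]
  last_of_value <- !duplicated(pep_sorted, fromLast = TRUE)
  ok <- frac <= target_fdr & last_of_value
  if (!any(ok)) {
    return(list(cutoff = -Inf, keep = rep(FALSE, length(peps))))
  }
  cutoff <- max(pep_sorted[ok])
  list(cutoff = cutoff, keep = !decoys & peps <= cutoff)
}

#' Filter a PSM table for single-cell quantification
#'
#' Applies, in order: the precursor-purity filter (drop rows with
#' `pif < pif_min`), the carrier-ratio filter (drop rows whose mean
#' single-cell reporter intensity exceeds `carrier_ratio_max` times the
#' carrier-channel intensity), the decoy-based FDR threshold
#' ([compute_fdr_threshold()]), and removal of decoy and contaminant rows.
#'
#' @param psms PSM tibble; see [make_psm_table()] for the expected layout.
#'   Reporter-ion columns are named in `channels`.
#' @param channels A list with elements `carrier` (one column name) and
#'   `cells` (column names of the single-cell channels).
#' @param pif_min Minimum precursor ion fraction; the conventional cut
#'   removes PIFs below 50%.
#' @param carrier_ratio_max Maximum allowed mean single-cell/carrier reporter
#'   ratio (e.g. 0.10 for a ~200-cell carrier; 0.02 for stricter designs).
#' @param fdr Target decoy FDR for the PEP threshold.
#' @return The filtered tibble, with the applied PEP cutoff in the
#'   `pep_cutoff` attribute.
#' @export
filter_psms <- function(psms, channels, pif_min = 0.5,
                        carrier_ratio_max = 0.1, fdr = 0.01) {
  if (!channels$carrier %in% names(psms)) {
    stop("carrier channel column not found: ", channels$carrier,
         call. = FALSE)
  }
  missing_cells <- setdiff(channels$cells, names(psms))
  if (length(missing_cells)) {
    stop("single-cell channel columns not found: ",
         paste(missing_cells, collapse = ", "), call. = FALSE)
  }
  out <- psms[psms$pif >= pif_min, , drop = FALSE]
  cell_mean <- rowMeans(as.matrix(out[, channels$cells, drop = FALSE]),
                        na.rm = TRUE)
  ratio <- cell_mean / out[[channels$carrier]]
  out <- out[is.finite(ratio) & ratio <= carrier_ratio_max, , drop = FALSE]
  thr <- compute_fdr_threshold(out$pep, out$decoy, fdr)
  out <- out[thr$keep & !out$contaminant, , drop = FALSE]
  attr(out, "pep_cutoff") <- thr$cutoff
  out
}

#' Condense charge states to the most confident identification
#'
#' Per modified sequence, keeps the single row with the lowest PEP (most
#' confident charge state); ties are broken by higher precursor intensity,
#' then by lower charge for a stable order.
#'
#' @param psms PSM tibble with columns `modified_sequence`, `pep`,
#'   `precursor_intensity`, `charge`.
#' @return Tibble with one row per modified sequence.
#' @export
dedupe_charge_states <- function(psms) {
  psms |>
    dplyr::arrange(.data$pep, dplyr::desc(.data$precursor_intensity),
                   .data$charge) |>
    dplyr::distinct(.data$modified_sequence, .keep_all = TRUE)
}

#' Declare one priority tier of an inclusion list
#'
#' A tier is a named priority level plus an ordered set of selection rules
#' evaluated against a (filtered, charge-condensed) PSM table. Rules mirror
#' the vocabulary used when stratifying precursors into priority levels:
#' spectral-confidence and purity cuts, top-k peptides per protein by
#' confidence, identification-frequency windows across prior runs, seeded
#' random subsampling, and a size cap.
#'
#' @param name Tier label.
#' @param priority Non-negative integer priority; higher is fragmented first.
#' @param pep_max Keep peptides with PEP at or below this value.
#' @param pif_min Keep peptides with PIF at or above this value.
#' @param top_k_per_protein Keep at most k peptides per leading protein,
#'   ranked by PEP ascending (spectral confidence).
#' @param run_fraction_max,run_fraction_min Keep peptides identified in at
#'   most/at least this fraction of prior runs (run-level identification
#'   frequency, e.g. "identified in 50% or fewer of the shotgun runs").
#' @param sample_k Randomly subsample this many peptides (seeded, without
#'   replacement).
#' @param size_cap Cap the tier at this many peptides, keeping the most
#'   confident (lowest PEP).
#' @param fill_policy `"fixed"` (default fill time) or `"tertile"`
#'   (intensity-dependent fill times, see [assign_fill_times()]).
#' @return A list of class `tier_spec`.
#' @export
tier_spec <- function(name, priority, pep_max = NULL, pif_min = NULL,
                      top_k_per_protein = NULL, run_fraction_max = NULL,
                      run_fraction_min = NULL, sample_k = NULL,
                      size_cap = NULL, fill_policy = c("fixed", "tertile")) {
  stopifnot(priority >= 0)
  structure(list(
    name = name, priority = as.integer(priority), pep_max = pep_max,
    pif_min = pif_min, top_k_per_protein = top_k_per_protein,
    run_fraction_max = run_fraction_max, run_fraction_min = run_fraction_min,
    sample_k = sample_k, size_cap = size_cap,
    fill_policy = match.arg(fill_policy)
  ), class = "tier_spec")
}

apply_tier_rules <- function(pool, spec) {
  out <- pool
  if (!is.null(spec$pep_max)) out <- out[out$pep <= spec$pep_max, ]
  if (!is.null(spec$pif_min)) out <- out[out$pif >= spec$pif_min, ]
  if (!is.null(spec$run_fraction_max)) {
    out <- out[out$run_fraction <= spec$run_fraction_max, ]
  }
  if (!is.null(spec$run_fraction_min)) {
    out <- out[out$run_fraction >= spec$run_fraction_min, ]
  }
  if (!is.null(spec$top_k_per_protein)) {
    out <- out |>
      dplyr::arrange(.data$pep, dplyr::desc(.data$precursor_intensity)) |>
      dplyr::group_by(.data$leading_protein) |>
      dplyr::slice_head(n = spec$top_k_per_protein) |>
      dplyr::ungroup()
  }
  if (!is.null(spec$sample_k) && nrow(out) > spec$sample_k) {
    out <- out[sample.int(nrow(out), spec$sample_k), ]
  }
  if (!is.null(spec$size_cap) && nrow(out) > spec$size_cap) {
    out <- out |> dplyr::arrange(.data$pep) |>
      dplyr::slice_head(n = spec$size_cap)
  }
  out
}

#' Annotate per-peptide run identification frequency
#'
#' Adds a `run_fraction` column: for each modified sequence, the number of
#' distinct runs with at least one identification divided by the total
#' number of runs in the table. Run counting happens at the PSM level, so
#' apply this before [dedupe_charge_states()] — condensing charge states
#' first would discard the run evidence the fraction is defined over.
#'
#' @param psms PSM tibble with `modified_sequence` and `run_id`.
#' @param n_runs Total number of runs; defaults to the distinct `run_id`
#'   count of the table (pass explicitly when some runs identified nothing).
#' @return The tibble with `run_fraction` added.
#' @export
add_run_fractions <- function(psms, n_runs = dplyr::n_distinct(psms$run_id)) {
  psms |>
    dplyr::group_by(.data$modified_sequence) |>
    dplyr::mutate(run_fraction = dplyr::n_distinct(.data$run_id) / n_runs) |>
    dplyr::ungroup()
}

#' Build a tiered inclusion list from a PSM table
#'
#' Evaluates tier specifications from highest priority downward. Each tier
#' draws only from peptides not yet assigned to a higher tier, so tiers are
#' disjoint by construction. Peptides identified in the table but assigned to
#' no tier become retention-time-calibration entries: they stay on the list
#' with `ms2_enabled = FALSE` so that they participate in real-time alignment
#' without being fragmented.
#'
#' @param psms Filtered, charge-condensed PSM tibble. Rules on run
#'   identification frequency need a `run_fraction` column computed on the
#'   pre-condensation table with [add_run_fractions()]; if the column is
#'   absent it is computed from this table's `run_id` as a fallback.
#' @param specs List of [tier_spec()]s, ordered highest priority first.
#' @param seed Integer seed for `sample_k` rules; recorded in the result's
#'   `seed` attribute.
#' @return An inclusion-list tibble (see [inclusion_list()]) with columns
#'   `id`, `mz`, `charge`, `apex_rt_min`, `priority`, `ms2_enabled`,
#'   `max_fill_ms` (default fill, refine with [assign_fill_times()]), `tier`,
#'   and `precursor_intensity` carried along for fill-time assignment. A
#'   tier that cannot reach its `size_cap` is emitted short, with a row in
#'   the `warnings` attribute.
#' @export
build_tiers <- function(psms, specs, seed = 1L) {
  prios <- vapply(specs, function(s) s$priority, integer(1))
  if (anyDuplicated(prios)) {
    stop("tier priorities must be unique", call. = FALSE)
  }
  if (!"run_fraction" %in% names(psms)) {
    psms <- add_run_fractions(psms)
  }
  psms <- psms |>
    dplyr::mutate(id = paste0(.data$modified_sequence, "/", .data$charge))
  pool <- psms
  set.seed(seed)
  tiers <- list()
  warns <- character(0)
  for (spec in specs) {
    sel <- apply_tier_rules(pool, spec)
    if (!is.null(spec$size_cap) && nrow(sel) < spec$size_cap) {
      warns <- c(warns, sprintf("tier '%s': %d of %d requested entries",
                                spec$name, nrow(sel), spec$size_cap))
    }
    sel$tier <- spec$name
    sel$priority_assigned <- spec$priority
    sel$fill_policy <- spec$fill_policy
    tiers[[spec$name]] <- sel
    pool <- pool[!pool$id %in% sel$id, , drop = FALSE]
  }
  assigned <- dplyr::bind_rows(tiers)
  calib <- pool
  out <- tibble::tibble(
    id = c(assigned$id, calib$id),
    mz = c(assigned$mz, calib$mz),
    charge = c(assigned$charge, calib$charge),
    apex_rt_min = c(assigned$rt, calib$rt),
    priority = c(assigned$priority_assigned, rep(0L, nrow(calib))),
    ms2_enabled = c(rep(TRUE, nrow(assigned)), rep(FALSE, nrow(calib))),
    max_fill_ms = 500,
    tier = c(assigned$tier, rep("rt_calibration", nrow(calib))),
    fill_policy = c(assigned$fill_policy, rep("fixed", nrow(calib))),
    precursor_intensity = c(assigned$precursor_intensity,
                            calib$precursor_intensity)
  )
  attr(out, "seed") <- seed
  attr(out, "warnings") <- warns
  out
}

#' Assign intensity-dependent MS2 fill times
#'
#' Splits the supplied precursor-intensity pool into tertiles and allots fill
#' times to entries of tiers declared with the tertile policy: 1000 ms for
#' the bottom intensity tertile, 750 ms for the middle, 500 ms for the top —
#' scarce ions get more accumulation time. All other entries receive the
#' fixed default. Tertile boundaries are computed across the full supplied
#' intensity vector (conventionally, all filtered PSMs of the calibration
#' run), not per tier; ties at a boundary fall into the lower-intensity bin.
#'
#' @param inclusion Inclusion-list tibble from [build_tiers()] (columns
#'   `fill_policy` and `precursor_intensity` present).
#' @param intensity_pool Numeric vector of precursor intensities defining the
#'   tertile boundaries; needs at least 3 values for the tertile policy.
#' @param tertile_fill_ms Fill times (ms) for bottom/middle/top tertile;
#'   default `c(1000, 750, 500)`.
#' @param default_fill_ms Fill time for entries under the fixed policy.
#' @return The inclusion list with `max_fill_ms` set; entries under the
#'   tertile policy with a missing intensity fall back to the default, with a
#'   row in the `warnings` attribute.
#' @export
assign_fill_times <- function(inclusion, intensity_pool,
                              tertile_fill_ms = c(1000, 750, 500),
                              default_fill_ms = 500) {
  stopifnot(length(tertile_fill_ms) == 3)
  needs_tertile <- inclusion$fill_policy == "tertile"
  out <- inclusion
  out$max_fill_ms <- default_fill_ms
  warns <- character(0)
  if (any(needs_tertile)) {
    if (length(intensity_pool) < 3) {
      stop("tertile fill policy needs at least 3 pool intensities",
           call. = FALSE)
    }
    pool_bins <- intensity_tertile(intensity_pool)
    edges <- c(max(intensity_pool[pool_bins == 1]),
               max(intensity_pool[pool_bins == 2]))
    x <- out$precursor_intensity
    bin <- 1L + (x > edges[1]) + (x > edges[2])  # ties -> lower bin
    miss <- needs_tertile & is.na(x)
    if (any(miss)) {
      warns <- c(warns, sprintf(
        "%d tertile-policy entries lack an intensity; default fill used",
        sum(miss)))
    }
    sel <- needs_tertile & !is.na(x)
    out$max_fill_ms[sel] <- tertile_fill_ms[bin[sel]]
  }
  attr(out, "warnings") <- warns
  out
}

#' Tertile bin index of intensities
#'
#' Rank-balanced tertile assignment used for scout-run stratification: the
#' sorted intensities are split into three groups whose sizes differ by at
#' most one (extra members go to the lower bins), bin 1 = bottom third.
#'
#' @param x Numeric vector (distinct values give exactly balanced bins).
#' @return Integer vector of bins in `{1, 2, 3}`.
#' @export
intensity_tertile <- function(x) {
  n <- length(x)
  sizes <- rep(n %/% 3, 3) + c(rep(1L, n %% 3), rep(0L, 3 - n %% 3))
  bins <- rep.int(1:3, sizes)
  out <- integer(n)
  out[order(x)] <- bins
  out
}
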