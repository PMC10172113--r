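#' Acquisition configuration
#'
#' Bundles the instrument and scheduling parameters of the duty-cycle
#' simulator. One duty cycle consists of a survey (MS1) scan followed by as
#' many MS2 scans as fit into the remaining cycle time; each MS2 scan costs
#' its allotted maximum fill time plus a fixed per-scan overhead.
#'
#' @param cycle_time_s Total duty-cycle time budget, seconds.
#' @param survey_cost_s Cost of the survey scan, seconds. Must be smaller
#'   than `cycle_time_s`.
#' @param ms2_overhead_s Fixed per-MS2-scan overhead (transients, processing),
#'   seconds.
#' @param default_fill_ms Fill time used for MS2 scans that carry no explicit
#'   allotment (topN mode), milliseconds.
#' @param rt_tolerance_min Retention-time tolerance around the (offset
#'   corrected) predicted apex within which an inclusion entry is considered
#'   detectable, minutes.
#' @param noise_floor Minimum instantaneous MS1 intensity for a precursor to
#'   be detected in a survey scan, arbitrary intensity units.
#' @param topn_n Number of precursors fragmented per cycle in topN shotgun
#'   mode.
#' @param dyn_exclusion_s Dynamic-exclusion duration after a precursor is
#'   fragmented, seconds.
#' @param id_threshold_ions Sampled-ion threshold (instantaneous intensity
#'   times fill time in ms) above which an MS2 event yields a confident
#'   identification.
#' @param calib_window Number of most recent calibration observations used by
#'   the real-time retention-time alignment.
#' @param gradient_min Active gradient length (run span), minutes.
#' @param seed Optional integer seed recorded with the configuration.
#'
#' @return A list of class `acq_config`.
#' @export
#' @examples
#' cfg <- acquisition_config(cycle_time_s = 3, topn_n = 5)
#' cfg$rt_tolerance_min
acquisition_config <- function(cycle_time_s = 3,
                               survey_cost_s = 0.5,
                               ms2_overhead_s = 0.02,
                               default_fill_ms = 300,
                               rt_tolerance_min = 1,
                               noise_floor = 100,
                               topn_n = 10,
                               dyn_exclusion_s = 30,
                               id_threshold_ions = 1e5,
                               calib_window = 20,
                               gradient_min = 60,
                               seed = NULL) {
  cfg <- list(
    cycle_time_s = cycle_time_s, survey_cost_s = survey_cost_s,
    ms2_overhead_s = ms2_overhead_s, default_fill_ms = default_fill_ms,
    rt_tolerance_min = rt_tolerance_min, noise_floor = noise_floor,
    topn_n = topn_n, dyn_exclusion_s = dyn_exclusion_s,
    id_threshold_ions = id_threshold_ions, calib_window = calib_window,
    gradient_min = gradient_min, seed = seed
  )
  durs <- c("cycle_time_s", "survey_cost_s", "ms2_overhead_s",
            "default_fill_ms", "rt_tolerance_min", "gradient_min")
  if (any(unlist(cfg[durs]) <= 0)) {
    stop("all durations in an acquisition config must be > 0", call. = FALSE)
  }
  if (cycle_time_s <= survey_cost_s) {
    stop("cycle_time_s must exceed survey_cost_s", call. = FALSE)
  }
  structure(cfg, class = "acq_config")
}

#' Instantaneous Gaussian elution intensity
#'
#' @param peptides Tibble of simulated peptides (`sim_peptides()` layout) with
#'   columns `apex_rt`, `rt_drift`, `peak_sigma`, `max_intensity`.
#' @param t Time point, minutes.
#' @return Numeric vector of intensities at `t`; the elution profile is
#'   Gaussian around the drift-shifted apex.
#' @keywords internal
elution_intensity <- function(peptides, t) {
  apex_true <- peptides$apex_rt + peptides$rt_drift
  peptides$max_intensity * exp(-(t - apex_true)^2 / (2 * peptides$peak_sigma^2))
}

#' Survey-scan detection of inclusion-list entries
#'
#' An inclusion entry is detected at time `t` when `t` lies within the
#' retention-time tolerance of its offset-corrected predicted apex and the
#' matched peptide's instantaneous Gaussian elution intensity is at or above
#' the configured noise floor.
#'
#' @param peptides Ground-truth peptide tibble (see [sim_peptides()]):
#'   columns `id`, `mz`, `charge`, `apex_rt`, `peak_sigma`, `max_intensity`,
#'   `rt_drift`.
#' @param inclusion Inclusion-list tibble (see [inclusion_list()]): columns
#'   `id`, `mz`, `apex_rt_min`, `priority`, `ms2_enabled`, `max_fill_ms`.
#' @param t Survey-scan time, minutes.
#' @param offset Current retention-time offset estimate, minutes.
#' @param config An [acquisition_config()].
#'
#' @return Tibble of detected entries with columns `id`, `mz`, `priority`,
#'   `ms2_enabled`, `max_fill_ms`, `intensity`, `apex_true`. Entries whose id
#'   has no matching peptide are undetectable and are returned in the
#'   `unmatched` attribute (a character vector) — this signals a mismatch
#'   between the list and the fixture rather than an empty survey.
#' @export
detect_survey <- function(peptides, inclusion, t, offset = 0, config) {
  stopifnot(inherits(config, "acq_config"))
  hit <- dplyr::inner_join(inclusion, peptides,
                           by = "id", suffix = c("", ".pep"))
  unmatched <- setdiff(inclusion$id, hit$id)
  inten <- elution_intensity(hit, t)
  in_window <- abs(t - (hit$apex_rt_min + offset)) <= config$rt_tolerance_min
  keep <- in_window & inten >= config$noise_floor
  out <- tibble::tibble(
    id = hit$id[keep], mz = hit$mz[keep], priority = hit$priority[keep],
    ms2_enabled = hit$ms2_enabled[keep], max_fill_ms = hit$max_fill_ms[keep],
    intensity = inten[keep],
    apex_true = hit$apex_rt[keep] + hit$rt_drift[keep]
  )
  attr(out, "unmatched") <- unmatched
  out
}

#' Real-time retention-time alignment
#'
#' Estimates the additive offset between predicted and observed apex
#' retention times as the median of (observed - predicted) over the most
#' recent `calib_window` calibration observations. With no observations the
#' offset is zero.
#'
#' @param calibration A data frame with columns `predicted` and `observed`
#'   (minutes), oldest first, or `NULL`.
#' @param config An [acquisition_config()].
#' @return Offset in minutes.
#' @export
#' @examples
#' cfg <- acquisition_config()
#' align_rt(data.frame(predicted = c(10, 20), observed = c(12, 22)), cfg)
align_rt <- function(calibration, config) {
  if (is.null(calibration) || nrow(calibration) == 0) return(0)
  n <- nrow(calibration)
  recent <- calibration[max(1L, n - config$calib_window + 1L):n, , drop = FALSE]
  stats::median(recent$observed - recent$predicted)
}

#' Select the MS2 targets of one duty cycle
#'
#' In prioritized mode candidates are ordered by current priority
#' (descending), then intensity (descending), then m/z (ascending), and
#' packed greedily first-fit: an entry is selected when its cost (its own
#' maximum fill time plus the per-scan overhead) still fits the remaining
#' budget at its turn; later, cheaper entries may still be taken after a
#' misfit so that duty cycles stay full. In topN mode candidates are ordered
#' by intensity alone, each scan costs the default fill time plus overhead,
#' and at most `topn_n` entries are taken.
#'
#' @param detected Tibble of detected candidates with columns `id`, `mz`,
#'   `intensity`, `priority`, `max_fill_ms` (entries must already be
#'   MS2-enabled and not dynamically excluded).
#' @param budget_s Remaining cycle time after the survey scan, seconds. A
#'   negative budget selects nothing.
#' @param config An [acquisition_config()].
#' @param mode `"prioritized"` or `"topn"`.
#' @return The selected rows, in selection order, with columns `fill_ms` and
#'   `cost_s` added; total cost never exceeds `budget_s`.
#' @export
select_cycle <- function(detected, budget_s, config,
                         mode = c("prioritized", "topn")) {
  mode <- match.arg(mode)
  empty <- dplyr::mutate(detected[0, ], fill_ms = numeric(0),
                         cost_s = numeric(0))
  if (budget_s < 0 || nrow(detected) == 0) return(empty)
  sel <- select_indices(detected$priority, detected$intensity, detected$mz,
                        detected$max_fill_ms, budget_s, config, mode)
  out <- detected[sel$idx, , drop = FALSE]
  out$fill_ms <- sel$fill_ms
  out$cost_s <- sel$cost_s
  out
}

# shared selection kernel: returns indices (in selection order) plus their
# fill times and costs; greedy first-fit down the sorted candidate list
select_indices <- function(priority, intensity, mz, max_fill_ms, budget_s,
                           config, mode) {
  if (mode == "prioritized") {
    ord <- order(-priority, -intensity, mz)
    fill <- max_fill_ms[ord]
  } else {
    ord <- order(-intensity, mz)
    ord <- ord[seq_len(min(length(ord), config$topn_n))]
    fill <- rep(config$default_fill_ms, length(ord))
  }
  cost <- fill / 1000 + config$ms2_overhead_s
  remaining <- budget_s
  take <- logical(length(ord))
  for (i in seq_along(ord)) {
    if (cost[i] <= remaining) {
      take[i] <- TRUE
      remaining <- remaining - cost[i]
    }
  }
  list(idx = ord[take], fill_ms = fill[take], cost_s = cost[take])
}

#' Simulate one LC-MS run
#'
#' Iterates duty cycles across the gradient. Each cycle performs a survey
#' scan, updates the retention-time offset from calibration observations
#' accumulated so far, selects MS2 targets among the detected, non-excluded,
#' MS2-enabled inclusion entries, and executes the MS2 events. After each
#' fragmentation that occurred within the retention-time tolerance of the
#' entry's true apex, the entry's stored priority is decremented by one
#' (floored at zero); fragmentation outside the tolerance leaves the
#' priority unchanged. Fragmented entries enter dynamic exclusion. The number
#' of ions sampled by an MS2 event is the instantaneous precursor intensity
#' times the fill time (ms); the event counts as identified when that product
#' reaches `id_threshold_ions`.
#'
#' Every inclusion entry — MS2-enabled or calibration-only — contributes one
#' retention-time calibration observation the first time a survey scan
#' detects it at or past its true apex.
#'
#' @inheritParams detect_survey
#' @param config An [acquisition_config()].
#' @param mode `"prioritized"` or `"topn"`.
#' @param seed Optional integer; the scheduler itself is deterministic, the
#'   seed is recorded in the log attributes for provenance.
#' @return A tibble of class `run_log`: one row per event with columns
#'   `cycle_index`, `scan_time_min`, `event_kind` (`"survey"`/`"ms2"`),
#'   `precursor_id`, `priority_at_selection`, `fill_ms`, `ions_sampled`,
#'   `identified`, `rt_offset_estimate_min`. Survey rows list each detected
#'   entry (or a single `NA` row when nothing was detected).
#' @export
simulate_run <- function(peptides, inclusion, config,
                         mode = c("prioritized", "topn"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "acq_config"))
  if (!is.null(seed)) set.seed(seed)
  cycle_min <- config$cycle_time_s / 60
  n_cycles <- floor(config$gradient_min / cycle_min)
  if (n_cycles < 1) {
    out <- empty_run_log()
    attr(out, "mode") <- mode
    attr(out, "seed") <- seed
    return(out)
  }

  # resolve inclusion entries to ground-truth peptides once
  hit <- dplyr::inner_join(
    inclusion, peptides[, c("id", "apex_rt", "peak_sigma", "max_intensity",
                            "rt_drift")], by = "id")
  ord <- order(hit$apex_rt_min)
  id <- hit$id[ord]
  mz <- hit$mz[ord]
  apex_pred <- hit$apex_rt_min[ord]
  apex_true <- hit$apex_rt[ord] + hit$rt_drift[ord]
  sigma <- hit$peak_sigma[ord]
  max_int <- hit$max_intensity[ord]
  ms2_enabled <- hit$ms2_enabled[ord]
  max_fill <- hit$max_fill_ms[ord]
  cur_pri <- as.numeric(hit$priority[ord])
  excluded_until <- rep(-Inf, length(id))
  calibrated <- logical(length(id))
  calib_pred <- numeric(0)
  calib_obs <- numeric(0)
  offset <- 0
  budget_s <- config$cycle_time_s - config$survey_cost_s
  rows <- vector("list", n_cycles)

  for (k in seq_len(n_cycles)) {
    t <- (k - 1) * cycle_min
    # RT window on the sorted predicted apexes, then the noise-floor gate
    lo <- findInterval(t - offset - config$rt_tolerance_min, apex_pred,
                       left.open = TRUE) + 1L
    hi <- findInterval(t - offset + config$rt_tolerance_min, apex_pred)
    det <- integer(0)
    inten <- numeric(0)
    if (hi >= lo) {
      win <- lo:hi
      inten_w <- max_int[win] *
        exp(-(t - apex_true[win])^2 / (2 * sigma[win]^2))
      keep <- inten_w >= config$noise_floor
      det <- win[keep]
      inten <- inten_w[keep]
    }
    # calibration: first survey detection at/past the true apex
    new_obs <- det[!calibrated[det] & t >= apex_true[det]]
    if (length(new_obs)) {
      calibrated[new_obs] <- TRUE
      calib_pred <- c(calib_pred, apex_pred[new_obs])
      calib_obs <- c(calib_obs, apex_true[new_obs])
    }
    offset <- align_rt(
      if (length(calib_pred)) {
        data.frame(predicted = calib_pred, observed = calib_obs)
      } else NULL, config)

    cand <- det[ms2_enabled[det] & excluded_until[det] <= t]
    sel <- select_indices(cur_pri[cand], inten[match(cand, det)], mz[cand],
                          max_fill[cand], budget_s, config, mode)
    si <- cand[sel$idx]
    n_ms2 <- length(si)
    scan_t <- if (n_ms2) {
      t + (config$survey_cost_s + cumsum(sel$cost_s)) / 60
    } else numeric(0)
    ions <- inten[match(si, det)] * sel$fill_ms
    pri_at_sel <- cur_pri[si]
    if (n_ms2) {
      in_tol <- abs(scan_t - apex_true[si]) <= config$rt_tolerance_min
      cur_pri[si] <- ifelse(in_tol, pmax(cur_pri[si] - 1, 0), cur_pri[si])
      excluded_until[si] <- scan_t + config$dyn_exclusion_s / 60
    }
    n_sur <- max(length(det), 1L)
    rows[[k]] <- list(
      cycle_index = rep(k, n_sur + n_ms2),
      scan_time_min = c(rep(t, n_sur), scan_t),
      event_kind = rep(c("survey", "ms2"), c(n_sur, n_ms2)),
      precursor_id = c(if (length(det)) id[det] else NA_character_,
                       id[si]),
      priority_at_selection = c(rep(NA_real_, n_sur), pri_at_sel),
      fill_ms = c(rep(NA_real_, n_sur), sel$fill_ms),
      ions_sampled = c(rep(NA_real_, n_sur), ions),
      identified = c(rep(NA, n_sur), ions >= config$id_threshold_ions),
      rt_offset_estimate_min = rep(offset, n_sur + n_ms2)
    )
  }
  out <- tibble::as_tibble(lapply(stats::setNames(nm = names(rows[[1]])),
                                  function(f) {
                                    unlist(lapply(rows, `[[`, f),
                                           use.names = FALSE)
                                  }))
  class(out) <- c("run_log", class(out))
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  attr(out, "config") <- config
  out
}

run_log_row <- function(cycle, t, kind, id, pri, fill, ions, ident, offset) {
  tibble::tibble(
    cycle_index = cycle, scan_time_min = t, event_kind = kind,
    precursor_id = id, priority_at_selection = as.numeric(pri),
    fill_ms = as.numeric(fill), ions_sampled = as.numeric(ions),
    identified = as.logical(ident), rt_offset_estimate_min = offset
  )
}

empty_run_log <- function() {
  out <- run_log_row(integer(0), numeric(0), character(0), character(0),
                     numeric(0), numeric(0), numeric(0), logical(0),
                     numeric(0))
  class(out) <- c("run_log", class(out))
  out
}

#' Per-tier acquisition metrics
#'
#' Summarizes a simulated run per initial-priority tier of the MS2-enabled
#' inclusion entries: the percentage of tier entries detected in at least one
#' survey scan, sent to at least one MS2 scan, and identified at least once.
#'
#' @param log A `run_log` from [simulate_run()].
#' @param inclusion The inclusion list the run was simulated over.
#' @return Tibble with columns `priority`, `n_entries`, `detect_pct`,
#'   `send_pct`, `id_pct`; rates are in `[0, 100]`. A tier with no entries is
#'   reported with `NA` rates rather than zero.
#' @export
run_metrics <- function(log, inclusion) {
  targets <- dplyr::filter(inclusion, .data$ms2_enabled)
  detected_ids <- unique(log$precursor_id[log$event_kind == "survey" &
                                            !is.na(log$precursor_id)])
  ms2 <- log[log$event_kind == "ms2", , drop = FALSE]
  sent_ids <- unique(ms2$precursor_id)
  ident_ids <- unique(ms2$precursor_id[ms2$identified])
  targets |>
    dplyr::group_by(priority = .data$priority) |>
    dplyr::summarise(
      n_entries = dplyr::n(),
      detect_pct = 100 * mean(.data$id %in% detected_ids),
      send_pct = 100 * mean(.data$id %in% sent_ids),
      id_pct = 100 * mean(.data$id %in% ident_ids),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$priority))
}

#' Percent gain of an improved rate over a baseline
#'
#' Reports the relative increase of `improved_pct` over `baseline_pct` as a
#' percentage, rounded to the nearest integer: an 18% baseline rising to 59%
#' is a 228% gain.
#'
#' @param baseline_pct Baseline percentage; must be positive (a zero baseline
#'   has no defined relative gain).
#' @param improved_pct Improved percentage.
#' @return Integer-valued percent increase.
#' @export
#' @examples
#' percent_gain(18, 59)
percent_gain <- function(baseline_pct, improved_pct) {
  if (any(baseline_pct <= 0)) {
    stop("percent gain is undefined for a non-positive baseline", call. = FALSE)
  }
  round((improved_pct - baseline_pct) / baseline_pct * 100)
}
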