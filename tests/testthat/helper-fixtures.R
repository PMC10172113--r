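# shared fixtures and independent oracles used across test files

# a small deterministic peptide population plus matching inclusion list
tiny_population <- function(n = 40, seed = 7, gradient_min = 20,
                            drift = list(type = "constant", value = 0,
                                         jitter_sd = 0)) {
  pop <- make_lcms_population(n_peptides = n, gradient_min = gradient_min,
                              drift = drift, seed = seed)
  list(pop = pop,
       inclusion = inclusion_list(pop$candidates,
                                  priority = rep_len(0:2, n)))
}

# independent greedy packing oracle: sort, then first-fit down the list
oracle_select <- function(detected, budget_s, config, mode) {
  if (budget_s < 0 || nrow(detected) == 0) return(character(0))
  if (mode == "prioritized") {
    ord <- order(-detected$priority, -detected$intensity, detected$mz)
    fill <- detected$max_fill_ms[ord]
  } else {
    ord <- order(-detected$intensity, detected$mz)
    ord <- head(ord, config$topn_n)
    fill <- rep(config$default_fill_ms, length(ord))
  }
  cost <- fill / 1000 + config$ms2_overhead_s
  chosen <- character(0)
  for (i in seq_along(ord)) {
    if (cost[i] <= budget_s) {
      chosen <- c(chosen, detected$id[ord[i]])
      budget_s <- budget_s - cost[i]
    }
  }
  chosen
}

# exhaustive-scan FDR oracle: try every observed PEP as cutoff
oracle_fdr_cutoff <- function(peps, decoys, target) {
  cand <- sort(unique(peps))
  ok <- vapply(cand, function(cut) {
    sel <- peps <= cut
    mean(decoys[sel]) <= target
  }, logical(1))
  if (!any(ok)) -Inf else max(cand[ok])
}

# step-up BH oracle written directly from the procedure definition
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# per-cycle budget audit of a run log against its configuration
cycle_costs <- function(log, config) {
  ms2 <- log[log$event_kind == "ms2", , drop = FALSE]
  per_cycle <- tapply(ms2$fill_ms / 1000 + config$ms2_overhead_s,
                      ms2$cycle_index, sum)
  config$survey_cost_s + as.numeric(per_cycle)
}

# the constrained-budget scenario: dense co-elution so per-cycle MS2 budget
# covers only part of the detected load
constrained_scenario <- function(seed = 101) {
  pop <- make_lcms_population(
    n_peptides = 1500, gradient_min = 15,
    drift = list(type = "constant", value = 0.3, jitter_sd = 0.05),
    seed = seed)
  set.seed(seed + 1)
  pri <- sample(rep(0:2, each = 500))
  inc <- inclusion_list(pop$candidates, priority = pri, max_fill_ms = 500)
  cfg <- acquisition_config(
    cycle_time_s = 2, survey_cost_s = 0.5, ms2_overhead_s = 0.05,
    default_fill_ms = 500, rt_tolerance_min = 0.5, noise_floor = 50,
    topn_n = 5, dyn_exclusion_s = 60, id_threshold_ions = 1e6,
    gradient_min = 15)
  list(pop = pop, inclusion = inc, config = cfg)
}
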