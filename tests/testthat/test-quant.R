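# a tiny fully controlled matrix: 2 proteins x 2-3 peptides, 3 cells + 1
# control column
tiny_qm <- function(values) {
  feats <- tibble::tibble(
    feature = c("pA_1", "pA_2", "pB_1", "pB_2", "pB_3"),
    protein = c("A", "A", "B", "B", "B"),
    tier = c("high", "high", "low", "low", "low"))
  cells <- tibble::tibble(
    cell = c("c1", "c2", "c3", "ctrl1"),
    condition = c("x", "x", "y", "control"),
    control = c(FALSE, FALSE, FALSE, TRUE),
    run_id = c("r1", "r1", "r2", "r2"))
  quant_matrix(values, cells, feats)
}

test_that("per-cell protein CVs match a direct sd/mean recomputation", {
  set.seed(23)
  v <- matrix(rlnorm(20, 3, 0.5), 5, 4,
              dimnames = list(c("pA_1", "pA_2", "pB_1", "pB_2", "pB_3"),
                              c("c1", "c2", "c3", "ctrl1")))
  qm <- tiny_qm(v)
  rep <- qc_cells(qm, cv_threshold = Inf)$report
  for (cl in c("c1", "c2", "c3")) {
    cv_a <- sd(v[1:2, cl]) / mean(v[1:2, cl])
    cv_b <- sd(v[3:5, cl]) / mean(v[3:5, cl])
    expect_equal(rep$cv[rep$cell == cl], mean(c(cv_a, cv_b)))
  }
  # median aggregator
  rep_med <- qc_cells(qm, cv_threshold = Inf, aggregator = "median")$report
  cv_a <- sd(v[1:2, "c1"]) / mean(v[1:2, "c1"])
  cv_b <- sd(v[3:5, "c1"]) / mean(v[3:5, "c1"])
  expect_equal(rep_med$cv[rep_med$cell == "c1"], median(c(cv_a, cv_b)))
  # random matrices against the oracle across aggregators
  for (i in 1:5) {
    v2 <- matrix(rlnorm(20, 2, 1), 5, 4,
                 dimnames = dimnames(v))
    rep2 <- qc_cells(tiny_qm(v2), cv_threshold = Inf)$report
    ora <- vapply(colnames(v2), function(cl) {
      mean(c(sd(v2[1:2, cl]) / mean(v2[1:2, cl]),
             sd(v2[3:5, cl]) / mean(v2[3:5, cl])))
    }, numeric(1))
    expect_equal(rep2$cv, unname(ora))
  }
})

test_that("the CV filter keeps tight cells, drops noisy or undefined ones,
           and sidelines controls", {
  v <- matrix(10, 5, 4,
              dimnames = list(c("pA_1", "pA_2", "pB_1", "pB_2", "pB_3"),
                              c("c1", "c2", "c3", "ctrl1")))
  # c1: all peptides equal -> CV 0, kept
  # c2: dispersion tuned to mean CV 0.45 -> removed at 0.4
  v["pA_1", "c2"] <- 10 * (1 + 0.45 * sqrt(2) / sqrt(2))  # cv_A = .45-ish
  v[, "c2"] <- c(6, 14, 6, 10, 14)   # direct construction instead
  # c3: only one observed peptide per protein -> undefined, removed
  v[c("pA_2", "pB_2", "pB_3"), "c3"] <- NA
  qm <- tiny_qm(v)
  res <- qc_cells(qm, cv_threshold = 0.4)
  rep <- res$report
  expect_true(rep$pass[rep$cell == "c1"])
  cv_c2 <- mean(c(sd(c(6, 14)) / 10, sd(c(6, 10, 14)) / 10))
  expect_equal(rep$cv[rep$cell == "c2"], cv_c2)
  expect_equal(rep$pass[rep$cell == "c2"], cv_c2 <= 0.4)
  expect_equal(rep$reason[rep$cell == "c3"], "no_multi_peptide_protein")
  # controls never enter the filtered matrix even if they pass
  expect_false("ctrl1" %in% colnames(res$filtered$values))
  expect_true("ctrl1" %in% rep$cell)
  # cells at exactly the threshold are kept (strict 'greater than' removal)
  v2 <- matrix(10, 5, 4, dimnames = dimnames(v))
  expect_true(all(qc_cells(tiny_qm(v2), 0.4)$report$pass))
})

test_that("normalization chain matches a straight-line oracle and
           aggregates by median", {
  set.seed(29)
  v <- matrix(rlnorm(20, 4, 1), 5, 4,
              dimnames = list(c("pA_1", "pA_2", "pB_1", "pB_2", "pB_3"),
                              c("c1", "c2", "c3", "ctrl1")))
  qm <- tiny_qm(v)
  res <- normalize_and_aggregate(qm)
  # independent straight-line reimplementation
  o <- v
  o <- sweep(o, 2, apply(o, 2, median), "/")
  o <- sweep(o, 1, rowMeans(o), "/")
  lo <- log2(o)
  expect_equal(res$precursor_log2, lo)
  prot_oracle <- rbind(A = apply(lo[1:2, ], 2, median),
                       B = apply(lo[3:5, ], 2, median))
  expect_equal(res$protein_log2, prot_oracle)
  # post-condition: observed column medians are 1 after column scaling
  col_med <- apply(sweep(v, 2, apply(v, 2, median), "/"), 2, median)
  expect_equal(unname(col_med), rep(1, 4))
  # median aggregation example: peptide log2 values {-1, 0, 2} -> 0
  vv <- matrix(2^c(-1, 0, 2), 3, 1,
               dimnames = list(c("pB_1", "pB_2", "pB_3"), "c1"))
  feats <- tibble::tibble(feature = rownames(vv), protein = "B",
                          tier = "low")
  cells <- tibble::tibble(cell = "c1", condition = "x", control = FALSE)
  qm1 <- quant_matrix(vv, cells, feats)
  lv <- log2(vv)  # skip normalization: aggregate directly
  expect_equal(median(lv[, 1]), 0)
  # missingness propagates; no imputation
  v_na <- v
  v_na["pA_1", "c1"] <- NA
  res_na <- normalize_and_aggregate(tiny_qm(v_na))
  expect_true(is.na(res_na$precursor_log2["pA_1", "c1"]))
  expect_false(anyNA(res_na$protein_log2[, "c2"]))
  # all-missing columns are dropped with a report
  v_drop <- v
  v_drop[, "c3"] <- NA
  res_drop <- normalize_and_aggregate(tiny_qm(v_drop))
  expect_equal(res_drop$dropped_cells, "c3")
})

test_that("column/row normalization is idempotent on complete matrices with
           multiplicative sample and peptide effects", {
  # the normalization removes exactly per-cell loading and per-peptide
  # efficiency factors; on such product-structured matrices a second pass
  # is a no-op (general matrices only approach idempotence asymptotically)
  set.seed(31)
  norm_once <- function(m) {
    m <- sweep(m, 2, apply(m, 2, median), "/")
    sweep(m, 1, rowMeans(m), "/")
  }
  for (i in 1:5) {
    v <- outer(rlnorm(8, 0, 1), rlnorm(12, 0, 1))
    once <- norm_once(v)
    twice <- norm_once(once)
    expect_equal(twice, once, tolerance = 1e-12)
  }
})

test_that("missingness filtering uses a strict threshold, cells before
           features", {
  # feature observed in 1 of 200 cells: 99.5% missing -> dropped
  v <- matrix(rlnorm(200 * 3), 3, 200,
              dimnames = list(c("f1", "f2", "f3"),
                              sprintf("c%03d", 1:200)))
  v["f1", 2:200] <- NA
  feats <- tibble::tibble(feature = rownames(v), protein = "P",
                          tier = "high")
  cells <- tibble::tibble(cell = colnames(v), condition = "x",
                          control = FALSE)
  qm <- quant_matrix(v, cells, feats)
  out <- missingness_filter(qm, 0.99)
  expect_false("f1" %in% rownames(out$values))
  # boundary: 98.9% missing is kept under the strict rule
  v2 <- v
  v2["f1", ] <- NA
  v2["f1", 1:3] <- 1   # 197/200 = 98.5% missing
  out2 <- missingness_filter(quant_matrix(v2, cells, feats), 0.99)
  expect_true("f1" %in% rownames(out2$values))
  # complete matrices pass unchanged
  v3 <- matrix(1, 3, 4, dimnames = list(rownames(v), sprintf("c%d", 1:4)))
  qm3 <- quant_matrix(v3, tibble::tibble(cell = colnames(v3),
                                         condition = "x", control = FALSE),
                      feats)
  expect_equal(dim(missingness_filter(qm3)$values), c(3L, 4L))
  # cells are filtered before features (a cell that is all-NA is removed
  # first, which can rescue a feature)
  v4 <- matrix(1, 2, 3, dimnames = list(c("f1", "f2"), c("c1", "c2", "c3")))
  v4[, "c1"] <- NA
  v4["f1", c("c2", "c3")] <- c(1, NA)
  qm4 <- quant_matrix(v4, tibble::tibble(cell = colnames(v4),
                                         condition = "x", control = FALSE),
                      feats[1:2, ])
  out4 <- missingness_filter(qm4, max_missing_fraction = 0.6)
  expect_false("c1" %in% colnames(out4$values))
  expect_true("f1" %in% rownames(out4$values))  # 1/2 = 50% < 60% after drop
})

test_that("completeness equals a boolean counting oracle", {
  set.seed(37)
  v <- matrix(rlnorm(5 * 4), 5, 4,
              dimnames = list(c("pA_1", "pA_2", "pB_1", "pB_2", "pB_3"),
                              c("c1", "c2", "c3", "ctrl1")))
  v[matrix(runif(20) < 0.3, 5, 4)] <- NA
  qm <- tiny_qm(v)
  comp <- completeness(qm)
  for (cl in colnames(v)) {
    hi <- comp$per_cell[comp$per_cell$cell == cl &
                          comp$per_cell$tier == "high", ]
    expect_equal(hi$completeness_pct, 100 * sum(!is.na(v[1:2, cl])) / 2)
    lo <- comp$per_cell[comp$per_cell$cell == cl &
                          comp$per_cell$tier == "low", ]
    expect_equal(lo$completeness_pct, 100 * sum(!is.na(v[3:5, cl])) / 3)
  }
  # 3 of 4 observed -> 75%; fully observed -> 100%
  v5 <- matrix(1, 4, 1, dimnames = list(sprintf("f%d", 1:4), "c1"))
  v5[4, 1] <- NA
  qm5 <- quant_matrix(
    v5, tibble::tibble(cell = "c1", condition = "x", control = FALSE),
    tibble::tibble(feature = rownames(v5), protein = "P", tier = "t"))
  expect_equal(completeness(qm5)$per_cell$completeness_pct, 75)
  # per-feature across-run identification rate
  pf <- comp$per_feature
  runs <- split(qm$cells$cell, qm$cells$run_id)
  for (f in rownames(v)) {
    ident <- sum(vapply(runs, function(cls) any(!is.na(v[f, cls])),
                        logical(1)))
    expect_equal(pf$id_rate_pct[pf$feature == f], 100 * ident / 2)
  }
  # numerators never exceed denominators
  expect_true(all(comp$per_cell$n_observed <= comp$per_cell$n_total))
})

test_that("intensity bins partition PSMs and expose platform shifts", {
  set.seed(41)
  n <- 600
  psms <- tibble::tibble(
    run_id = rep(sprintf("r%d", 1:6), each = n / 6),
    platform = rep(c("shotgun", "prioritized"), each = n / 2),
    precursor_intensity = rlnorm(n, 11, 1))
  dist <- intensity_distribution(psms, n_bins = 30)
  expect_equal(nrow(dist), 60)  # 30 bins per platform
  # identical runs give zero s.d. in all bins
  psms_id <- tibble::tibble(
    run_id = rep(c("a", "b"), each = 50),
    platform = "p",
    precursor_intensity = rep(rlnorm(50, 10, 1), 2))
  dist_id <- intensity_distribution(psms_id)
  expect_true(all(dist_id$sd_n == 0))
  expect_equal(sum(dist_id$median_n), 50)
  # a platform shifted to lower abundance populates bins the other leaves
  # empty, by construction of disjoint supports
  lo <- tibble::tibble(run_id = "lo", platform = "low",
                       precursor_intensity = rlnorm(100, 6, 0.1))
  hi <- tibble::tibble(run_id = "hi", platform = "high",
                       precursor_intensity = rlnorm(100, 14, 0.1))
  both <- dplyr::bind_rows(lo, hi)
  d2 <- intensity_distribution(both)
  expect_equal(sum(d2$median_n[d2$platform == "low"]), 100)
  expect_equal(sum(d2$median_n[d2$platform == "high"]), 100)
  expect_equal(attr(d2, "single_run_platforms"), c("high", "low"))
})

test_that("quant matrices round-trip through TSV with sidecar metadata", {
  sc <- make_singlecell_matrix(n_cells = 8, n_controls = 2,
                               n_modules = 2, module_size = 3,
                               peptides_per_protein = 2, seed = 43)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_matrix(sc$qm, path)
  back <- read_quant_matrix(path)
  expect_equal(back$values, sc$qm$values)
  expect_equal(as.data.frame(back$cells), as.data.frame(sc$qm$cells))
  expect_equal(as.data.frame(back$features), as.data.frame(sc$qm$features))
})
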