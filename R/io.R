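#' Read and write inclusion-list TSV
#'
#' The on-disk layout has header columns `id`, `mz`, `charge`,
#' `apex_rt_min`, `priority`, `ms2_enabled` (0/1), `max_fill_ms`; the
#' priority is a plain column of the table so lists remain hand-editable.
#' Extra columns (e.g. `tier`) round-trip unchanged.
#'
#' @param path File path.
#' @param x Inclusion-list tibble.
#' @return `read_inclusion_list()` returns the tibble with `ms2_enabled` as
#'   logical.
#' @export
read_inclusion_list <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out$ms2_enabled <- as.logical(out$ms2_enabled)
  out$priority <- as.integer(out$priority)
  out
}

#' @rdname read_inclusion_list
#' @export
write_inclusion_list <- function(x, path) {
  x$ms2_enabled <- as.integer(x$ms2_enabled)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a PSM table from a column-mapped TSV
#'
#' Reads an evidence-style TSV and renames columns according to `mapping`
#' (names = canonical names used by the package, values = file headers), so
#' arbitrary search-engine exports can be adapted without a bespoke parser.
#'
#' @param path File path.
#' @param mapping Named character vector; `NULL` assumes canonical headers.
#' @return PSM tibble with logical `decoy`/`contaminant`.
#' @export
read_psm_table <- function(path, mapping = NULL) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(mapping)) {
    miss <- setdiff(unname(mapping), names(out))
    if (length(miss)) {
      stop("mapped columns absent from file: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    out <- dplyr::rename(out, !!!rlang::set_names(mapping, names(mapping)))
  }
  for (col in c("decoy", "contaminant")) {
    if (col %in% names(out)) out[[col]] <- as.logical(out[[col]])
  }
  out
}

#' @rdname read_psm_table
#' @param x PSM tibble.
#' @export
write_psm_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write and read a run log
#'
#' Logs are written as JSONL (one event per line, replayable) plus a TSV
#' summary of per-tier metrics when an inclusion list is supplied.
#'
#' @param log A `run_log` tibble.
#' @param path Output path for the JSONL stream.
#' @param inclusion Optional inclusion list; when given, a `<path>.summary.tsv`
#'   with [run_metrics()] is written alongside.
#' @return The path, invisibly.
#' @export
write_run_log <- function(log, path, inclusion = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  if (!is.null(inclusion)) {
    readr::write_tsv(run_metrics(log, inclusion),
                     paste0(path, ".summary.tsv"), progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_run_log
#' @export
read_run_log <- function(path) {
  rows <- lapply(readLines(path), function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    tibble::as_tibble(x)
  })
  out <- dplyr::bind_rows(rows)
  out$precursor_id <- as.character(out$precursor_id)
  out$identified <- as.logical(out$identified)
  for (col in c("priority_at_selection", "fill_ms", "ions_sampled")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  class(out) <- c("run_log", class(out))
  out
}

#' Read and write GMT protein-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector parallel to `sets`.
#' @return `read_gmt()` returns a named list of member vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names in GMT", call. = FALSE)
  }
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write flat key=value configuration files
#'
#' Numeric-looking values are converted; `true`/`false` become logical.
#'
#' @param path File path.
#' @param config Named list.
#' @return `read_config()` returns a named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, function(p) trimws(p[[1]]), character(1)))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, as.character, character(1))), path)
  invisible(path)
}

#' Read and write a quantification matrix as TSV with sidecar metadata
#'
#' The matrix is written features-by-cells with a `feature` first column; a
#' `<path>.cells.tsv` and `<path>.features.tsv` carry the metadata.
#'
#' @param qm A [quant_matrix()].
#' @param path Matrix TSV path.
#' @return `read_quant_matrix()` returns a [quant_matrix()].
#' @export
write_quant_matrix <- function(qm, path) {
  mat <- tibble::as_tibble(qm$values, rownames = "feature")
  readr::write_tsv(mat, path, progress = FALSE)
  readr::write_tsv(qm$cells, paste0(path, ".cells.tsv"), progress = FALSE)
  readr::write_tsv(qm$features, paste0(path, ".features.tsv"),
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_quant_matrix
#' @export
read_quant_matrix <- function(path) {
  mat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  values <- as.matrix(mat[, -1])
  rownames(values) <- mat$feature
  cells <- readr::read_tsv(paste0(path, ".cells.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  cells$control <- as.logical(cells$control)
  features <- readr::read_tsv(paste0(path, ".features.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  quant_matrix(values, cells, features)
}
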