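#' Remove trypsin-consistent cleavage annotations
#'
#' Drops every protease-cleavage record whose P1 residue is lysine or
#' arginine: such cleavages are indistinguishable from tryptic digestion and
#' would add no searchable neo-termini. Records referencing proteins absent
#' from the sequence set, or whose annotated P1 residue disagrees with the
#' sequence, are dropped with a warning record.
#'
#' @param records Tibble of cleavage annotations with columns `protein_id`,
#'   `enzyme`, `p1_position` (1-based index of the P1 residue; the scissile
#'   bond lies between P1 and P1'), and optionally `p1_residue`.
#' @param proteins Named character vector (or `Biostrings::AAStringSet`) of
#'   protein sequences used for validation; `NULL` skips validation.
#' @return The filtered tibble, order preserved; dropped-record messages in
#'   the `warnings` attribute.
#' @export
filter_tryptic_cleavages <- function(records, proteins = NULL) {
  warns <- character(0)
  out <- records
  if (!is.null(proteins)) {
    seqs <- as_seq_vector(proteins)
    known <- out$protein_id %in% names(seqs)
    if (any(!known)) {
      warns <- c(warns, sprintf("dropped %d records for unknown proteins: %s",
                                sum(!known),
                                paste(unique(out$protein_id[!known]),
                                      collapse = ", ")))
      out <- out[known, , drop = FALSE]
    }
    at <- substr(seqs[out$protein_id], out$p1_position, out$p1_position)
    valid <- out$p1_position >= 1 &
      out$p1_position < nchar(seqs[out$protein_id])
    mismatch <- valid & !is.na(out$p1_residue) & at != out$p1_residue
    if (any(mismatch | !valid)) {
      warns <- c(warns, sprintf(
        "dropped %d records with out-of-range or mismatched P1 positions",
        sum(mismatch | !valid)))
      out <- out[valid & !mismatch, , drop = FALSE]
    }
    if (!"p1_residue" %in% names(out) || anyNA(out$p1_residue)) {
      out$p1_residue <- substr(seqs[out$protein_id], out$p1_position,
                               out$p1_position)
    }
  }
  keep <- !out$p1_residue %in% c("K", "R")
  out <- out[keep, , drop = FALSE]
  attr(out, "warnings") <- warns
  out
}

as_seq_vector <- function(x) {
  if (is.character(x)) x else as.character(x)  # AAStringSet keeps names
}

# 1-based positions after which trypsin cuts (K/R, optionally not before P)
tryptic_sites <- function(seq, block_proline = FALSE) {
  chars <- strsplit(seq, "")[[1]]
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < length(chars)]
  if (block_proline && length(sites)) {
    sites <- sites[chars[sites + 1] != "P"]
  }
  sites
}

#' Append semi-tryptic protease cleavage products to a FASTA database
#'
#' For each annotated cleavage site the protein sequence is split between the
#' P1 and P1' residues. Each half is digested in silico with trypsin and the
#' fragment abutting the cleavage site is kept: from the N-terminal half, the
#' peptide running from the residue after the last tryptic site up to the cut
#' (it carries the neo-C terminus); from the C-terminal half, the peptide
#' from the cut to the first tryptic site (neo-N terminus). Fragments shorter
#' than `min_len` residues are suppressed. The surviving fragments are
#' appended to the database as separate entries whose headers annotate the
#' enzyme, the cleavage residue number and which neo-terminus the fragment
#' carries; the original entries are preserved unchanged.
#'
#' @param fasta Named character vector or `Biostrings::AAStringSet` of
#'   protein sequences.
#' @param records Cleavage annotations that already passed
#'   [filter_tryptic_cleavages()].
#' @param min_len Minimum fragment length in residues (default 6).
#' @param block_proline If `TRUE`, tryptic sites followed by proline are not
#'   cut (trypsin rule vs. trypsin/P); default `FALSE` (plain digestion).
#' @return A list with `fragments` (tibble: `parent_protein_id`, `sequence`,
#'   `terminus_kind`, `cleavage_enzyme`, `cleavage_position`, `header`) and
#'   `fasta` (a `Biostrings::AAStringSet` of originals plus appended
#'   fragments).
#' @export
#' @examples
#' prot <- c(P1 = "MSSSSKAAAAAALGGGGGGKEEEE")
#' cl <- tibble::tibble(protein_id = "P1", enzyme = "CatL", p1_position = 13)
#' augment_fasta(prot, cl)$fragments$sequence
augment_fasta <- function(fasta, records, min_len = 6,
                          block_proline = FALSE) {
  seqs <- as_seq_vector(fasta)
  if (is.null(names(seqs)) || anyNA(names(seqs))) {
    stop("fasta sequences must be named", call. = FALSE)
  }
  frag_rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    pid <- records$protein_id[i]
    seq <- seqs[[pid]]
    pos <- records$p1_position[i]
    enzyme <- records$enzyme[i]
    n_half <- substr(seq, 1, pos)
    c_half <- substr(seq, pos + 1, nchar(seq))

    frs <- list()
    sites_n <- tryptic_sites(n_half, block_proline)
    start_n <- if (length(sites_n)) max(sites_n) + 1L else 1L
    neo_c <- substr(n_half, start_n, pos)
    if (nchar(neo_c) >= min_len) {
      frs <- c(frs, list(data.frame(sequence = neo_c,
                                    terminus_kind = "neo_C")))
    }
    if (nchar(c_half) > 0) {
      sites_c <- tryptic_sites(c_half, block_proline)
      end_c <- if (length(sites_c)) min(sites_c) else nchar(c_half)
      neo_n <- substr(c_half, 1, end_c)
      if (nchar(neo_n) >= min_len) {
        frs <- c(frs, list(data.frame(sequence = neo_n,
                                      terminus_kind = "neo_N")))
      }
    }
    if (length(frs)) {
      fr <- do.call(rbind, frs)
      fr$parent_protein_id <- pid
      fr$cleavage_enzyme <- enzyme
      fr$cleavage_position <- pos
      frag_rows[[i]] <- fr
    }
  }
  fragments <- dplyr::bind_rows(frag_rows)
  if (nrow(fragments) == 0) {
    fragments <- tibble::tibble(
      parent_protein_id = character(0), sequence = character(0),
      terminus_kind = character(0), cleavage_enzyme = character(0),
      cleavage_position = integer(0), header = character(0))
  } else {
    fragments <- tibble::as_tibble(fragments)[
      , c("parent_protein_id", "sequence", "terminus_kind",
          "cleavage_enzyme", "cleavage_position")]
    fragments$header <- sprintf("%s|MEROPS|%s|pos%d|%s",
                                fragments$parent_protein_id,
                                fragments$cleavage_enzyme,
                                fragments$cleavage_position,
                                fragments$terminus_kind)
  }
  combined <- c(seqs, stats::setNames(fragments$sequence, fragments$header))
  list(fragments = fragments, fasta = Biostrings::AAStringSet(combined))
}

#' Read and write protein FASTA
#'
#' Thin wrappers over `Biostrings` keeping the rest of the package free of
#' format details.
#'
#' @param path File path.
#' @param x An `AAStringSet` or named character vector.
#' @return `read_fasta()` returns an `AAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readAAStringSet(path)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "AAStringSet")) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
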