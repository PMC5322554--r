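# Codon-aware alignment: back-threading a protein alignment onto coding
# sequences, occupancy-based column filtering, and the paralog-vs-ortholog
# rate contrast.

#' Thread coding sequences onto a protein alignment
#'
#' Each aligned amino-acid column maps to one codon column of the
#' corresponding CDS; protein gaps become whole-codon gaps (`---`). Each
#' protein row must translate exactly from its CDS (a trailing stop codon
#' on the CDS is trimmed).
#'
#' @param protein_alignment Named character vector of aligned protein rows
#'   (equal lengths, gaps as `-`).
#' @param cds_by_id Named character vector of coding sequences for every
#'   row id.
#' @return Named character vector of aligned CDS rows (class
#'   `"codon_alignment"`); all rows equal length, divisible by 3, gaps only
#'   in whole-codon units.
#' @export
thread_codon_alignment <- function(protein_alignment, cds_by_id) {
  stopifnot(!is.null(names(protein_alignment)))
  if (length(unique(nchar(protein_alignment))) != 1) {
    stop("protein alignment rows differ in length", call. = FALSE)
  }
  out <- vapply(names(protein_alignment), function(id) {
    row <- protein_alignment[[id]]
    cds <- cds_by_id[[id]]
    if (is.null(cds) || is.na(cds)) {
      stop("no CDS for aligned sequence '", id, "'", call. = FALSE)
    }
    if (nchar(cds) %% 3 != 0) {
      stop("CDS length of '", id, "' not divisible by 3", call. = FALSE)
    }
    codons <- split_codons(cds)
    aa <- genetic_code()[codons]
    if (length(aa) > 0 && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    res <- strsplit(row, "")[[1]]
    ungapped <- res[res != "-"]
    if (length(ungapped) != length(aa)) {
      stop("translation mismatch for '", id, "': protein row has ",
           length(ungapped), " residues, CDS encodes ", length(aa),
           call. = FALSE)
    }
    bad <- which(ungapped != aa)
    if (length(bad) > 0) {
      stop("translation mismatch for '", id, "' at residue ", bad[1],
           ": protein '", ungapped[bad[1]], "' vs CDS-encoded '",
           aa[bad[1]], "'", call. = FALSE)
    }
    pieces <- character(length(res))
    j <- 0L
    for (k in seq_along(res)) {
      if (res[k] == "-") {
        pieces[k] <- "---"
      } else {
        j <- j + 1L
        pieces[k] <- codons[j]
      }
    }
    paste(pieces, collapse = "")
  }, character(1))
  structure(out, class = "codon_alignment")
}

#' Filter codon alignment columns by occupancy
#'
#' Removes codon columns in which the fraction of non-gap rows is below
#' `min_occupancy` (a column exactly at the threshold is kept). Column
#' order is preserved.
#'
#' @param aln A codon alignment (named character vector, from
#'   [thread_codon_alignment()]).
#' @param min_occupancy Minimum fraction of non-gap rows, default 0.6.
#' @return The filtered codon alignment.
#' @export
filter_columns <- function(aln, min_occupancy = 0.6) {
  rows <- lapply(aln, split_codons)
  n_col <- length(rows[[1]])
  stopifnot(all(lengths(rows) == n_col))
  occ <- vapply(seq_len(n_col), function(j) {
    mean(vapply(rows, function(r) r[j] != "---", logical(1)))
  }, numeric(1))
  keep <- occ >= min_occupancy
  if (!any(keep)) {
    stop("filter_columns: all columns removed at occupancy ",
         min_occupancy, call. = FALSE)
  }
  out <- vapply(rows, function(r) paste(r[keep], collapse = ""), character(1))
  structure(stats::setNames(out, names(aln)), class = "codon_alignment")
}

# Global protein alignment of two CDS, threaded back to codons.
align_codon_pair <- function(cds_a, cds_b, scheme = scoring_scheme(),
                             ids = c("a", "b")) {
  prot <- vapply(c(cds_a, cds_b), function(cds) {
    p <- translate_cds(cds)
    sub("\\*$", "", p)
  }, character(1))
  if (grepl("\\*", prot[1]) || grepl("\\*", prot[2])) {
    stop("align_codon_pair: internal stop codon", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot[1]), Biostrings::AAString(prot[2]),
    type = "global", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  aln <- stats::setNames(c(as.character(Biostrings::alignedPattern(pa)),
                           as.character(Biostrings::alignedSubject(pa))), ids)
  thread_codon_alignment(aln, stats::setNames(c(cds_a, cds_b), ids))
}

#' Contrast evolutionary rates of two paralogs against a reference ortholog
#'
#' Computes pairwise NG86 estimates of the reference CDS against each
#' paralog (protein-level global alignment threaded back to codons) and
#' reports which paralog is more diverged. A saturated estimate counts as
#' more diverged than any finite one.
#'
#' @param reference_cds,paralog1_cds,paralog2_cds Coding sequences.
#' @param scheme [scoring_scheme()] for the protein alignments.
#' @return List with `paralog1`, `paralog2` (both [ng86_pairwise()]
#'   estimates) and `more_diverged` (`"paralog1"`, `"paralog2"` or
#'   `"tie"`).
#' @export
paralog_rate_contrast <- function(reference_cds, paralog1_cds, paralog2_cds,
                                  scheme = scoring_scheme()) {
  est <- lapply(list(paralog1_cds, paralog2_cds), function(cds) {
    aln <- align_codon_pair(reference_cds, cds, scheme)
    ng86_pairwise(aln[[1]], aln[[2]])
  })
  div <- vapply(est, function(e) {
    if (is.na(e$dS)) Inf else e$dS
  }, numeric(1))
  more <- if (div[1] > div[2]) "paralog1" else
    if (div[2] > div[1]) "paralog2" else "tie"
  list(paralog1 = est[[1]], paralog2 = est[[2]], more_diverged = more)
}
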