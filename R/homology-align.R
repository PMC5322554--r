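# Desk-scale protein similarity search: optimal Smith-Waterman local
# alignment with affine gaps (engine: Biostrings::pairwiseAlignment) and
# Karlin-Altschul E-values. E-values from the ungapped formula with
# gapped-default BLOSUM62 parameters are approximate by design; all
# downstream logic relies on relative contrasts, never on absolute
# agreement with NCBI BLAST.

#' Construct a protein scoring scheme
#'
#' Bundles a symmetric substitution matrix, affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`) and Karlin-Altschul
#' parameters used to convert raw scores to E-values. Defaults follow
#' BLOSUM62 with BLAST's gapped parameters (lambda = 0.267, K = 0.041).
#'
#' @param matrix Substitution matrix name (`"BLOSUM62"`) or a symmetric
#'   numeric matrix with amino-acid dimnames.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param lambda,k Karlin-Altschul parameters, both > 0.
#' @return List of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1,
                           lambda = 0.267, k = 0.041) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  if (!isTRUE(all.equal(matrix, t(matrix)))) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, k > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, k = k),
            class = "scoring_scheme")
}

count_gap_opens <- function(aligned) {
  sum(vapply(gregexpr("-+", aligned), function(g) sum(g > 0), numeric(1)))
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gaps under the given scoring
#' scheme. When every residue pairing scores negative, the optimal local
#' alignment is empty and the score is 0.
#'
#' @param query,subject Non-empty amino-acid strings.
#' @param scheme A [scoring_scheme()].
#' @return List with `score`, `q_start`, `q_end`, `s_start`, `s_end`
#'   (1-based inclusive aligned spans; 0-length spans when score is 0),
#'   `aln_length`, `n_match`, `n_mismatch`, `gap_opens` and `pct_identity`.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme()) {
  if (!nzchar(query) || !nzchar(subject)) {
    stop("local_align: sequences must be non-empty", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(score = 0, q_start = 0L, q_end = -1L, s_start = 0L,
                s_end = -1L, aln_length = 0L, n_match = 0L, n_mismatch = 0L,
                gap_opens = 0L, pct_identity = NA_real_))
  }
  p_aln <- as.character(Biostrings::alignedPattern(pa))
  s_aln <- as.character(Biostrings::alignedSubject(pa))
  aln_len <- nchar(p_aln)
  nm <- Biostrings::nmatch(pa)
  list(
    score = sc,
    q_start = Biostrings::start(Biostrings::pattern(pa)),
    q_end = Biostrings::end(Biostrings::pattern(pa)),
    s_start = Biostrings::start(Biostrings::subject(pa)),
    s_end = Biostrings::end(Biostrings::subject(pa)),
    aln_length = aln_len,
    n_match = nm,
    n_mismatch = Biostrings::nmismatch(pa),
    gap_opens = as.integer(count_gap_opens(p_aln) + count_gap_opens(s_aln)),
    pct_identity = 100 * nm / aln_len
  )
}

#' Karlin-Altschul E-value for a raw alignment score
#'
#' `E = k * m * n * exp(-lambda * score)`: the expected number of chance
#' local alignments at least as good, for query length m against a database
#' of n residues. Monotonically decreasing in the score and linear in both
#' lengths.
#'
#' @param raw_score Raw alignment score, >= 0.
#' @param query_len Query length in residues.
#' @param db_len Total database length in residues.
#' @param scheme A [scoring_scheme()] supplying lambda and K.
#' @return The E-value (non-negative numeric).
#' @export
evalue <- function(raw_score, query_len, db_len, scheme = scoring_scheme()) {
  stopifnot(raw_score >= 0, query_len > 0, db_len > 0)
  scheme$k * query_len * db_len * exp(-scheme$lambda * raw_score)
}

bit_score <- function(raw_score, scheme) {
  (scheme$lambda * raw_score - log(scheme$k)) / log(2)
}

as_seq_vec <- function(x) {
  if (is.data.frame(x)) stats::setNames(x$residues, x$id)
  else if (is.character(x) && !is.null(names(x))) x
  else stop("expected a read_fasta() data frame or a named character vector",
            call. = FALSE)
}

#' All-vs-all protein similarity search
#'
#' Aligns every query against every subject and reports pairs whose E-value
#' falls below `e_max` as a BLAST-tabular hit table, sorted by query id and
#' ascending E-value. Pairs of identical ids (self hits) are never reported.
#'
#' @param queries,subjects Named character vectors of protein sequences, or
#'   [read_fasta()] data frames.
#' @param scheme A [scoring_scheme()].
#' @param e_max E-value cutoff; hits with `E < e_max` are reported. Use
#'   `Inf` to report all pairs.
#' @return Hit table data frame (see [read_hit_table()] for columns).
#' @export
search <- function(queries, subjects, scheme = scoring_scheme(),
                   e_max = 1e-10) {
  queries <- as_seq_vec(queries)
  subjects <- as_seq_vec(subjects)
  if (length(queries) == 0 || length(subjects) == 0) {
    stop("search: empty sequence set", call. = FALSE)
  }
  db_len <- sum(nchar(subjects))
  qset <- Biostrings::AAStringSet(queries)
  rows <- list()
  for (j in seq_along(subjects)) {
    scores <- Biostrings::pairwiseAlignment(
      qset, Biostrings::AAString(subjects[[j]]), type = "local",
      substitutionMatrix = scheme$matrix, gapOpening = scheme$gap_open,
      gapExtension = scheme$gap_extend, scoreOnly = TRUE)
    scores <- pmax(scores, 0)
    evs <- evalue(scores, nchar(queries), db_len, scheme)
    keep <- which(evs < e_max & names(queries) != names(subjects)[j])
    for (i in keep) {
      al <- local_align(queries[[i]], subjects[[j]], scheme)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = names(queries)[i], subject_id = names(subjects)[j],
        pct_identity = al$pct_identity, aln_length = al$aln_length,
        mismatches = al$n_mismatch, gap_opens = al$gap_opens,
        q_start = al$q_start, q_end = al$q_end,
        s_start = al$s_start, s_end = al$s_end,
        e_value = evs[i], bit_score = bit_score(al$score, scheme),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_hit_table())
  out <- do.call(rbind, rows)
  out <- out[order(out$query_id, out$e_value, -out$bit_score, out$subject_id), ]
  rownames(out) <- NULL
  out
}
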