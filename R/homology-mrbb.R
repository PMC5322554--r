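# Modified reciprocal-best-BLAST (MRBB) ortholog calling over hit tables.
#
# Strict reciprocal best hit (RBH) keeps only mutual best pairs and thus
# forces 1:1 calls. The "modified" rule implemented here relaxes this so
# genes with several homologs in the other species can still receive calls:
# a pair (a, b) is emitted when hits exist in both directions below the
# E-value cutoff and EITHER b is a's best forward hit OR a is b's best
# reverse hit. Every strict RBH pair satisfies both conditions, so strict
# output is always a subset of modified output.
#
# "Best" means most significant: ascending E-value, ties broken by
# descending bit score, then lexicographic subject id, so results are
# deterministic and invariant under permutation of hit-table rows.

best_subject_per_query <- function(hits) {
  if (nrow(hits) == 0) return(character(0))
  o <- order(hits$query_id, hits$e_value, -hits$bit_score, hits$subject_id)
  h <- hits[o, ]
  first <- !duplicated(h$query_id)
  stats::setNames(h$subject_id[first], h$query_id[first])
}

#' Call orthologs by modified reciprocal best BLAST
#'
#' Takes the two directional hit tables between species A and B (queries of
#' `hits_ab` are A genes, subjects are B genes; vice versa for `hits_ba`),
#' applies the E-value cutoff to both, and emits ortholog pairs under the
#' modified or strict reciprocal-best rule. Many-to-one calls are permitted
#' in modified mode. Output is deduplicated and sorted.
#'
#' @param hits_ab,hits_ba Hit tables (see [read_hit_table()]) for the two
#'   search directions. The A and B gene id spaces must be disjoint; a table
#'   containing within-species pairs is rejected.
#' @param mode `"modified"` (either-direction best, the default) or
#'   `"strict"` (plain reciprocal best hit).
#' @param e_max E-value cutoff applied to both tables before calling.
#' @return Data frame with columns `gene_a`, `gene_b`, `e_ab`, `e_ba` and
#'   `source = "mrbb"`.
#' @export
mrbb <- function(hits_ab, hits_ba, mode = c("modified", "strict"),
                 e_max = 1e-10) {
  mode <- match.arg(mode)
  genes_a <- union(hits_ab$query_id, hits_ba$subject_id)
  genes_b <- union(hits_ab$subject_id, hits_ba$query_id)
  if (length(intersect(genes_a, genes_b)) > 0) {
    stop("mrbb: hit tables contain within-species pairs (gene id spaces ",
         "of the two species overlap)", call. = FALSE)
  }
  ab <- hits_ab[hits_ab$e_value < e_max, , drop = FALSE]
  ba <- hits_ba[hits_ba$e_value < e_max, , drop = FALSE]
  if (nrow(ab) == 0 || nrow(ba) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      e_ab = numeric(), e_ba = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  }
  best_fwd <- best_subject_per_query(ab)  # a -> its best b
  best_rev <- best_subject_per_query(ba)  # b -> its best a
  # candidate pairs: hits present in both directions
  key_ab <- paste(ab$query_id, ab$subject_id, sep = "\r")
  key_ba <- paste(ba$subject_id, ba$query_id, sep = "\r")
  both <- intersect(key_ab, key_ba)
  if (length(both) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      e_ab = numeric(), e_ba = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(both, "\r", fixed = TRUE)
  a <- vapply(parts, `[`, character(1), 1)
  b <- vapply(parts, `[`, character(1), 2)
  fwd_best <- !is.na(best_fwd[a]) & best_fwd[a] == b
  rev_best <- !is.na(best_rev[b]) & best_rev[b] == a
  keep <- if (mode == "modified") fwd_best | rev_best else fwd_best & rev_best
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      e_ab = numeric(), e_ba = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  }
  e_ab_min <- tapply(ab$e_value, paste(ab$query_id, ab$subject_id, sep = "\r"), min)
  e_ba_min <- tapply(ba$e_value, paste(ba$query_id, ba$subject_id, sep = "\r"), min)
  out <- data.frame(
    gene_a = a, gene_b = b,
    e_ab = as.numeric(e_ab_min[paste(a, b, sep = "\r")]),
    e_ba = as.numeric(e_ba_min[paste(b, a, sep = "\r")]),
    source = "mrbb", stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  out
}
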