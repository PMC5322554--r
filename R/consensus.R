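# Two-of-three consensus ortholog calling: MRBB plus two external database
# call tables (e.g. OrthoDB- and eggNOG-style TSVs), combined per ensemble
# gene. A consensus ortholog requires at least `min_support` methods naming
# the SAME target gene; genes where two methods each name a different
# ortholog get a disagreement flag and no consensus.

.METHODS <- c("mrbb", "db1", "db2")

#' Build an evidence matrix from three per-method call tables
#'
#' @param genes Character vector of ensemble gene ids (reference species).
#' @param mrbb,db1,db2 Two-column data frames (`gene`, `ortholog`) of
#'   per-method calls; genes absent from a table have no call from that
#'   method. An MRBB pair table (`gene_a`, `gene_b`) is also accepted.
#' @param extra Optional data frame of per-gene annotation columns (e.g.
#'   `functional_class`) carried through to the consensus catalog; must have
#'   a `gene` column.
#' @return Data frame with one row per ensemble gene and columns `gene`,
#'   `mrbb`, `db1`, `db2` (called ortholog id or `NA`), plus any extras.
#' @export
evidence_matrix <- function(genes, mrbb = NULL, db1 = NULL, db2 = NULL,
                            extra = NULL) {
  norm <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) {
      return(stats::setNames(character(0), character(0)))
    }
    if (all(c("gene_a", "gene_b") %in% names(tab))) {
      tab <- data.frame(gene = tab$gene_a, ortholog = tab$gene_b,
                        stringsAsFactors = FALSE)
    }
    stopifnot(all(c("gene", "ortholog") %in% names(tab)))
    tab <- tab[!duplicated(tab$gene), ]  # first call per gene
    stats::setNames(tab$ortholog, tab$gene)
  }
  calls <- lapply(list(mrbb = mrbb, db1 = db1, db2 = db2), norm)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (m in .METHODS) {
    out[[m]] <- unname(calls[[m]][genes])
  }
  if (!is.null(extra)) {
    stopifnot("gene" %in% names(extra))
    out <- merge(out, extra, by = "gene", all.x = TRUE, sort = FALSE)
    out <- out[match(genes, out$gene), ]
  }
  rownames(out) <- NULL
  out
}

#' Call consensus orthologs under the 2-of-3 rule
#'
#' For each ensemble gene, `support_count` is the number of methods calling
#' any ortholog. A consensus ortholog is assigned iff at least `min_support`
#' methods name the same target id (set `require_agreement = FALSE` to relax
#' agreement to presence-only support, in which case the most-named id
#' wins). Genes with enough supporting methods but no agreeing id receive a
#' disagreement flag and no consensus; genes with several ids tied at the
#' required support are flagged ambiguous and all candidates are kept.
#'
#' @param evidence Data frame from [evidence_matrix()]: columns `gene`,
#'   `mrbb`, `db1`, `db2` and optional annotation columns.
#' @param min_support Required number of supporting methods (1, 2 or 3).
#' @param require_agreement Require `min_support` methods to name the same
#'   ortholog id (the default), not merely to make a call.
#' @return A consensus catalog: data frame with columns `gene`,
#'   `support_count`, `consensus_ortholog` (`NA` when none), `agreement`
#'   (did supporting methods name the same id), `ambiguous`, `candidates`
#'   (semicolon-joined tied ids), plus any annotation columns carried over.
#' @export
call_consensus <- function(evidence, min_support = 2,
                           require_agreement = TRUE) {
  if (!min_support %in% c(1, 2, 3)) {
    stop("min_support must be 1, 2 or 3", call. = FALSE)
  }
  stopifnot(all(c("gene", .METHODS) %in% names(evidence)))
  n <- nrow(evidence)
  support <- integer(n)
  consensus <- rep(NA_character_, n)
  agreement <- rep(NA, n)
  ambiguous <- logical(n)
  candidates <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    calls <- unlist(evidence[i, .METHODS], use.names = FALSE)
    calls <- calls[!is.na(calls)]
    support[i] <- length(calls)
    if (length(calls) == 0) next
    tab <- sort(table(calls), decreasing = TRUE)
    if (require_agreement) {
      top <- tab[tab >= min_support]
    } else {
      top <- if (length(calls) >= min_support) tab[1] else tab[0]
    }
    if (length(top) == 1) {
      consensus[i] <- names(top)
      agreement[i] <- max(tab) >= 2
    } else if (length(top) > 1) {
      ambiguous[i] <- TRUE
      candidates[i] <- paste(sort(names(top)), collapse = ";")
      agreement[i] <- TRUE
    } else {
      agreement[i] <- FALSE
    }
  }
  out <- data.frame(gene = evidence$gene, support_count = support,
                    consensus_ortholog = consensus, agreement = agreement,
                    ambiguous = ambiguous, candidates = candidates,
                    stringsAsFactors = FALSE)
  extra_cols <- setdiff(names(evidence), c("gene", .METHODS))
  for (cc in extra_cols) out[[cc]] <- evidence[[cc]]
  class(out) <- c("consensus_catalog", class(out))
  out
}

#' Support-level distribution of a consensus catalog
#'
#' @param catalog A catalog from [call_consensus()].
#' @return Named integer vector with counts at support levels `"3"`, `"2"`,
#'   `"1"`, `"0"`; sums to the ensemble size.
#' @export
support_distribution <- function(catalog) {
  stopifnot("support_count" %in% names(catalog))
  vapply(c("3", "2", "1", "0"), function(s) {
    sum(catalog$support_count == as.integer(s))
  }, integer(1))
}

#' Per-functional-class ortholog accounting
#'
#' Tallies, per functional class, the reference-species ensemble size and
#' the number of genes receiving a consensus ortholog, with grand totals.
#'
#' @param catalog A catalog from [call_consensus()] whose rows carry a
#'   `functional_class` column.
#' @param ensemble_catalog Data frame with columns `functional_class` and
#'   `n_reference` (ensemble membership per class in the reference species).
#' @return Data frame with columns `functional_class`, `n_reference`,
#'   `n_with_consensus`; grand totals in attribute `"totals"`.
#' @export
class_accounting <- function(catalog, ensemble_catalog) {
  stopifnot("functional_class" %in% names(catalog),
            all(c("functional_class", "n_reference") %in% names(ensemble_catalog)))
  unknown <- setdiff(catalog$functional_class, ensemble_catalog$functional_class)
  if (length(unknown) > 0 || anyNA(catalog$functional_class)) {
    stop("class_accounting: gene with unknown functional class: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  called <- !is.na(catalog$consensus_ortholog)
  n_cons <- vapply(ensemble_catalog$functional_class, function(cl) {
    sum(called & catalog$functional_class == cl)
  }, integer(1))
  out <- data.frame(functional_class = ensemble_catalog$functional_class,
                    n_reference = ensemble_catalog$n_reference,
                    n_with_consensus = unname(n_cons),
                    stringsAsFactors = FALSE)
  attr(out, "totals") <- c(n_reference = sum(out$n_reference),
                           n_with_consensus = sum(out$n_with_consensus))
  out
}

#' Ensemble conservation rate
#'
#' Percentage of ensemble genes receiving a consensus ortholog.
#'
#' @param catalog A catalog from [call_consensus()].
#' @return List with `percent` (full precision) and `percent_rounded`
#'   (nearest integer).
#' @export
conservation_rate <- function(catalog) {
  if (nrow(catalog) == 0) stop("conservation_rate: empty catalog", call. = FALSE)
  pct <- 100 * sum(!is.na(catalog$consensus_ortholog)) / nrow(catalog)
  list(percent = pct, percent_rounded = round(pct))
}
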