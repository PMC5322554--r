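# Gene-family copy-number dynamics across species: copy-number tabulation,
# the unplaced-contig (UNKN) artifact filter, expansion/contraction event
# calling relative to a reference species, per-species 1:1 conservation
# statistics and retrocopy detection from exon structure.

#' Construct a copy-number table
#'
#' @param copies Integer matrix, families in rows, species in columns.
#' @param reference Reference species (must be a column).
#' @param genes Optional nested list `genes[[family]][[species]]` of the
#'   gene ids behind each count (needed by [filter_unkn()]).
#' @return List of class `"copy_table"` with elements `copies`, `reference`,
#'   `genes`.
#' @export
copy_number_table <- function(copies, reference, genes = NULL) {
  stopifnot(is.matrix(copies), !is.null(rownames(copies)),
            !is.null(colnames(copies)))
  if (!reference %in% colnames(copies)) {
    stop("reference species '", reference, "' absent from table", call. = FALSE)
  }
  if (any(copies < 0)) stop("copy counts must be non-negative", call. = FALSE)
  structure(list(copies = copies, reference = reference, genes = genes),
            class = "copy_table")
}

#' @export
print.copy_table <- function(x, ...) {
  cat("Copy-number table:", nrow(x$copies), "families x",
      ncol(x$copies), "species (reference:", x$reference, ")\n")
  print(x$copies)
  invisible(x)
}

#' Build a copy-number table from per-species family catalogs
#'
#' @param per_species_catalogs Named list (one element per species) of data
#'   frames with columns `family` and `gene_id`; each row is one gene copy.
#' @param reference Reference species name (must be in the list).
#' @return A [copy_number_table()]; families missing from a species count 0.
#' @export
build_copy_table <- function(per_species_catalogs, reference) {
  if (!reference %in% names(per_species_catalogs)) {
    stop("reference species '", reference, "' absent from catalogs",
         call. = FALSE)
  }
  species <- names(per_species_catalogs)
  families <- sort(unique(unlist(lapply(per_species_catalogs, `[[`, "family"))))
  copies <- matrix(0L, nrow = length(families), ncol = length(species),
                   dimnames = list(families, species))
  genes <- lapply(families, function(f) {
    stats::setNames(lapply(species, function(s) {
      cat_s <- per_species_catalogs[[s]]
      cat_s$gene_id[cat_s$family == f]
    }), species)
  })
  names(genes) <- families
  for (s in species) {
    tab <- table(per_species_catalogs[[s]]$family)
    copies[names(tab), s] <- as.integer(tab)
  }
  copy_number_table(copies, reference, genes)
}

#' Exclude apparent expansions on the unplaced (UNKN) chromosome
#'
#' Gene copies above the reference-species count whose gene model sits on
#' chromosome `"UNKN"` may be assembly artifacts rather than real
#' expansions; they are removed from the counts, and the affected families
#' are logged.
#'
#' @param table A [copy_number_table()] carrying gene-level info.
#' @param gene_models Named list of gene models (see
#'   [read_gff3_gene_models()]) covering all counted genes.
#' @return List with `table` (the filtered [copy_number_table()]) and
#'   `removed` (data frame `family`, `species`, `gene_id` of excluded
#'   copies).
#' @export
filter_unkn <- function(table, gene_models) {
  stopifnot(inherits(table, "copy_table"))
  if (is.null(table$genes)) {
    stop("filter_unkn: table lacks gene-level information", call. = FALSE)
  }
  copies <- table$copies
  genes <- table$genes
  ref <- table$reference
  removed <- list()
  for (f in rownames(copies)) {
    for (s in colnames(copies)) {
      excess <- copies[f, s] - copies[f, ref]
      if (s == ref || excess <= 0) next
      ids <- genes[[f]][[s]]
      chroms <- gene_model_field(gene_models, ids, "chromosome")
      unkn <- ids[chroms == "UNKN"]
      drop <- utils::head(unkn, excess)
      if (length(drop) > 0) {
        copies[f, s] <- copies[f, s] - length(drop)
        genes[[f]][[s]] <- setdiff(ids, drop)
        removed[[length(removed) + 1L]] <- data.frame(
          family = f, species = s, gene_id = drop, stringsAsFactors = FALSE)
      }
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(family = character(), species = character(),
               gene_id = character(), stringsAsFactors = FALSE)
  list(table = copy_number_table(copies, ref, genes), removed = removed)
}

#' Detect gene-family expansion/contraction events
#'
#' Emits one event per (family, species) whose copy count differs from the
#' reference species, and classifies each family by its dominant direction
#' across species (ties flagged).
#'
#' @param table A (filtered) [copy_number_table()].
#' @return List with `events` (data frame `family`, `species`, `direction`,
#'   `delta`), `family_summary` (data frame `family`, `direction`,
#'   `n_species_up`, `n_species_down`, `tie`), and counts `n_event_families`,
#'   `n_expansion_families`, `n_contraction_families`.
#' @export
detect_events <- function(table) {
  stopifnot(inherits(table, "copy_table"))
  copies <- table$copies
  ref <- table$reference
  events <- list()
  fam_rows <- list()
  for (f in rownames(copies)) {
    deltas <- copies[f, ] - copies[f, ref]
    deltas <- deltas[names(deltas) != ref]
    hit <- deltas[deltas != 0]
    if (length(hit) > 0) {
      events[[length(events) + 1L]] <- data.frame(
        family = f, species = names(hit),
        direction = ifelse(hit > 0, "expansion", "contraction"),
        delta = as.integer(hit), stringsAsFactors = FALSE)
    }
    n_up <- sum(deltas > 0)
    n_down <- sum(deltas < 0)
    if (n_up + n_down > 0) {
      fam_rows[[length(fam_rows) + 1L]] <- data.frame(
        family = f,
        direction = if (n_up > n_down) "expansion" else
          if (n_down > n_up) "contraction" else "tie",
        n_species_up = n_up, n_species_down = n_down,
        tie = n_up == n_down, stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(family = character(), species = character(),
               direction = character(), delta = integer(),
               stringsAsFactors = FALSE)
  rownames(events) <- NULL
  fam <- if (length(fam_rows)) do.call(rbind, fam_rows) else
    data.frame(family = character(), direction = character(),
               n_species_up = integer(), n_species_down = integer(),
               tie = logical(), stringsAsFactors = FALSE)
  rownames(fam) <- NULL
  list(events = events, family_summary = fam,
       n_event_families = nrow(fam),
       n_expansion_families = sum(fam$direction == "expansion"),
       n_contraction_families = sum(fam$direction == "contraction"))
}

#' Per-species 1:1 copy-number conservation statistics
#'
#' For each non-reference species s, conservation is
#' `100 * (F - d(s)) / F` where `F` is the number of ensemble families and
#' `d(s)` the number of families whose copy count differs from the
#' reference. Families absent from the table are 1:1 by definition.
#'
#' @param table A [copy_number_table()].
#' @param n_ensemble_families Total ensemble family count `F` (at least the
#'   number of rows in the table).
#' @return List of class `"conservation_summary"` with `per_species_pct`
#'   (named numeric), `min_pct`, `mean_pct`, `n_families`.
#' @export
conservation_stats <- function(table, n_ensemble_families) {
  stopifnot(inherits(table, "copy_table"))
  copies <- table$copies
  ref <- table$reference
  others <- setdiff(colnames(copies), ref)
  d <- vapply(others, function(s) sum(copies[, s] != copies[, ref]),
              numeric(1))
  if (n_ensemble_families < nrow(copies) || any(d > n_ensemble_families)) {
    stop("n_ensemble_families smaller than the number of differing families",
         call. = FALSE)
  }
  pct <- 100 * (n_ensemble_families - d) / n_ensemble_families
  structure(list(per_species_pct = pct, min_pct = min(pct),
                 mean_pct = mean(pct), n_families = n_ensemble_families),
            class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat("1:1 copy-number conservation over", x$n_families, "families\n")
  print(round(x$per_species_pct, 1))
  cat(sprintf("min %.1f%%, mean %.1f%%\n", x$min_pct, x$mean_pct))
  invisible(x)
}

#' Detect retrocopies among paralog pairs
#'
#' A paralog pair is flagged as a retrotransposition event when one gene is
#' intronless (exactly 1 exon), the other has >= 2 exons, and the protein
#' identity over the locally aligned region is at least `min_identity`. The
#' single-exon member is labelled the retrocopy.
#'
#' @param paralog_pairs Data frame with columns `gene_a`, `gene_b`.
#' @param gene_models Named list of gene models covering both genes of each
#'   pair (see [read_gff3_gene_models()]).
#' @param proteins Named character vector of protein sequences.
#' @param min_identity Minimum aligned-region protein identity (0-1 scale).
#' @param scheme [scoring_scheme()] used for the identity alignment.
#' @return Data frame with columns `parent`, `retrocopy`, `identity`.
#' @export
detect_retrocopies <- function(paralog_pairs, gene_models, proteins,
                               min_identity = 0.5,
                               scheme = scoring_scheme()) {
  out <- list()
  for (i in seq_len(nrow(paralog_pairs))) {
    a <- paralog_pairs$gene_a[i]
    b <- paralog_pairs$gene_b[i]
    na_ <- gene_model_field(gene_models, a, "n_exons")
    nb_ <- gene_model_field(gene_models, b, "n_exons")
    single <- c(a, b)[c(na_, nb_) == 1L]
    multi <- c(a, b)[c(na_, nb_) >= 2L]
    if (length(single) != 1 || length(multi) != 1) next
    if (!single %in% names(proteins) || !multi %in% names(proteins)) {
      stop("detect_retrocopies: missing protein sequence", call. = FALSE)
    }
    al <- local_align(proteins[[single]], proteins[[multi]], scheme)
    ident <- if (al$aln_length > 0) al$n_match / al$aln_length else 0
    if (ident >= min_identity) {
      out[[length(out) + 1L]] <- data.frame(
        parent = multi, retrocopy = single, identity = ident,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(parent = character(), retrocopy = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
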