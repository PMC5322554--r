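# GFF3 gene-model reading (gene/mRNA/exon features) and the simulator's
# GFF3 writer. Coordinates are 1-based inclusive throughout, matching the
# GFF3 standard; the chromosome field is taken verbatim from column 1 so
# unplaced-contig labels such as "UNKN" survive.

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon features into per-gene exon structures. One mRNA per
#' gene is expected; when a gene carries several mRNAs the first is used and a
#' warning is logged. Exons of a transcript must not overlap.
#'
#' @param path Path to a GFF3 file.
#' @param species Optional species label stored on every gene model.
#' @return A named list of gene models. Each model is a list with elements
#'   `gene_id`, `species`, `chromosome`, `strand`, `exons` (two-column matrix
#'   of sorted `start`/`end` pairs, 1-based inclusive) and `cds_length`.
#' @export
read_gff3_gene_models <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("GFF3 file does not exist: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (!all(c("type", "ID") %in% names(df))) {
    stop("GFF3 format error: features must carry ID attributes", call. = FALSE)
  }
  parent_of <- function(row) {
    p <- df$Parent[[row]]
    if (length(p) == 0) NA_character_ else as.character(p)[1]
  }
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  if (nrow(genes) == 0) stop("GFF3 format error: no gene features in ", path, call. = FALSE)
  mrna_parent <- vapply(which(df$type == "mRNA"), parent_of, character(1))
  exon_parent <- vapply(which(df$type == "exon"), parent_of, character(1))
  if (anyNA(mrna_parent) || anyNA(exon_parent)) {
    stop("GFF3 format error: mRNA/exon features without Parent", call. = FALSE)
  }
  models <- vector("list", nrow(genes))
  names(models) <- genes$ID
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    midx <- which(mrna_parent == gid)
    if (length(midx) == 0) {
      stop("GFF3 format error: gene '", gid, "' has no mRNA", call. = FALSE)
    }
    if (length(midx) > 1) {
      warning("gene '", gid, "' has ", length(midx),
              " mRNAs; using the first", call. = FALSE)
      midx <- midx[1]
    }
    mid <- mrnas$ID[midx]
    ex <- exons[exon_parent == mid, , drop = FALSE]
    if (nrow(ex) == 0) {
      stop("GFF3 format error: mRNA '", mid, "' has no exons", call. = FALSE)
    }
    ord <- order(ex$start)
    em <- cbind(start = ex$start[ord], end = ex$end[ord])
    if (any(em[, "end"] < em[, "start"])) {
      stop("GFF3 format error: exon with end < start in gene '", gid, "'",
           call. = FALSE)
    }
    if (nrow(em) > 1 && any(em[-1, "start"] <= em[-nrow(em), "end"])) {
      stop("GFF3 format error: overlapping exons in gene '", gid, "'",
           call. = FALSE)
    }
    models[[i]] <- list(
      gene_id = gid,
      species = species,
      chromosome = genes$seqnames[i],
      strand = genes$strand[i],
      exons = em,
      cds_length = sum(em[, "end"] - em[, "start"] + 1L)
    )
  }
  models
}

# Writes the simulator's gene models as GFF3 (gene -> mRNA -> exon).
write_gene_models_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    g_start <- min(m$exons[, "start"])
    g_end <- max(m$exons[, "end"])
    src <- "epiensemble_sim"
    mid <- paste0(m$gene_id, ".t1")
    lines <- c(
      lines,
      paste(m$chromosome, src, "gene", g_start, g_end, ".", m$strand, ".",
            paste0("ID=", m$gene_id), sep = "\t"),
      paste(m$chromosome, src, "mRNA", g_start, g_end, ".", m$strand, ".",
            paste0("ID=", mid, ";Parent=", m$gene_id), sep = "\t")
    )
    for (j in seq_len(nrow(m$exons))) {
      lines <- c(lines, paste(
        m$chromosome, src, "exon", m$exons[j, "start"], m$exons[j, "end"],
        ".", m$strand, ".",
        paste0("ID=", mid, ".e", j, ";Parent=", mid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Convenience lookup: gene id -> exon count / chromosome from a model list.
gene_model_field <- function(models, ids, field = c("n_exons", "chromosome")) {
  field <- match.arg(field)
  vapply(ids, function(g) {
    m <- models[[g]]
    if (is.null(m)) stop("missing gene model for '", g, "'", call. = FALSE)
    if (field == "n_exons") nrow(m$exons) else m$chromosome
  }, if (field == "n_exons") integer(1) else character(1))
}
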