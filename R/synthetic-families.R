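# Multi-species gene-family simulator with planted duplication, loss and
# retrotransposition events and full ground truth. Events are planted on
# terminal branches of non-reference species only, so every event maps to
# exactly one species and reference-relative copy-number accounting can be
# compared 1:1 against the planted truth. The reference species therefore
# carries exactly one copy per family.

.CHROMS <- c("2L", "2R", "3L", "3R", "X")

#' Simulate multi-species gene families with ground truth
#'
#' Simulates `n_families` gene families along the configured species tree.
#' Each family starts from a random ancestral CDS; sequences evolve along
#' branches under the accept/reject codon process of [evolve_codons()] at
#' the family's omega. On terminal branches of non-reference species,
#' duplications, losses and retrotranspositions occur as Poisson events at
#' the configured rates; a retrotransposition copies the parent CDS
#' verbatim at birth (divergence accrues afterwards) and its gene model is
#' single-exon. A configurable fraction of duplication/retrocopy-born genes
#' is placed on the "UNKN" chromosome. Fully deterministic for a fixed
#' config seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, per-species CDS FASTA,
#'   protein FASTA and GFF3 files plus a ground-truth JSON are written.
#' @return List with `species` (per species: `cds` and `proteins` as named
#'   character vectors, `gene_models` as by [read_gff3_gene_models()]),
#'   `ground_truth` (list: `genes` data frame, `copies` matrix,
#'   `ortholog_map`, `events`, `retrocopies`, `true_omega`,
#'   `expression_class`) and `config`.
#' @export
simulate_families <- function(config, out_dir = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  tree <- read_species_tree(config)
  tree <- stats::reorder(tree, "cladewise")
  species <- tree$tip.label
  reference <- if (is.null(config$reference)) species[1] else config$reference
  if (!reference %in% species) {
    stop("reference species '", reference, "' not a tree tip", call. = FALSE)
  }
  omega_by_family <- rep(config$omega, length.out = config$n_families)
  n_tips <- length(species)
  root <- n_tips + 1L

  gene_rows <- list()
  extinct <- character(0)

  for (fam_i in seq_len(config$n_families)) {
    fam <- sprintf("F%03d", fam_i)
    omega_f <- omega_by_family[fam_i]
    ancestor <- random_cds(config$codons_per_gene)
    node_state <- vector("list", max(tree$edge))
    node_state[[root]] <- list(list(seq = ancestor, born = "root", parent = NA))
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      bl <- tree$edge.length[e]
      lineages <- node_state[[parent]]
      is_tip <- child <= n_tips
      sp <- if (is_tip) species[child] else NA
      if (is_tip && sp != reference && length(lineages) > 0) {
        n_dup <- stats::rpois(1, config$dup_rate * bl)
        n_retro <- stats::rpois(1, config$retro_rate * bl)
        n_loss <- stats::rpois(1, config$loss_rate * bl)
        for (k in seq_len(n_dup)) {
          src <- sample.int(length(lineages), 1)
          lineages[[length(lineages) + 1L]] <-
            list(seq = lineages[[src]]$seq, born = "dup", parent = NA)
        }
        for (k in seq_len(n_retro)) {
          src <- sample.int(length(lineages), 1)
          lineages[[length(lineages) + 1L]] <-
            list(seq = lineages[[src]]$seq, born = "retro", parent = src)
        }
        for (k in seq_len(n_loss)) {
          if (length(lineages) == 0) break
          drop <- sample.int(length(lineages), 1)
          # fix retro parent indices after removal
          lineages <- lapply(lineages[-drop], function(ln) {
            if (!is.na(ln$parent)) {
              if (ln$parent == drop) ln$parent <- NA
              else if (ln$parent > drop) ln$parent <- ln$parent - 1L
            }
            ln
          })
        }
        if (length(lineages) == 0) extinct <- c(extinct, paste0(fam, "/", sp))
      }
      lineages <- lapply(lineages, function(ln) {
        ln$seq <- as.character(
          evolve_codons(ln$seq, bl, omega_f, config$kappa))
        ln
      })
      node_state[[child]] <- lineages
    }
    fam_class <- sample(c("high", "low"), 1)
    for (t_i in seq_len(n_tips)) {
      sp <- species[t_i]
      lineages <- node_state[[t_i]]
      if (length(lineages) == 0) next
      ids <- sprintf("%s_%s_g%d", sp, fam, seq_along(lineages))
      cls <- fam_class
      if (sp != reference && stats::runif(1) < config$expression$swap_fraction) {
        cls <- if (fam_class == "high") "low" else "high"
      }
      for (k in seq_along(lineages)) {
        ln <- lineages[[k]]
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = ids[k], species = sp, family = fam, born = ln$born,
          retrocopy = ln$born == "retro",
          parent_gene = if (!is.na(ln$parent)) ids[ln$parent] else NA_character_,
          expression_class = cls, seq = ln$seq, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(extinct) > 0) {
    warning("families extinct in some species: ",
            paste(extinct, collapse = ", "), call. = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL

  # chromosome placement: ancestral genes on placed chromosomes round-robin;
  # a fraction of event-born genes on "UNKN"
  genes$chromosome <- .CHROMS[(seq_len(nrow(genes)) - 1L) %% length(.CHROMS) + 1L]
  event_born <- genes$born %in% c("dup", "retro")
  if (config$unkn_fraction > 0 && any(event_born)) {
    on_unkn <- stats::runif(sum(event_born)) < config$unkn_fraction
    genes$chromosome[event_born][on_unkn] <- "UNKN"
  }
  genes$n_exons <- ifelse(genes$retrocopy, 1L, config$exons_per_gene)

  species_out <- lapply(species, function(sp) {
    g <- genes[genes$species == sp, , drop = FALSE]
    cds <- stats::setNames(g$seq, g$gene_id)
    prot <- vapply(cds, translate_cds, character(1))
    models <- build_sim_gene_models(g)
    list(cds = cds, proteins = prot, gene_models = models)
  })
  names(species_out) <- species

  copies <- table(factor(genes$family, levels = sort(unique(genes$family))),
                  factor(genes$species, levels = species))
  copies <- matrix(as.integer(copies), nrow = nrow(copies),
                   dimnames = dimnames(copies))
  events <- events_from_copies(copies, reference)
  retro <- genes[genes$retrocopy & !is.na(genes$parent_gene),
                 c("parent_gene", "gene_id", "species")]
  names(retro) <- c("parent_gene", "retro_gene", "species")
  rownames(retro) <- NULL

  ortholog_map <- build_ortholog_map(genes)

  ground_truth <- list(
    genes = genes[, setdiff(names(genes), "seq")],
    copies = copies,
    events = events,
    retrocopies = retro,
    ortholog_map = ortholog_map,
    true_omega = stats::setNames(omega_by_family,
                                 sprintf("F%03d", seq_len(config$n_families))),
    expression_class = stats::setNames(genes$expression_class, genes$gene_id),
    reference = reference
  )
  out <- list(species = species_out, ground_truth = ground_truth,
              config = config)
  if (!is.null(out_dir)) write_simulation(out, out_dir)
  out
}

# net copy-number differences vs the reference species
events_from_copies <- function(copies, reference) {
  rows <- list()
  for (f in rownames(copies)) {
    for (s in setdiff(colnames(copies), reference)) {
      delta <- copies[f, s] - copies[f, reference]
      if (delta != 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          family = f, species = s,
          direction = if (delta > 0) "expansion" else "contraction",
          delta = as.integer(delta), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(family = character(), species = character(),
                      direction = character(), delta = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

build_sim_gene_models <- function(g) {
  pos <- stats::setNames(rep(0L, length(unique(g$chromosome))),
                         unique(g$chromosome))
  models <- vector("list", nrow(g))
  names(models) <- g$gene_id
  for (i in seq_len(nrow(g))) {
    chr <- g$chromosome[i]
    len <- nchar(g$seq[i])
    n_ex <- g$n_exons[i]
    base <- len %/% n_ex
    sizes <- rep(base, n_ex)
    sizes[n_ex] <- sizes[n_ex] + len - base * n_ex
    start <- pos[chr] + 501L
    exons <- matrix(0L, nrow = n_ex, ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
    cur <- start
    for (j in seq_len(n_ex)) {
      exons[j, ] <- c(cur, cur + sizes[j] - 1L)
      cur <- cur + sizes[j] + 100L   # 100-nt introns
    }
    pos[chr] <- exons[n_ex, "end"]
    models[[i]] <- list(gene_id = g$gene_id[i], species = g$species[i],
                        chromosome = chr,
                        strand = if (i %% 2 == 0) "-" else "+",
                        exons = exons, cds_length = len)
  }
  models
}

build_ortholog_map <- function(genes) {
  rows <- list()
  for (f in unique(genes$family)) {
    gf <- genes[genes$family == f, ]
    sps <- unique(gf$species)
    if (length(sps) < 2) next
    for (i in seq_along(sps)[-length(sps)]) {
      for (j in seq((i + 1), length(sps))) {
        ga <- gf$gene_id[gf$species == sps[i]]
        gb <- gf$gene_id[gf$species == sps[j]]
        grid <- expand.grid(gene_a = ga, gene_b = gb,
                            stringsAsFactors = FALSE)
        grid$species_a <- sps[i]
        grid$species_b <- sps[j]
        grid$family <- f
        rows[[length(rows) + 1L]] <- grid
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      species_a = character(), species_b = character(),
                      family = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$species)) {
    spd <- sim$species[[sp]]
    write_fasta(spd$cds, file.path(out_dir, paste0(sp, "_cds.fasta")))
    write_fasta(spd$proteins, file.path(out_dir, paste0(sp, "_protein.fasta")))
    write_gene_models_gff3(spd$gene_models,
                           file.path(out_dir, paste0(sp, ".gff3")))
  }
  gt <- sim$ground_truth
  gt$copies <- as.data.frame(gt$copies)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
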