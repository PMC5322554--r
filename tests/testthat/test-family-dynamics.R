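# Copy-number tables, the UNKN artifact filter, event calling,
# conservation statistics and retrocopy detection.

test_that("copy tables build from catalogs with implicit zeros", {
  cats <- list(
    ref = data.frame(family = c("F1", "F2"), gene_id = c("r1", "r2"),
                     stringsAsFactors = FALSE),
    sp2 = data.frame(family = c("F1", "F1"), gene_id = c("a1", "a2"),
                     stringsAsFactors = FALSE))
  tab <- build_copy_table(cats, "ref")
  expect_equal(tab$copies["F1", "sp2"], 2L)
  expect_equal(tab$copies["F2", "sp2"], 0L)   # missing family -> 0 copies
  expect_error(build_copy_table(cats, "nope"), "reference")

  single <- build_copy_table(cats["ref"], "ref")
  expect_equal(nrow(detect_events(single)$events), 0)
})

test_that("the published copy table reconstructs from per-species catalogs", {
  fx <- make_table_fixtures()
  copies <- fx$copy_table$copies
  cats <- lapply(colnames(copies), function(sp) {
    fams <- rep(rownames(copies), copies[, sp])
    data.frame(family = fams,
               gene_id = paste0(gsub("[^A-Za-z]", "", sp), "_",
                                make.unique(fams)),
               stringsAsFactors = FALSE)
  })
  names(cats) <- colnames(copies)
  rebuilt <- build_copy_table(cats, "A. gambiae")
  expect_equal(rebuilt$copies[rownames(copies), colnames(copies)], copies)
})

mk_model <- function(id, chrom, n_exons) {
  ex <- cbind(start = seq(1, by = 200, length.out = n_exons),
              end = seq(100, by = 200, length.out = n_exons))
  list(gene_id = id, species = NA, chromosome = chrom, strand = "+",
       exons = ex, cds_length = sum(ex[, 2] - ex[, 1] + 1))
}

test_that("the UNKN filter reverts unplaced duplicates and logs them", {
  cats <- list(
    ref = data.frame(family = "F1", gene_id = "r1", stringsAsFactors = FALSE),
    sp2 = data.frame(family = c("F1", "F1"), gene_id = c("a1", "a2"),
                     stringsAsFactors = FALSE),
    sp3 = data.frame(family = c("F1", "F1"), gene_id = c("b1", "b2"),
                     stringsAsFactors = FALSE))
  models <- list(r1 = mk_model("r1", "2L", 3), a1 = mk_model("a1", "2R", 3),
                 a2 = mk_model("a2", "UNKN", 1), b1 = mk_model("b1", "3L", 3),
                 b2 = mk_model("b2", "3R", 1))
  tab <- build_copy_table(cats, "ref")
  filt <- filter_unkn(tab, models)
  # the unplaced duplicate reverts to the reference count and is logged
  expect_equal(filt$table$copies["F1", "sp2"], 1L)
  expect_equal(filt$removed$gene_id, "a2")
  # a duplicate on a mapped chromosome is retained
  expect_equal(filt$table$copies["F1", "sp3"], 2L)

  no_unkn <- filter_unkn(build_copy_table(cats[c("ref", "sp3")], "ref"),
                         models)
  expect_equal(no_unkn$table$copies, build_copy_table(cats[c("ref", "sp3")],
                                                      "ref")$copies)
  expect_equal(nrow(no_unkn$removed), 0)
})

test_that("event detection matches the published family accounting", {
  fx <- make_table_fixtures()
  ev <- detect_events(fx$copy_table)
  expect_equal(ev$n_event_families, 7)
  expect_equal(ev$n_expansion_families, 4)
  expect_equal(ev$n_contraction_families, 3)
  expect_setequal(
    ev$family_summary$family[ev$family_summary$direction == "expansion"],
    c("Cap-G", "CG18004", "Orc2", "Effete"))
  expect_setequal(
    ev$family_summary$family[ev$family_summary$direction == "contraction"],
    c("Parg", "GRO", "CC14"))
  # loss to zero counts as a contraction event
  parg <- ev$events[ev$events$family == "Parg", ]
  expect_equal(parg$species, "A. albimanus")
  expect_equal(parg$direction, "contraction")

  flat <- copy_number_table(matrix(1L, 3, 4, dimnames = list(
    paste0("F", 1:3), paste0("s", 1:4))), "s1")
  expect_equal(nrow(detect_events(flat)$events), 0)
})

test_that("conservation statistics reproduce the printed percentages", {
  fx <- make_table_fixtures()
  cons <- conservation_stats(fx$copy_table, 169)
  expect_equal(cons$per_species_pct[["A. arabiensis"]], 100)
  expect_equal(cons$per_species_pct[["A. quadriannulatus"]], 100)
  expect_equal(round(cons$min_pct, 1), 97.6)
  expect_equal(names(which.min(cons$per_species_pct)), "A. atroparvus")
  # the committed formula puts A. albimanus at (169-3)/169, i.e. 98.2
  expect_equal(round(cons$per_species_pct[["A. albimanus"]], 1), 98.2)
  expect_true(all(cons$per_species_pct >= 0 & cons$per_species_pct <= 100))
  expect_lte(cons$min_pct, cons$mean_pct)

  flat <- copy_number_table(matrix(1L, 2, 3, dimnames = list(
    c("F1", "F2"), c("s1", "s2", "s3"))), "s1")
  all100 <- conservation_stats(flat, 10)
  expect_equal(unname(all100$per_species_pct), c(100, 100))
  expect_equal(all100$mean_pct, 100)
  expect_error(conservation_stats(fx$copy_table, 3), "smaller")
})

test_that("retrocopy detection requires exon asymmetry and identity", {
  scheme <- scoring_scheme()
  set.seed(51)
  aas <- rownames(scheme$matrix)[1:20]
  prot <- paste(sample(aas, 120, replace = TRUE), collapse = "")
  prots <- c(p1 = prot, p2 = prot,
             junk = paste(sample(aas, 120, replace = TRUE), collapse = ""))
  models <- list(p1 = mk_model("p1", "2L", 4), p2 = mk_model("p2", "2R", 1),
                 junk = mk_model("junk", "3L", 1))
  hit <- detect_retrocopies(data.frame(gene_a = "p1", gene_b = "p2"),
                            models, prots)
  expect_equal(hit$parent, "p1")
  expect_equal(hit$retrocopy, "p2")

  # two multi-exon paralogs: never flagged
  models2 <- list(p1 = mk_model("p1", "2L", 4), p2 = mk_model("p2", "2R", 3))
  expect_equal(nrow(detect_retrocopies(
    data.frame(gene_a = "p1", gene_b = "p2"), models2, prots)), 0)

  # single-exon partner below the identity floor: not flagged
  expect_equal(nrow(detect_retrocopies(
    data.frame(gene_a = "p1", gene_b = "junk"), models, prots)), 0)
})

test_that("events and retrocopies recover the planted truth under perfect calls", {
  cfg <- sim_config(n_families = 25, dup_rate = 1.2, loss_rate = 0.6,
                    retro_rate = 1.2, codons_per_gene = 60, seed = 17,
                    unkn_fraction = 0.4)
  sim <- suppressWarnings(simulate_families(cfg))
  gt <- sim$ground_truth
  genes <- gt$genes
  # perfect ortholog calls: catalogs straight from the ground truth
  cats <- lapply(split(genes, genes$species), function(g) {
    data.frame(family = g$family, gene_id = g$gene_id,
               stringsAsFactors = FALSE)
  })
  models <- do.call(c, lapply(sim$species, function(s) s$gene_models))
  names(models) <- unlist(lapply(sim$species, function(s) names(s$gene_models)))
  filt <- filter_unkn(build_copy_table(cats, gt$reference), models)
  ev <- detect_events(filt$table)

  # independent recount: net copy difference vs reference, UNKN genes that
  # exceed the reference count excluded per family x species
  expected <- list()
  ref_counts <- table(genes$family[genes$species == gt$reference])
  for (f in sort(unique(genes$family))) {
    for (sp in setdiff(unique(genes$species), gt$reference)) {
      g <- genes[genes$family == f & genes$species == sp, ]
      n_ref <- if (f %in% names(ref_counts)) ref_counts[[f]] else 0L
      n <- nrow(g)
      if (n > n_ref) {
        n <- n - min(sum(g$chromosome == "UNKN"), n - n_ref)
      }
      if (n != n_ref) {
        expected[[paste(f, sp)]] <- data.frame(
          family = f, species = sp,
          direction = if (n > n_ref) "expansion" else "contraction",
          delta = as.integer(n - n_ref), stringsAsFactors = FALSE)
      }
    }
  }
  expected <- do.call(rbind, expected)
  rownames(expected) <- NULL
  got <- ev$events[order(ev$events$family, ev$events$species), ]
  expected <- expected[order(expected$family, expected$species), ]
  rownames(got) <- rownames(expected) <- NULL
  expect_equal(got, expected)

  # retrocopy detection: every planted retrocopy with a surviving
  # multi-exon family member is recovered, and nothing else is flagged
  for (sp in setdiff(unique(genes$species), gt$reference)) {
    g <- genes[genes$species == sp, ]
    pairs <- list()
    for (f in unique(g$family)) {
      ids <- g$gene_id[g$family == f]
      if (length(ids) >= 2) {
        cmb <- combn(sort(ids), 2)
        pairs[[f]] <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                                 stringsAsFactors = FALSE)
      }
    }
    if (length(pairs) == 0) next
    hits <- detect_retrocopies(do.call(rbind, pairs),
                               sim$species[[sp]]$gene_models,
                               sim$species[[sp]]$proteins)
    planted <- g$gene_id[g$retrocopy]
    has_multi_partner <- vapply(planted, function(r) {
      fam <- g$family[g$gene_id == r]
      any(!g$retrocopy[g$family == fam])
    }, logical(1))
    expect_setequal(unique(hits$retrocopy), planted[has_multi_partner])
    expect_true(all(!hits$parent %in% planted))
  }
})
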