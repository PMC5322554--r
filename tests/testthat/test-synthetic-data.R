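# Synthetic gene-family generator: codon evolution, event planting,
# expression simulation and the printed-table fixtures.

test_that("codon evolution respects the no-change and purifying limits", {
  set.seed(31)
  anc <- random_cds(100)
  expect_equal(as.character(evolve_codons(anc, 0, 0.5)), anc)

  # omega = 0: protein unchanged, nucleotides free to change synonymously
  tr <- function(x) as.character(Biostrings::translate(Biostrings::DNAString(x)))
  out <- evolve_codons(anc, 2, 0, kappa = 2)
  expect_equal(tr(as.character(out)), tr(anc))
  expect_false(as.character(out) == anc)
  expect_equal(attr(out, "substitutions")$nonsyn, 0L)
  expect_gt(attr(out, "substitutions")$syn, 0)

  bad <- paste0(substr(anc, 1, 30), "TAA", substr(anc, 34, nchar(anc)))
  expect_error(evolve_codons(bad, 0.1, 0.1), "stop")
})

test_that("neutral evolution realizes Nd/Sd near the site ratio", {
  # at omega = 1 every proposal is accepted, so realized substitution
  # counts split between nonsynonymous and synonymous in proportion to
  # the NG86 site counts (kappa = 1 matches the unweighted site model)
  set.seed(32)
  anc <- random_cds(3000)
  out <- evolve_codons(anc, 0.2, 1, kappa = 1)
  subs <- attr(out, "substitutions")
  est <- ng86_pairwise(anc, anc)  # site counts of the ancestor
  site_ratio <- est$n_sites / est$s_sites
  realized <- subs$nonsyn / subs$syn
  expect_equal(realized, site_ratio, tolerance = 0.15)
})

test_that("synonymous divergence grows with branch length", {
  for (s in 1:5) {
    set.seed(s)
    anc <- random_cds(200)
    syn <- sapply(c(0.05, 0.2, 0.5), function(bl) {
      attr(evolve_codons(anc, bl, 0.1), "substitutions")$syn
    })
    expect_true(all(diff(syn) > 0))
  }
})

test_that("a no-event simulation yields perfect 1:1 families", {
  cfg <- sim_config(n_families = 8, dup_rate = 0, loss_rate = 0,
                    retro_rate = 0, codons_per_gene = 60, seed = 5)
  sim <- simulate_families(cfg)
  expect_equal(nrow(sim$ground_truth$events), 0)
  expect_true(all(sim$ground_truth$copies == 1))
  counts <- table(sim$ground_truth$ortholog_map$family)
  expect_true(all(counts == choose(4, 2)))  # one pair per species pair
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_families = 6, dup_rate = 0.5, loss_rate = 0.3,
                    retro_rate = 0.5, codons_per_gene = 60, seed = 7,
                    unkn_fraction = 0.5)
  d1 <- tempfile(); d2 <- tempfile()
  suppressWarnings(simulate_families(cfg, out_dir = d1))
  suppressWarnings(simulate_families(cfg, out_dir = d2))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("planted retrocopies are single-exon in the emitted GFF3", {
  cfg <- sim_config(n_families = 15, dup_rate = 0, loss_rate = 0,
                    retro_rate = 3, codons_per_gene = 60, seed = 9)
  d <- tempfile()
  sim <- simulate_families(cfg, out_dir = d)
  retro <- sim$ground_truth$retrocopies
  expect_gt(nrow(retro), 0)
  for (sp in unique(retro$species)) {
    models <- read_gff3_gene_models(file.path(d, paste0(sp, ".gff3")))
    n_ex <- function(ids) vapply(models[ids], function(m) nrow(m$exons),
                                 integer(1))
    ids <- retro$retro_gene[retro$species == sp]
    expect_true(all(n_ex(ids) == 1L))
    others <- setdiff(names(models), sim$ground_truth$genes$gene_id[
      sim$ground_truth$genes$retrocopy])
    expect_true(all(n_ex(others) == cfg$exons_per_gene))
  }
})

test_that("expression classes separate exactly at zero noise", {
  gt <- fake_expression_truth(30, classes = rep(c("high", "low"), 15),
                              seed = 41)
  cfg <- sim_config(expression = list(lognormal_sd = 0, swap_fraction = 0))
  mats <- simulate_expression(gt, cfg, seed = 41)
  m <- mats$spX
  labels <- cluster_two_class(m)
  truth <- gt$expression_class[rownames(m)]
  expect_equal(unname(labels[names(truth)]), unname(truth))
})

test_that("class swapping produces binomially distributed discordance", {
  cfg <- sim_config(n_families = 200, dup_rate = 0, loss_rate = 0,
                    retro_rate = 0, codons_per_gene = 50, seed = 42,
                    expression = list(swap_fraction = 0.3))
  sim <- simulate_families(cfg)
  gt <- sim$ground_truth
  cls <- gt$expression_class
  g_ref <- gt$genes[gt$genes$species == "gambiae", ]
  g_other <- gt$genes[gt$genes$species == "arabiensis", ]
  n_diff <- sum(cls[g_ref$gene_id] !=
                  cls[g_other$gene_id[match(g_ref$family, g_other$family)]])
  # binomial oracle: 200 trials at p = 0.3, 99.9% interval
  expect_gt(n_diff, 200 * 0.3 - 3.3 * sqrt(200 * 0.3 * 0.7))
  expect_lt(n_diff, 200 * 0.3 + 3.3 * sqrt(200 * 0.3 * 0.7))

  cfg0 <- sim_config(n_families = 40, dup_rate = 0, loss_rate = 0,
                     retro_rate = 0, codons_per_gene = 50, seed = 43,
                     expression = list(swap_fraction = 0))
  sim0 <- simulate_families(cfg0)
  expect_equal(length(unique(tapply(
    sim0$ground_truth$expression_class,
    sim0$ground_truth$genes$family, function(x) length(unique(x))))), 1)
})

test_that("table fixtures transcribe the printed values", {
  fx <- make_table_fixtures()
  expect_equal(nrow(fx$ensemble_catalog), 17)
  expect_equal(fx$copy_table$copies["Parg", "A. albimanus"], 0L)
  expect_equal(fx$copy_table$copies["CC14", "A. gambiae"], 2L)
  expect_length(fx$evidence_support, 215)
  expect_equal(dim(fx$copy_table$copies), c(7L, 12L))
  expect_equal(unname(table(factor(fx$evidence_support, levels = 3:0))),
               c(146L, 23L, 10L, 36L), ignore_attr = TRUE)
})
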