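# Simulation configuration for the synthetic multi-species gene-family
# generator. Defaults emulate a small anopheline-like panel: a 4-taxon
# species tree with pairwise divergences up to 0.3 substitutions/site,
# strong purifying selection (omega = 0.1, the regime measured for
# chromatin-modifier genes), rare duplication/loss/retrotransposition, and
# two lognormal expression classes with stage-structured profiles.

#' Simulation configuration
#'
#' Builds and validates the configuration consumed by
#' [simulate_families()] and [simulate_expression()].
#'
#' @param species_tree Newick string (or path understood by
#'   `ape::read.tree`) with branch lengths in substitutions/site. The first
#'   tip is the reference species unless `reference` is given.
#' @param n_families Number of gene families to simulate.
#' @param dup_rate,loss_rate,retro_rate Event rates per branch-length unit
#'   (duplication, loss, retrotransposition). Events are planted on
#'   terminal branches of non-reference species so each event maps to one
#'   species.
#' @param omega dN/dS under which coding sequences evolve; scalar or
#'   per-family vector of length `n_families`.
#' @param kappa Transition/transversion rate ratio of the mutation
#'   proposal process.
#' @param codons_per_gene Codons per gene (>= 50).
#' @param exons_per_gene Exons per (non-retrocopy) gene model, >= 2.
#' @param unkn_fraction Fraction of duplication/retrocopy-born genes placed
#'   on the unplaced "UNKN" chromosome, to exercise the artifact filter.
#' @param expression List with `n_stages`, `high_mean`, `low_mean`
#'   (lognormal meanlog of the two classes), `lognormal_sd` (sdlog) and
#'   `swap_fraction` (fraction of non-reference orthologs whose class is
#'   swapped relative to the reference species).
#' @param reference Reference species tip label (default: first tip).
#' @param seed Integer seed; all stochastic draws flow from one generator.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(species_tree = paste0(
                         "((gambiae:0.10,arabiensis:0.10):0.05,",
                         "(stephensi:0.10,albimanus:0.10):0.05);"),
                       n_families = 50,
                       dup_rate = 0.05, loss_rate = 0.05, retro_rate = 0.02,
                       omega = 0.1, kappa = 2, codons_per_gene = 100,
                       exons_per_gene = 3, unkn_fraction = 0,
                       expression = list(),
                       reference = NULL, seed = 1L) {
  expr_defaults <- list(n_stages = 9, high_mean = log(100), low_mean = log(2),
                        lognormal_sd = 0.5, swap_fraction = 0.3)
  expression <- utils::modifyList(expr_defaults, expression)
  cfg <- list(species_tree = species_tree, n_families = n_families,
              dup_rate = dup_rate, loss_rate = loss_rate,
              retro_rate = retro_rate, omega = omega, kappa = kappa,
              codons_per_gene = codons_per_gene,
              exons_per_gene = exons_per_gene,
              unkn_fraction = unkn_fraction, expression = expression,
              reference = reference, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(c(dup_rate, loss_rate, retro_rate) < 0)) {
      stop("event rates must be >= 0", call. = FALSE)
    }
    if (any(omega <= 0)) stop("omega must be > 0", call. = FALSE)
    if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
    if (codons_per_gene < 50) stop("codons_per_gene must be >= 50", call. = FALSE)
    if (exons_per_gene < 2) stop("exons_per_gene must be >= 2", call. = FALSE)
    if (unkn_fraction < 0 || unkn_fraction > 1) {
      stop("unkn_fraction must be in [0, 1]", call. = FALSE)
    }
    if (expression$swap_fraction < 0 || expression$swap_fraction > 1) {
      stop("swap_fraction must be in [0, 1]", call. = FALSE)
    }
    if (expression$n_stages < 2) stop("n_stages must be >= 2", call. = FALSE)
  })
  invisible(cfg)
}

read_species_tree <- function(cfg) {
  tr <- tryCatch({
    if (file.exists(cfg$species_tree)) ape::read.tree(cfg$species_tree)
    else ape::read.tree(text = cfg$species_tree)
  }, error = function(e) NULL)
  if (is.null(tr) || is.null(tr$edge.length)) {
    stop("sim_config: species tree unreadable or lacks branch lengths",
         call. = FALSE)
  }
  tr
}
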