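# Codon sequence evolution by mutation proposal + selection accept/reject.
#
# Proposals arrive as a Poisson process at rate 1 per nucleotide site per
# branch-length unit; the target nucleotide is drawn with transition/
# transversion weighting (kappa : 1 : 1). Proposals creating stop codons
# are rejected; synonymous proposals are always accepted; nonsynonymous
# proposals are accepted with probability min(1, omega). Synonymous sites
# therefore accumulate about `branch_length` substitutions per site, and
# the realized nonsynonymous/synonymous substitution ratio scales with
# omega. This accept/reject scheme is deliberately simpler than a full
# codon rate matrix; it is adequate for parameter-recovery testing and is
# distinct from maximum-likelihood codon models.

.transition <- c(A = "G", G = "A", C = "T", T = "C")

#' Generate a random ancestral coding sequence
#'
#' Uniform random sense codons (stops excluded), balanced GC.
#'
#' @param n_codons Number of codons.
#' @return A CDS string of length `3 * n_codons` with no internal stops.
#' @export
random_cds <- function(n_codons) {
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' Evolve a coding sequence along a branch
#'
#' Simulates nucleotide substitutions under the proposal/acceptance scheme
#' described above. Deterministic given the RNG state: the simulator drives
#' all draws from one seeded generator, so leave `seed = NULL` when calling
#' from [simulate_families()].
#'
#' @param ancestor_cds CDS string, length divisible by 3, no internal stop
#'   codons.
#' @param branch_length Expected substitutions per synonymous site (>= 0).
#' @param omega dN/dS: acceptance probability of nonsynonymous proposals.
#' @param kappa Transition/transversion rate ratio of proposals.
#' @param seed Optional integer seed for standalone use.
#' @return The descendant CDS string, with attribute `"substitutions"` - a
#'   list with realized counts `syn` and `nonsyn` - for use as a
#'   ground-truth oracle.
#' @export
evolve_codons <- function(ancestor_cds, branch_length, omega, kappa = 2,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nchar(ancestor_cds) %% 3 != 0) {
    stop("ancestor CDS length not divisible by 3", call. = FALSE)
  }
  codons0 <- split_codons(ancestor_cds)
  aas <- genetic_code()[codons0]
  if (any(aas == "*")) {
    stop("ancestor CDS contains an internal stop codon", call. = FALSE)
  }
  stopifnot(branch_length >= 0, omega >= 0, kappa > 0)
  nt <- strsplit(ancestor_cds, "")[[1]]
  if (any(!nt %in% .NT)) stop("ancestor CDS must be plain ACGT", call. = FALSE)
  L <- length(nt)
  n_events <- stats::rpois(1, L * branch_length)
  n_syn <- 0L
  n_nonsyn <- 0L
  code <- genetic_code()
  if (n_events > 0) {
    sites <- sample.int(L, n_events, replace = TRUE)
    for (ev in seq_len(n_events)) {
      i <- sites[ev]
      cur <- nt[i]
      ts <- .transition[[cur]]
      tv <- setdiff(.NT, c(cur, ts))
      target <- sample(c(ts, tv), 1, prob = c(kappa, 1, 1) / (kappa + 2))
      codon_idx <- (i - 1L) %/% 3L
      cpos <- codon_idx * 3L + 1:3
      old_codon <- paste(nt[cpos], collapse = "")
      new_nt <- nt[cpos]
      new_nt[i - codon_idx * 3L] <- target
      new_codon <- paste(new_nt, collapse = "")
      if (code[new_codon] == "*") next        # stop-creating: rejected
      if (code[new_codon] == code[old_codon]) {
        nt[i] <- target
        n_syn <- n_syn + 1L
      } else if (stats::runif(1) < min(1, omega)) {
        nt[i] <- target
        n_nonsyn <- n_nonsyn + 1L
      }
    }
  }
  out <- paste(nt, collapse = "")
  attr(out, "substitutions") <- list(syn = n_syn, nonsyn = n_nonsyn)
  out
}
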