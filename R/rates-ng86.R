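# Pairwise dN/dS by the Nei-Gojobori (1986) counting method with
# Jukes-Cantor correction. Synonymous site fractions are counted per codon
# position with changes to stop codons excluded from the site denominators;
# codon pairs differing at several positions are averaged over all
# single-step mutational paths that avoid stop codons. This is a counting
# estimator, deliberately simpler than maximum-likelihood codon models
# (codeml-style): it is fully specifiable and checkable against exhaustive
# enumeration.

.NT <- c("A", "C", "G", "T")

.codon_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(.codon_env$code)) {
    .codon_env$code <- Biostrings::GENETIC_CODE
  }
  .codon_env$code
}

is_stop_codon <- function(codon) unname(genetic_code()[codon] == "*")

translate_cds <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(genetic_code()[codons], collapse = "")
}

# Per-codon synonymous site count: for each position, the fraction of
# non-stop single-nucleotide changes that are synonymous. Cached for all 61
# sense codons; the nonsynonymous count is 3 minus the synonymous count.
syn_sites <- function(codon) {
  if (is.null(.codon_env$syn_sites)) {
    code <- genetic_code()
    sense <- names(code)[code != "*"]
    tab <- vapply(sense, function(cd) {
      nts <- strsplit(cd, "")[[1]]
      s <- 0
      for (pos in 1:3) {
        alt <- .NT[.NT != nts[pos]]
        muts <- vapply(alt, function(a) {
          x <- nts; x[pos] <- a; paste(x, collapse = "")
        }, character(1))
        aa <- code[muts]
        ok <- aa != "*"
        if (any(ok)) s <- s + sum(aa[ok] == code[cd]) / sum(ok)
      }
      s
    }, numeric(1))
    .codon_env$syn_sites <- tab
  }
  unname(.codon_env$syn_sites[codon])
}

.perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Average synonymous/nonsynonymous difference counts between two sense
# codons over all single-step paths avoiding stop codons. Returns NULL when
# every path passes through a stop (the codon pair is then dropped from the
# comparison entirely).
ng86_codon_diff <- function(codon_a, codon_b) {
  if (codon_a == codon_b) return(list(sd = 0, nd = 0))
  code <- genetic_code()
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diffs <- which(a != b)
  sd_tot <- 0; nd_tot <- 0; n_paths <- 0L
  for (ord in .perms(diffs)) {
    cur <- a
    sd <- 0; nd <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- b[pos]
      from <- code[paste(cur, collapse = "")]
      to <- code[paste(nxt, collapse = "")]
      if (to == "*") { ok <- FALSE; break }
      if (from == to) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) {
      sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd
      n_paths <- n_paths + 1L
    }
  }
  if (n_paths == 0L) return(NULL)
  list(sd = sd_tot / n_paths, nd = nd_tot / n_paths)
}

jc_correct <- function(p) {
  # Jukes-Cantor multiple-hit correction; saturates (returns NA) at p >= 3/4
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

split_codons <- function(x) {
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

#' Pairwise dN/dS by the NG86 counting method
#'
#' Estimates synonymous (dS) and nonsynonymous (dN) substitutions per site
#' between two equal-length coding sequences. Codons containing gaps or
#' ambiguity characters in either sequence are skipped pairwise, as are
#' stop codons and codon pairs whose every mutational path passes through a
#' stop. Proportions of differences are corrected with the Jukes-Cantor
#' formula; a proportion at or above 3/4 flags saturation. Per the study's
#' exclusion rule, estimates with dS > 1 are flagged `ds_saturated` and
#' estimates with dS = 0 are flagged `ds_zero`; omega is defined only for
#' unflagged estimates.
#'
#' @param codons_a,codons_b Coding sequences (strings), equal length
#'   divisible by 3, aligned codon-wise (gap codons allowed).
#' @return Object of class `"rate_estimate"`: list with `dN`, `dS`, `omega`,
#'   `n_sites`, `s_sites`, `nd`, `sd`, `n_codons` (compared codons), `pn`,
#'   `ps`, and `excluded` (one of `"none"`, `"ds_saturated"`, `"ds_zero"`).
#' @export
ng86_pairwise <- function(codons_a, codons_b) {
  if (nchar(codons_a) != nchar(codons_b)) {
    stop("ng86_pairwise: sequences differ in length", call. = FALSE)
  }
  if (nchar(codons_a) %% 3 != 0) {
    stop("ng86_pairwise: length not divisible by 3", call. = FALSE)
  }
  ca <- split_codons(codons_a)
  cb <- split_codons(codons_b)
  plain <- function(x) !grepl("[^ACGT]", x)
  code <- genetic_code()
  S <- 0; N <- 0; sd <- 0; nd <- 0; n_codons <- 0L
  for (i in seq_along(ca)) {
    if (!plain(ca[i]) || !plain(cb[i])) next
    if (code[ca[i]] == "*" || code[cb[i]] == "*") next
    d <- ng86_codon_diff(ca[i], cb[i])
    if (is.null(d)) next
    s_i <- (syn_sites(ca[i]) + syn_sites(cb[i])) / 2
    S <- S + s_i
    N <- N + (3 - s_i)
    sd <- sd + d$sd
    nd <- nd + d$nd
    n_codons <- n_codons + 1L
  }
  if (n_codons == 0L) {
    stop("ng86_pairwise: no comparable codons", call. = FALSE)
  }
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  dS <- jc_correct(ps)
  dN <- jc_correct(pn)
  excluded <- if (is.na(dS) || dS > 1) "ds_saturated"
  else if (dS == 0) "ds_zero"
  else "none"
  omega <- if (excluded == "none" && !is.na(dN)) dN / dS else NA_real_
  structure(list(dN = dN, dS = dS, omega = omega, n_sites = N, s_sites = S,
                 nd = nd, sd = sd, n_codons = n_codons, pn = pn, ps = ps,
                 excluded = excluded),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("NG86 rate estimate over %d codons\n", x$n_codons))
  cat(sprintf("  dN = %s  dS = %s  omega = %s  [%s]\n",
              format(x$dN, digits = 4), format(x$dS, digits = 4),
              format(x$omega, digits = 4), x$excluded))
  invisible(x)
}

#' Compare dN/dS between two gene groups
#'
#' Drops excluded (saturated or dS = 0) estimates, summarises omega per
#' group (mean, SEM, n) and tests for a rate difference with a Welch
#' two-sample t-test. When per-gene ids are supplied for both groups, a
#' second comparison restricted to genes usable in both groups is also
#' reported.
#'
#' @param estimates_a,estimates_b Lists of [ng86_pairwise()] estimates (or
#'   numeric omega vectors).
#' @param ids_a,ids_b Optional gene ids parallel to the estimates.
#' @return List of class `"group_comparison"`: `mean`, `sem`, `n` (each a
#'   2-vector), `n_excluded`, `t`, `p_value`, and optionally `restricted`
#'   (same summary over genes usable in both groups).
#' @export
compare_groups <- function(estimates_a, estimates_b,
                           ids_a = NULL, ids_b = NULL) {
  get_omega <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(e) {
      if (inherits(e, "rate_estimate") && e$excluded == "none") e$omega
      else NA_real_
    }, numeric(1))
  }
  oa <- get_omega(estimates_a)
  ob <- get_omega(estimates_b)
  usable_a <- !is.na(oa)
  usable_b <- !is.na(ob)
  if (sum(usable_a) < 2 || sum(usable_b) < 2) {
    stop("compare_groups: fewer than 2 usable omega values in a group",
         call. = FALSE)
  }
  summarise <- function(xa, xb) {
    tt <- stats::t.test(xa, xb, var.equal = FALSE)
    list(mean = c(a = mean(xa), b = mean(xb)),
         sem = c(a = stats::sd(xa) / sqrt(length(xa)),
                 b = stats::sd(xb) / sqrt(length(xb))),
         n = c(a = length(xa), b = length(xb)),
         t = unname(tt$statistic), p_value = tt$p.value)
  }
  out <- summarise(oa[usable_a], ob[usable_b])
  out$n_excluded <- c(a = sum(!usable_a), b = sum(!usable_b))
  if (!is.null(ids_a) && !is.null(ids_b)) {
    shared <- intersect(ids_a[usable_a], ids_b[usable_b])
    if (length(shared) >= 2) {
      out$restricted <- summarise(oa[match(shared, ids_a)],
                                  ob[match(shared, ids_b)])
      out$restricted$n_shared <- length(shared)
    }
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group A: mean omega %.4f (SEM %.4f, n = %d)\n",
              x$mean["a"], x$sem["a"], x$n["a"]))
  cat(sprintf("group B: mean omega %.4f (SEM %.4f, n = %d)\n",
              x$mean["b"], x$sem["b"], x$n["b"]))
  cat(sprintf("Welch t = %.3f, P = %.3g\n", x$t, x$p_value))
  invisible(x)
}
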