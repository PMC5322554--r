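# Independent oracles used across the suite. These deliberately re-derive
# results by brute force (quadratic DP table, explicit path enumeration,
# exhaustive pair scans) so they share no code path with the package.

# --- Smith-Waterman with affine gaps, brute-force Gotoh DP -----------------
# Gap of length L costs gap_open + L * gap_extend (same convention as the
# package's scoring scheme). Returns the optimal local alignment score.
sw_oracle <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)   # gap in b (vertical)
  Iy <- matrix(-Inf, n + 1, m + 1)   # gap in a (horizontal)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- scheme$matrix[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                     Iy[i - 1, j - 1] + s)
      Ix[i, j] <- max(M[i - 1, j] - go - ge, Ix[i - 1, j] - ge)
      Iy[i, j] <- max(M[i, j - 1] - go - ge, Iy[i, j - 1] - ge)
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- NG86 per-codon-pair oracle by explicit permutation enumeration -------
.oracle_code <- Biostrings::GENETIC_CODE

.oracle_perms <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L), c(2L, 3L, 1L),
             c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# average syn/nonsyn step counts over stop-avoiding paths; NULL if all
# paths blocked
ng86_diff_oracle <- function(ca, cb) {
  if (ca == cb) return(c(sd = 0, nd = 0))
  av <- strsplit(ca, "")[[1]]
  bv <- strsplit(cb, "")[[1]]
  pos <- which(av != bv)
  res <- list()
  for (p in .oracle_perms[[as.character(length(pos))]]) {
    cur <- av; sd <- 0; nd <- 0; dead <- FALSE
    for (step in pos[p]) {
      nxt <- cur; nxt[step] <- bv[step]
      if (.oracle_code[paste(nxt, collapse = "")] == "*") { dead <- TRUE; break }
      if (.oracle_code[paste(cur, collapse = "")] ==
          .oracle_code[paste(nxt, collapse = "")]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!dead) res[[length(res) + 1]] <- c(sd, nd)
  }
  if (length(res) == 0) return(NULL)
  mn <- Reduce(`+`, res) / length(res)
  c(sd = mn[1], nd = mn[2])
}

# synonymous site count of a codon, scanning all 9 single-nt changes
syn_sites_oracle <- function(codon) {
  cv <- strsplit(codon, "")[[1]]
  aa <- .oracle_code[codon]
  s <- 0
  for (pos in 1:3) {
    n_syn <- 0; n_ok <- 0
    for (alt in setdiff(c("A", "C", "G", "T"), cv[pos])) {
      mv <- cv; mv[pos] <- alt
      maa <- .oracle_code[paste(mv, collapse = "")]
      if (maa != "*") {
        n_ok <- n_ok + 1
        if (maa == aa) n_syn <- n_syn + 1
      }
    }
    if (n_ok > 0) s <- s + n_syn / n_ok
  }
  s
}

# --- exhaustive reciprocal-best enumeration for MRBB -----------------------
mrbb_oracle <- function(hits_ab, hits_ba, mode = "modified", e_max = 1e-10) {
  ab <- hits_ab[hits_ab$e_value < e_max, ]
  ba <- hits_ba[hits_ba$e_value < e_max, ]
  best_of <- function(tab, q) {
    h <- tab[tab$query_id == q, ]
    if (nrow(h) == 0) return(NA_character_)
    h <- h[order(h$e_value, -h$bit_score, h$subject_id), ]
    h$subject_id[1]
  }
  out <- list()
  for (i in seq_len(nrow(ab))) {
    a <- ab$query_id[i]; b <- ab$subject_id[i]
    if (!any(ba$query_id == b & ba$subject_id == a)) next
    fwd <- identical(best_of(ab, a), b)
    rev <- identical(best_of(ba, b), a)
    keep <- if (mode == "modified") fwd || rev else fwd && rev
    if (keep) out[[length(out) + 1]] <- c(a, b)
  }
  if (length(out) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  df <- unique(data.frame(gene_a = sapply(out, `[`, 1),
                          gene_b = sapply(out, `[`, 2),
                          stringsAsFactors = FALSE))
  df[order(df$gene_a, df$gene_b), ]
}

# random directional hit tables over two 20-gene species, with reciprocal
# hits present for most pairs
random_hit_tables <- function(n_genes = 20, p_hit = 0.2, p_recip = 0.8) {
  ga <- sprintf("A%02d", seq_len(n_genes))
  gb <- sprintf("B%02d", seq_len(n_genes))
  mk_row <- function(q, s) {
    data.frame(query_id = q, subject_id = s, pct_identity = runif(1, 30, 100),
               aln_length = 100L, mismatches = 10L, gap_opens = 1L,
               q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
               e_value = 10^runif(1, -60, -11), bit_score = runif(1, 50, 300),
               stringsAsFactors = FALSE)
  }
  ab <- list(); ba <- list()
  for (a in ga) for (b in gb) {
    if (runif(1) < p_hit) {
      ab[[length(ab) + 1]] <- mk_row(a, b)
      if (runif(1) < p_recip) ba[[length(ba) + 1]] <- mk_row(b, a)
    }
  }
  list(ab = if (length(ab)) do.call(rbind, ab) else empty_tab(),
       ba = if (length(ba)) do.call(rbind, ba) else empty_tab())
}

empty_tab <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), e_value = numeric(), bit_score = numeric(),
             stringsAsFactors = FALSE)
}

# unordered pair keys for precision/recall bookkeeping
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# minimal ground-truth object for expression-only simulations
fake_expression_truth <- function(n_genes, species = c("spX", "spY"),
                                  classes = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (sp in species) {
    cls <- if (is.null(classes)) sample(c("high", "low"), n_genes, TRUE)
           else classes
    rows[[sp]] <- data.frame(
      gene_id = sprintf("%s_g%03d", sp, seq_len(n_genes)), species = sp,
      family = sprintf("F%03d", seq_len(n_genes)),
      expression_class = cls, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  list(genes = genes,
       expression_class = stats::setNames(genes$expression_class,
                                          genes$gene_id))
}
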