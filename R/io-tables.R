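# BLAST-tabular (outfmt 6) hit tables and expression matrices as TSV.

.HIT_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
               "mismatches", "gap_opens", "q_start", "q_end", "s_start",
               "s_end", "e_value", "bit_score")

#' Read a BLAST-tabular (outfmt 6) hit table
#'
#' Accepts the classic 12-column dialect only; lines with any other column
#' count are rejected with the offending line number. E-values in scientific
#' notation ("1e-180" style) are parsed.
#'
#' @param path Path to a tab-separated hit table without header.
#' @return Data frame with columns `query_id`, `subject_id`, `pct_identity`,
#'   `aln_length`, `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `e_value`, `bit_score`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table does not exist: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hit_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 12L)) {
    bad <- which(ncols != 12L)[1]
    stop("hit table format error: line ", bad, " has ", ncols[bad],
         " columns (expected 12)", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$e_value) || any(out$e_value < 0)) {
    stop("hit table format error: unparseable or negative E-value", call. = FALSE)
  }
  if (any(out$aln_length < 1) || any(out$q_end < out$q_start)) {
    stop("hit table format error: invalid alignment coordinates", call. = FALSE)
  }
  out
}

#' Write a hit table in BLAST outfmt-6 dialect
#'
#' Round-trips with [read_hit_table()] field-wise; floating-point fields are
#' preserved to at least relative 1e-6.
#'
#' @param records Hit table data frame (see [read_hit_table()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(records, path) {
  stopifnot(identical(names(records), .HIT_COLS))
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    paste(r$query_id, r$subject_id, sprintf("%.4f", r$pct_identity),
          r$aln_length, r$mismatches, r$gap_opens, r$q_start, r$q_end,
          r$s_start, r$s_end, sprintf("%.6e", r$e_value),
          sprintf("%.6g", r$bit_score), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

empty_hit_table <- function() {
  out <- data.frame(query_id = character(), subject_id = character(),
                    pct_identity = numeric(), aln_length = integer(),
                    mismatches = integer(), gap_opens = integer(),
                    q_start = integer(), q_end = integer(),
                    s_start = integer(), s_end = integer(),
                    e_value = numeric(), bit_score = numeric(),
                    stringsAsFactors = FALSE)
  out
}

#' Read an expression matrix from TSV
#'
#' First column holds gene ids, header row holds condition (life stage or
#' tissue) ids. Values must be non-negative; gene and condition ids must be
#' unique.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes in rows, conditions in columns.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs at least one condition column", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("expression table: duplicate gene ids", call. = FALSE)
  if (anyDuplicated(names(df)[-1])) stop("expression table: duplicate condition ids", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  if (anyNA(m)) stop("expression table: non-numeric values", call. = FALSE)
  if (any(m < 0)) stop("expression table: negative values", call. = FALSE)
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix with gene rownames and condition colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
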