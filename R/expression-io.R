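#' Construct and validate an expression matrix
#'
#' An expression matrix is a numeric gene-by-condition matrix of TPM
#' (transcripts per million) abundances with unique row names (gene
#' identifiers) and unique column names (condition identifiers). Gene
#' identifiers are opaque, case-sensitive strings; no symbol/ID mapping
#' is attempted.
#'
#' @param values numeric matrix with gene row names and condition column
#'   names; all entries must be finite and non-negative.
#' @return the validated matrix with class `"expr_matrix"` prepended.
#' @export
expr_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    rt_abort("`values` must be a numeric matrix", "revtraj_error_bad_input")
  if (nrow(values) < 1L || ncol(values) < 1L)
    rt_abort("expression matrix must have at least one gene and one condition",
             "revtraj_error_empty_matrix")
  gid <- rownames(values)
  cid <- colnames(values)
  if (is.null(gid) || is.null(cid) || any(!nzchar(gid)) || any(!nzchar(cid)))
    rt_abort("gene and condition identifiers are required (dimnames)",
             "revtraj_error_bad_input")
  if (anyDuplicated(gid))
    rt_abort(sprintf("duplicate gene identifier(s): %s",
                     paste(unique(gid[duplicated(gid)]), collapse = ", ")),
             "revtraj_error_duplicate_id")
  if (anyDuplicated(cid))
    rt_abort(sprintf("duplicate condition identifier(s): %s",
                     paste(unique(cid[duplicated(cid)]), collapse = ", ")),
             "revtraj_error_duplicate_id")
  if (any(!is.finite(values)))
    rt_abort("all expression values must be finite", "revtraj_error_bad_value")
  if (any(values < 0))
    rt_abort("expression values must be non-negative (TPM scale)",
             "revtraj_error_bad_value")
  class(values) <- c("expr_matrix", "matrix", "array")
  values
}

as_expr_matrix <- function(values) {
  # internal: re-attach class after subsetting; allows 0-row results
  class(values) <- c("expr_matrix", "matrix", "array")
  values
}

#' Read an expression matrix from TSV
#'
#' The only supported dialect is tab-separated UTF-8 text with a header
#' row of condition identifiers, a first column of gene identifiers and
#' a numeric body (decimal point, no thousands separators).
#'
#' @param path path to the TSV file.
#' @return an [expr_matrix()].
#' @export
read_expr_matrix <- function(path) {
  if (!file.exists(path))
    rt_abort(sprintf("expression matrix file not found: %s", path),
             "revtraj_error_missing_file")
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L || !nzchar(header))
    rt_abort("expression matrix file is empty", "revtraj_error_empty_matrix")
  cid <- strsplit(header, "\t", fixed = TRUE)[[1]][-1]
  if (length(cid) == 0L)
    rt_abort("expression matrix has no condition columns",
             "revtraj_error_empty_matrix")
  body <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      check.names = FALSE, comment.char = "",
                      colClasses = c("character", rep("numeric", length(cid)))),
    error = function(e) rt_abort(
      sprintf("non-numeric value in expression matrix body (%s)",
              conditionMessage(e)),
      "revtraj_error_non_numeric")
  )
  if (nrow(body) == 0L)
    rt_abort("expression matrix has no gene rows", "revtraj_error_empty_matrix")
  m <- as.matrix(body[, -1, drop = FALSE])
  rownames(m) <- body[[1]]
  colnames(m) <- cid
  expr_matrix(m)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expr_matrix()]; values are written at full precision
#' (15 significant digits) so a write/read round-trip reproduces them.
#'
#' @param m an [expr_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expr_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m),
                   format(unclass(m), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter genes by detectable expression
#'
#' Retains exactly the genes with TPM at or above `min_tpm` in at least
#' `min_conditions` conditions. The condition set and the relative gene
#' order are unchanged. The default (TPM >= 1 in at least one condition)
#' is the package's definition of "detectable"; downstream reports echo
#' the thresholds used.
#'
#' @param m an [expr_matrix()].
#' @param min_tpm detection threshold in TPM (default 1).
#' @param min_conditions minimum number of conditions meeting the
#'   threshold (default 1).
#' @return the filtered [expr_matrix()]; possibly zero rows, with a
#'   warning.
#' @export
filter_detectable <- function(m, min_tpm = 1, min_conditions = 1L) {
  stopifnot(is.numeric(min_tpm), min_tpm >= 0,
            min_conditions >= 1, min_conditions <= ncol(m))
  keep <- rowSums(unclass(m) >= min_tpm) >= min_conditions
  out <- as_expr_matrix(unclass(m)[keep, , drop = FALSE])
  if (nrow(out) == 0L)
    warning("no genes pass the detectability filter", call. = FALSE)
  out
}

#' Average replicate condition columns
#'
#' Utility for callers with replicated profiles: collapses groups of
#' condition columns to their per-gene means, producing one column per
#' group. Ratio computations in this package always compare single
#' columns.
#'
#' @param m an [expr_matrix()].
#' @param groups named list; each element is a character vector of
#'   condition identifiers to average, the name is the output column.
#' @return an [expr_matrix()] with one column per group.
#' @export
average_conditions <- function(m, groups) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  missing <- setdiff(unlist(groups), colnames(m))
  if (length(missing))
    rt_abort(sprintf("unknown condition(s): %s", paste(missing, collapse = ", ")),
             "revtraj_error_unknown_condition")
  out <- vapply(groups, function(cols)
    rowMeans(unclass(m)[, cols, drop = FALSE]), numeric(nrow(m)))
  expr_matrix(out)
}

#' Compute pseudo-counted expression ratios between two conditions
#'
#' For every gene g the linear-scale ratio is
#' `(x[g, numerator] + pseudocount) / (x[g, denominator] + pseudocount)`.
#' The symmetric pseudocount (default 1 TPM) keeps ratios finite and
#' positive for zero-expression genes.
#'
#' @param m an [expr_matrix()].
#' @param numerator,denominator condition identifiers present in `m`.
#' @param pseudocount non-negative TPM offset added to both sides
#'   (default 1). Zero is only allowed when no denominator value is zero.
#' @return a `ratio_table`: data frame with columns `gene_id`, `ratio`,
#'   `log2_ratio` in the gene order of `m`, with the two condition
#'   identifiers recorded as attributes.
#' @export
compute_ratio <- function(m, numerator, denominator, pseudocount = 1) {
  missing <- setdiff(c(numerator, denominator), colnames(m))
  if (length(missing))
    rt_abort(sprintf("unknown condition(s): %s", paste(missing, collapse = ", ")),
             "revtraj_error_unknown_condition")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0)
    rt_abort("`pseudocount` must be a single non-negative number",
             "revtraj_error_bad_input")
  den <- unclass(m)[, denominator]
  if (pseudocount == 0 && any(den == 0))
    rt_abort("pseudocount 0 with zero denominator values",
             "revtraj_error_zero_denominator")
  num <- unclass(m)[, numerator]
  ratio <- (num + pseudocount) / (den + pseudocount)
  out <- data.frame(gene_id = rownames(m), ratio = ratio,
                    log2_ratio = log2(ratio),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "numerator_condition") <- numerator
  attr(out, "denominator_condition") <- denominator
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Read gene sets from a GMT file
#'
#' One set per non-empty line: name, description, then member gene
#' identifiers, all tab-separated. Duplicate members within a line are
#' collapsed.
#'
#' @param path path to the GMT file.
#' @return a named list of gene sets; each element is a list with
#'   `name`, `description` and a character vector `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    rt_abort(sprintf("gene set file not found: %s", path),
             "revtraj_error_missing_file")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    rt_abort("GMT file contains no gene sets", "revtraj_error_empty_file")
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      rt_abort(sprintf("malformed GMT line %d: fewer than 3 fields", i),
               "revtraj_error_malformed_line")
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      rt_abort(sprintf("malformed GMT line %d: no members", i),
               "revtraj_error_malformed_line")
    structure(list(name = fields[[1]], description = fields[[2]],
                   members = members), class = "gene_set")
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of gene sets as returned by [read_gmt()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
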