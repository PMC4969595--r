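# Reversal analysis: binning of perturbation fold changes and the
# three-way treatment-response classification with reversed/consistent
# interpretation per stratum.

check_matched_genes <- function(a, b) {
  if (nrow(a) != nrow(b) || !identical(a$gene_id, b$gene_id))
    rt_abort("ratio tables must cover the same genes in the same order",
             "revtraj_error_gene_mismatch")
}

#' Bin edges for perturbation log2 ratios
#'
#' @param config a [classification_config()].
#' @return numeric vector of `n_bins + 1` log2 edges (equal width,
#'   symmetric about 0).
#' @export
bin_edges <- function(config = classification_config()) {
  seq(-config$bin_range_log2, config$bin_range_log2,
      length.out = config$n_bins + 1L)
}

#' Assign genes to perturbation fold-change bins
#'
#' Genes are placed into `n_bins` equal-width bins on the log2
#' perturbation ratio over \[-bin_range_log2, +bin_range_log2); each bin
#' is a half-open interval closed on the left. The first and last bins
#' additionally absorb values below and above the range, so every gene
#' receives exactly one bin. Bin indices are 1-based.
#'
#' @param r1 `ratio_table` of perturbed vs baseline expression.
#' @param config a [classification_config()].
#' @return integer vector of bin indices in `1:n_bins`, one per gene.
#' @export
assign_bins <- function(r1, config = classification_config()) {
  if (nrow(r1) == 0L)
    rt_abort("cannot bin an empty ratio table", "revtraj_error_empty_input")
  width <- 2 * config$bin_range_log2 / config$n_bins
  idx <- floor((r1$log2_ratio + config$bin_range_log2) / width) + 1L
  pmin(pmax(as.integer(idx), 1L), config$n_bins)
}

#' Per-bin summary of treatment log2 ratios
#'
#' Groups genes by their perturbation fold-change bin (see
#' [assign_bins()]) and reports, per bin, the mean and standard error of
#' the log2 treatment ratio. The standard error is the sample standard
#' deviation divided by `sqrt(n)` and is reported as `NA` for bins with
#' fewer than two genes. Empty bins appear with `gene_count` 0.
#'
#' @param r1 `ratio_table` perturbed vs baseline.
#' @param rT `ratio_table` treated vs perturbed, same genes, same order.
#' @param config a [classification_config()].
#' @return data frame with one row per bin: `bin_index`,
#'   `lower_log2`, `upper_log2` (half-open bounds), `center_log2`,
#'   `gene_count`, `mean_log2_rT`, `se_log2_rT`.
#' @export
summarize_bins <- function(r1, rT, config = classification_config()) {
  check_matched_genes(r1, rT)
  bins <- assign_bins(r1, config)
  edges <- bin_edges(config)
  out <- data.frame(bin_index = seq_len(config$n_bins),
                    lower_log2 = edges[-length(edges)],
                    upper_log2 = edges[-1])
  out$center_log2 <- (out$lower_log2 + out$upper_log2) / 2
  x <- rT$log2_ratio
  out$gene_count <- vapply(out$bin_index, function(b) sum(bins == b), integer(1))
  out$mean_log2_rT <- vapply(out$bin_index, function(b) {
    v <- x[bins == b]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  out$se_log2_rT <- vapply(out$bin_index, function(b) {
    v <- x[bins == b]
    if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
  }, numeric(1))
  out
}

#' Classify per-gene treatment responses
#'
#' Genes are first stratified by their perturbation ratio `r1`:
#' `down` if `r1 < down_stratum_max_ratio` (down-regulated by more than
#' 50% at the default), `up` if `r1 > up_stratum_min_ratio`
#' (up-regulated by more than 100%), `neither` otherwise. The treatment
#' ratio `rT` is then categorized: `not_significant` when
#' `ns_lower <= rT <= ns_upper` (band inclusive at both ends),
#' `increased` above, `decreased` below. Interpretation: a treatment
#' change opposing the stratum direction is `reversed`, one extending it
#' is `consistent`, a not-significant change leaves the gene
#' `unaffected`, and genes outside both strata are `not_applicable`.
#'
#' @param r1 `ratio_table` perturbed vs baseline.
#' @param rT `ratio_table` treated vs perturbed, same genes, same order.
#' @param config a [classification_config()].
#' @return data frame of class `"response_labels"` with columns
#'   `gene_id`, `r1`, `rT`, `stratum`, `t20_category`, `interpretation`,
#'   `bin`.
#' @export
classify_t20_response <- function(r1, rT, config = classification_config()) {
  check_matched_genes(r1, rT)
  stratum <- ifelse(r1$ratio < config$down_stratum_max_ratio, "down",
             ifelse(r1$ratio > config$up_stratum_min_ratio, "up", "neither"))
  category <- ifelse(rT$ratio >= config$ns_lower & rT$ratio <= config$ns_upper,
                     "not_significant",
              ifelse(rT$ratio > config$ns_upper, "increased", "decreased"))
  interpretation <- rep("not_applicable", length(stratum))
  interpretation[stratum != "neither" & category == "not_significant"] <- "unaffected"
  interpretation[stratum == "down" & category == "increased"] <- "reversed"
  interpretation[stratum == "down" & category == "decreased"] <- "consistent"
  interpretation[stratum == "up" & category == "decreased"] <- "reversed"
  interpretation[stratum == "up" & category == "increased"] <- "consistent"
  out <- data.frame(gene_id = r1$gene_id, r1 = r1$ratio, rT = rT$ratio,
                    stratum = stratum, t20_category = category,
                    interpretation = interpretation,
                    bin = assign_bins(r1, config),
                    stringsAsFactors = FALSE)
  class(out) <- c("response_labels", "data.frame")
  out
}

#' Stratum-level counts and percentages of treatment responses
#'
#' Tabulates, within each stratum of perturbation-responsive genes, how
#' many were unaffected by the treatment, reversed, or pushed further in
#' the perturbation direction (consistent). Percentages are relative to
#' the stratum total and rounded to one decimal.
#'
#' @param labels output of [classify_t20_response()], or any data frame
#'   with `stratum` and `interpretation` columns.
#' @return data frame with one row per stratum (`down`, `up`): counts
#'   `unaffected`, `reversed`, `consistent`, their sum `total`, and
#'   percentage columns `pct_*`.
#' @export
summarize_strata <- function(labels) {
  out <- do.call(rbind, lapply(c("down", "up"), function(s) {
    in_s <- labels$stratum == s
    n_un <- sum(in_s & labels$interpretation == "unaffected")
    n_rev <- sum(in_s & labels$interpretation == "reversed")
    n_con <- sum(in_s & labels$interpretation == "consistent")
    tot <- n_un + n_rev + n_con
    data.frame(stratum = s, unaffected = n_un, reversed = n_rev,
               consistent = n_con, total = tot,
               pct_unaffected = pct(n_un, tot, 1L),
               pct_reversed = pct(n_rev, tot, 1L),
               pct_consistent = pct(n_con, tot, 1L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
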