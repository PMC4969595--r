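# Trajectory favorability: classifies perturbation-responsive genes by
# comparing the perturbation change (r1, perturbed vs baseline) with the
# endpoint change (r2, endpoint vs baseline), with the pre-endpoint
# ratio (r3) available to plug-in rules.

#' Select perturbation-responsive genes
#'
#' Returns the genes whose perturbation ratio exceeds `fold_threshold`
#' or falls below its reciprocal (both strict), i.e. genes changed by
#' more than `fold_threshold`-fold in either direction.
#'
#' @param r1 `ratio_table` perturbed vs baseline.
#' @param fold_threshold fold-change threshold, > 1 (default 2).
#' @return character vector of gene identifiers, in `r1` order.
#' @export
select_responsive_genes <- function(r1, fold_threshold = 2) {
  if (!is.numeric(fold_threshold) || fold_threshold <= 1)
    rt_abort("`fold_threshold` must be > 1", "revtraj_error_bad_input")
  r1$gene_id[r1$ratio > fold_threshold | r1$ratio < 1 / fold_threshold]
}

# Default four-way rule on log2 changes d1 (perturbation) and d2
# (endpoint). d3 (pre-endpoint vs endpoint) is accepted for interface
# compatibility with plug-in rules but unused here.
default_trajectory_rule <- function(d1, d2, d3, config) {
  ifelse(abs(d2) < config$endpoint_change_min_log2, "un_necessary",
  ifelse(sign(d1) != sign(d2), "opposite",
  ifelse(abs(d1) > abs(d2) + config$overshoot_margin_log2, "over_regulated",
         "consistent")))
}

#' Classify gene trajectories into favorability categories
#'
#' For each selected gene, compares the perturbation-induced log2 change
#' `d1 = log2(r1)` with the endpoint log2 change `d2 = log2(r2)`
#' (baseline to pluripotent endpoint). The default rule is:
#' `un_necessary` if the gene barely changes at the endpoint
#' (`|d2| < endpoint_change_min_log2`); otherwise `opposite` if the
#' perturbation moved it against the endpoint direction; otherwise
#' `over_regulated` if the perturbation change exceeds the endpoint
#' change by more than `overshoot_margin_log2`; otherwise `consistent`.
#' Genes missing from any input table are `unclassified`. The rule is
#' pluggable via `rule`; reports record which rule was used.
#'
#' @param r1,r2,r3 `ratio_table`s: perturbed vs baseline, endpoint vs
#'   baseline, pre-endpoint vs endpoint. `r3` may be `NULL`; the default
#'   rule does not use it.
#' @param config a [classification_config()].
#' @param genes gene identifiers to classify; defaults to
#'   [select_responsive_genes()] on `r1` at 2-fold.
#' @param rule function `(d1, d2, d3, config) -> category` applied to
#'   vectors of log2 changes; defaults to the four-way rule above.
#' @param rule_name label recorded in reports.
#' @return data frame of class `"trajectory_labels"` with columns
#'   `gene_id`, `r1_log2`, `r2_log2`, `r3_log2`, `category`.
#' @export
classify_trajectory <- function(r1, r2, r3 = NULL,
                                config = classification_config(),
                                genes = select_responsive_genes(r1),
                                rule = default_trajectory_rule,
                                rule_name = "default_four_way") {
  lookup <- function(tab, g) {
    if (is.null(tab)) return(rep(NA_real_, length(g)))
    tab$log2_ratio[match(g, tab$gene_id)]
  }
  d1 <- lookup(r1, genes)
  d2 <- lookup(r2, genes)
  d3 <- lookup(r3, genes)
  covered <- !is.na(d1) & !is.na(d2) & (is.null(r3) | !is.na(d3))
  category <- rep("unclassified", length(genes))
  if (any(covered))
    category[covered] <- rule(d1[covered], d2[covered], d3[covered], config)
  out <- data.frame(gene_id = genes, r1_log2 = d1, r2_log2 = d2, r3_log2 = d3,
                    category = category, stringsAsFactors = FALSE)
  attr(out, "rule_name") <- rule_name
  class(out) <- c("trajectory_labels", "data.frame")
  out
}

trajectory_categories <- c("consistent", "un_necessary", "opposite",
                           "over_regulated", "unclassified")

#' Favorability report from trajectory labels
#'
#' Counts genes per trajectory category and computes the unfavorable
#' percentage, defined as the share of genes whose perturbation-induced
#' change is un-necessary, opposite, or over-regulated relative to the
#' endpoint. Opposite and un-necessary are reported separately and also
#' pooled. Percentages are rounded to the nearest integer.
#'
#' @param labels output of [classify_trajectory()].
#' @return list of class `"favorability_report"`: `total_genes`, named
#'   `counts` and `percentages` per category,
#'   `opposite_or_unnecessary` pooled count and percentage,
#'   `unfavorable_count`, `unfavorable_percentage`, `rule_name`.
#' @export
favorability_report <- function(labels) {
  if (nrow(labels) == 0L)
    rt_abort("cannot report on an empty label set", "revtraj_error_empty_input")
  total <- nrow(labels)
  counts <- vapply(trajectory_categories,
                   function(k) sum(labels$category == k), integer(1))
  unfav <- counts[["un_necessary"]] + counts[["opposite"]] +
    counts[["over_regulated"]]
  pooled <- counts[["opposite"]] + counts[["un_necessary"]]
  structure(list(
    total_genes = total,
    counts = as.list(counts),
    percentages = lapply(counts, function(k) pct(k, total)),
    opposite_or_unnecessary = list(count = pooled,
                                   percentage = pct(pooled, total)),
    unfavorable_count = unfav,
    unfavorable_percentage = pct(unfav, total),
    rule_name = attr(labels, "rule_name") %||% "default_four_way"
  ), class = "favorability_report")
}

#' @export
print.favorability_report <- function(x, ...) {
  cat(sprintf("Favorability report (%d genes, rule %s)\n",
              x$total_genes, x$rule_name))
  for (k in names(x$counts))
    cat(sprintf("  %-15s %6d (%s%%)\n", k, x$counts[[k]],
                format(x$percentages[[k]])))
  cat(sprintf("  unfavorable     %6d (%s%%)\n", x$unfavorable_count,
              format(x$unfavorable_percentage)))
  invisible(x)
}

#' Unfavorable-change percentages along a reprogramming time course
#'
#' Applies responsive-gene selection and trajectory classification
#' independently at each time point of a perturbation series, against a
#' fixed endpoint, and reports the per-time favorability summaries.
#'
#' @param r1_series named list of `ratio_table`s (one per time point,
#'   names are time labels), each covering the same gene universe.
#' @param r2,r3 endpoint and pre-endpoint `ratio_table`s, as in
#'   [classify_trajectory()].
#' @param config a [classification_config()].
#' @param fold_threshold responsive-gene fold threshold (default 2).
#' @return list with `reports` (one [favorability_report()] per time
#'   point) and `summary`, a data frame with columns `time`,
#'   `n_responsive`, `unfavorable_percentage`.
#' @export
timecourse_unfavorable <- function(r1_series, r2, r3 = NULL,
                                   config = classification_config(),
                                   fold_threshold = 2) {
  stopifnot(is.list(r1_series), length(r1_series) >= 1,
            !is.null(names(r1_series)))
  universe <- sort(r1_series[[1]]$gene_id)
  for (tab in r1_series)
    if (!identical(sort(tab$gene_id), universe))
      rt_abort("time points must cover the same gene universe",
               "revtraj_error_gene_mismatch")
  reports <- lapply(r1_series, function(r1) {
    genes <- select_responsive_genes(r1, fold_threshold)
    if (length(genes) == 0L) return(NULL)
    favorability_report(classify_trajectory(r1, r2, r3, config, genes = genes))
  })
  summary <- data.frame(
    time = names(r1_series),
    n_responsive = vapply(reports, function(r)
      if (is.null(r)) 0L else r$total_genes, integer(1)),
    unfavorable_percentage = vapply(reports, function(r)
      if (is.null(r)) NA_real_ else r$unfavorable_percentage, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(reports = reports, summary = summary)
}
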