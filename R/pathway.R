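# Pathway-level direction summaries: detectability, up/down fractions
# under the perturbation, treatment-reversal fractions, and the
# divergent-gene shortlist.

#' Direction fractions of a gene set across condition pairs
#'
#' Restricts a gene set to its detectable members (per the config's
#' detectability thresholds applied to `m`) and reports the fraction
#' up- and down-regulated by the perturbation and the fraction whose
#' treatment response opposes their perturbation direction. Genes with a
#' ratio of exactly 1 have no direction and are excluded from both the
#' up and down fractions.
#'
#' @param m the [expr_matrix()] the ratio tables were computed from.
#' @param set a gene set (list with `name`, `description`, `members`).
#' @param r1 `ratio_table` perturbed vs baseline.
#' @param rT `ratio_table` treated vs perturbed.
#' @param config a [classification_config()].
#' @param min_abs_log2_r1,min_abs_log2_rT thresholds passed to
#'   [select_divergent_genes()].
#' @return list of class `"pathway_direction_report"`: `set_name`,
#'   `members_total`, `members_detectable`, `fraction_up_r1`,
#'   `fraction_down_r1`, `fraction_reversed_by_treatment`,
#'   `selected_divergent_genes`. Fractions are `NA` when no member is
#'   detectable.
#' @export
pathway_direction_fractions <- function(m, set, r1, rT,
                                        config = classification_config(),
                                        min_abs_log2_r1 = 1,
                                        min_abs_log2_rT = log2(1.5)) {
  stopifnot(length(set$members) >= 1)
  detectable <- rownames(filter_detectable(m, config$min_tpm,
                                           config$min_conditions))
  det <- intersect(set$members, intersect(detectable, r1$gene_id))
  i1 <- match(det, r1$gene_id)
  iT <- match(det, rT$gene_id)
  n <- length(det)
  if (n == 0L) {
    frac_up <- frac_down <- frac_rev <- NA_real_
    selected <- character(0)
  } else {
    v1 <- r1$ratio[i1]
    vT <- rT$ratio[iT]
    frac_up <- sum(v1 > 1) / n
    frac_down <- sum(v1 < 1) / n
    frac_rev <- sum((v1 > 1 & vT < 1) | (v1 < 1 & vT > 1)) / n
    selected <- select_divergent_genes(
      list(name = set$name, description = set$description, members = det),
      r1, rT, min_abs_log2_r1, min_abs_log2_rT)
  }
  structure(list(set_name = set$name,
                 members_total = length(set$members),
                 members_detectable = n,
                 fraction_up_r1 = frac_up,
                 fraction_down_r1 = frac_down,
                 fraction_reversed_by_treatment = frac_rev,
                 selected_divergent_genes = selected,
                 thresholds = list(min_abs_log2_r1 = min_abs_log2_r1,
                                   min_abs_log2_rT = min_abs_log2_rT,
                                   note = "divergence thresholds are package defaults, not study-reported values")),
            class = "pathway_direction_report")
}

#' Select set members with large perturbation and treatment changes
#'
#' Returns the gene-set members whose absolute log2 perturbation ratio
#' and absolute log2 treatment ratio both meet their thresholds, sorted
#' by decreasing absolute log2 perturbation change. Defaults (1 log2 for
#' the perturbation, log2 1.5 for the treatment, echoing the
#' not-significant band edge) are package choices; reports flag them as
#' such.
#'
#' @param set a gene set (list with `members`).
#' @param r1,rT `ratio_table`s perturbed vs baseline and treated vs
#'   perturbed.
#' @param min_abs_log2_r1,min_abs_log2_rT non-negative log2 thresholds.
#' @return character vector of gene identifiers.
#' @export
select_divergent_genes <- function(set, r1, rT,
                                   min_abs_log2_r1 = 1,
                                   min_abs_log2_rT = log2(1.5)) {
  stopifnot(min_abs_log2_r1 >= 0, min_abs_log2_rT >= 0)
  genes <- intersect(set$members, intersect(r1$gene_id, rT$gene_id))
  a1 <- abs(r1$log2_ratio[match(genes, r1$gene_id)])
  aT <- abs(rT$log2_ratio[match(genes, rT$gene_id)])
  keep <- a1 >= min_abs_log2_r1 & aT >= min_abs_log2_rT
  genes[keep][order(a1[keep], decreasing = TRUE)]
}
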