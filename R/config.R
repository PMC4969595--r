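#' Classification thresholds and binning parameters
#'
#' Collects every threshold used by the reversal and trajectory
#' classifiers in one validated object. Defaults are the fold-change
#' conventions of the reprogramming analysis this package implements:
#' treatment ratios between 0.67 and 1.50 are "not significant"; genes
#' down-regulated by more than 50% (ratio < 0.5) or up-regulated by more
#' than 100% (ratio > 2) by the perturbation form the down and up
#' strata; perturbation ratios are binned into 14 equal-width log2 bins
#' over \[-3.5, 3.5).
#'
#' @param ns_lower,ns_upper bounds of the not-significant band on the
#'   linear treatment ratio (inclusive at both ends); must bracket 1.
#' @param down_stratum_max_ratio genes with perturbation ratio strictly
#'   below this value form the down stratum (default 0.5, i.e. more
#'   than 50% down).
#' @param up_stratum_min_ratio genes with perturbation ratio strictly
#'   above this value form the up stratum (default 2, i.e. more than
#'   100% up).
#' @param n_bins number of equal-width log2 bins (default 14).
#' @param bin_range_log2 half-width of the symmetric log2 binning range
#'   (default 3.5); outer bins absorb out-of-range values.
#' @param min_tpm,min_conditions detectability filter, as in
#'   [filter_detectable()].
#' @param pseudocount TPM pseudocount for ratios, as in
#'   [compute_ratio()].
#' @param endpoint_change_min_log2 minimum absolute log2 endpoint change
#'   for a perturbation-responsive gene's change to count as needed at
#'   the endpoint (default 1, i.e. 2-fold).
#' @param overshoot_margin_log2 log2 margin by which the perturbation
#'   change must exceed the endpoint change to be called over-regulated
#'   (default 1).
#' @return a validated list of class `"classification_config"`.
#' @export
classification_config <- function(ns_lower = 0.67,
                                  ns_upper = 1.50,
                                  down_stratum_max_ratio = 0.50,
                                  up_stratum_min_ratio = 2.00,
                                  n_bins = 14L,
                                  bin_range_log2 = 3.5,
                                  min_tpm = 1,
                                  min_conditions = 1L,
                                  pseudocount = 1,
                                  endpoint_change_min_log2 = 1.0,
                                  overshoot_margin_log2 = 1.0) {
  cfg <- list(ns_lower = ns_lower, ns_upper = ns_upper,
              down_stratum_max_ratio = down_stratum_max_ratio,
              up_stratum_min_ratio = up_stratum_min_ratio,
              n_bins = as.integer(n_bins), bin_range_log2 = bin_range_log2,
              min_tpm = min_tpm, min_conditions = as.integer(min_conditions),
              pseudocount = pseudocount,
              endpoint_change_min_log2 = endpoint_change_min_log2,
              overshoot_margin_log2 = overshoot_margin_log2)
  num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1 &&
                  is.finite(x), logical(1))
  if (!all(num))
    rt_abort(sprintf("non-numeric config field(s): %s",
                     paste(names(cfg)[!num], collapse = ", ")),
             "revtraj_error_bad_config")
  if (!(cfg$ns_lower > 0 && cfg$ns_lower < 1 && cfg$ns_upper > 1))
    rt_abort("not-significant band must satisfy 0 < ns_lower < 1 < ns_upper",
             "revtraj_error_bad_config")
  if (!(cfg$down_stratum_max_ratio > 0 && cfg$down_stratum_max_ratio < 1 &&
        cfg$up_stratum_min_ratio > 1))
    rt_abort("strata must satisfy 0 < down_stratum_max_ratio < 1 < up_stratum_min_ratio",
             "revtraj_error_bad_config")
  if (cfg$n_bins < 2L)
    rt_abort("n_bins must be at least 2", "revtraj_error_bad_config")
  if (cfg$bin_range_log2 <= 0)
    rt_abort("bin_range_log2 must be positive", "revtraj_error_bad_config")
  if (cfg$min_tpm < 0 || cfg$pseudocount < 0 || cfg$min_conditions < 1)
    rt_abort("detectability/pseudocount fields out of range",
             "revtraj_error_bad_config")
  if (cfg$endpoint_change_min_log2 <= 0 || cfg$overshoot_margin_log2 <= 0)
    rt_abort("trajectory margins must be positive", "revtraj_error_bad_config")
  structure(cfg, class = "classification_config")
}

#' @export
print.classification_config <- function(x, ...) {
  cat("Classification config:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
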