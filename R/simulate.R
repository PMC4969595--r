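# Synthetic-data generator: log-normal TPM baseline, a perturbation
# whose direction is coupled to baseline expression, a treatment that
# reverses a configurable fraction of perturbation effects, optional
# endpoint / pre-endpoint columns and a time-course mode, plus ground
# truth for recovery tests.

#' Generator configuration
#'
#' Parameters of the synthetic expression-matrix generator. Baseline
#' log2 TPM is Gaussian (so TPM is log-normal). A fraction of genes is
#' perturbed, with the probability of being down-regulated following a
#' logistic function of the baseline expression rank: with negative
#' `baseline_coupling`, highly expressed genes tend to be down-regulated
#' and lowly expressed genes up-regulated, the pattern the perturbation
#' classifier is designed to detect. A `reversal_fraction` of perturbed
#' genes has a share `reversal_strength` of its perturbation effect
#' undone by the treatment. Every measured value carries multiplicative
#' log-normal noise.
#'
#' @param n_genes number of genes (>= 10).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @param baseline_log2_mean,baseline_log2_sd mean and SD of baseline
#'   log2 TPM.
#' @param frac_perturbed_down,frac_perturbed_up expected fractions of
#'   genes perturbed down/up; must sum to at most 1.
#' @param effect_log2_mean,effect_log2_sd mean and SD of the absolute
#'   log2 perturbation effect.
#' @param baseline_coupling correlation-like coupling in \[-1, 1\]
#'   between baseline expression rank and perturbation direction
#'   (negative: high expression tends down).
#' @param reversal_fraction fraction of perturbed genes whose effect the
#'   treatment reverses (each perturbed gene reversed independently with
#'   this probability).
#' @param reversal_strength share of the perturbation effect undone in
#'   reversed genes, in (0, 1\].
#' @param noise_log2_sd SD of the additive Gaussian noise on measured
#'   log2 values (multiplicative on TPM).
#' @param endpoint_mode `"attractor"` (endpoint change equals the
#'   perturbation effect for non-reversed perturbed genes and zero for
#'   reversed ones, so reversal and favorability align), `"independent"`
#'   (endpoint changes drawn independently of the perturbation), or
#'   `"none"` (no endpoint columns).
#' @param endpoint_frac fraction of genes with a nonzero endpoint change
#'   in `"independent"` mode.
#' @param timepoints optional character vector of time labels; adds one
#'   perturbed column per time point in which transient (reversed-class)
#'   genes switch on and off following `transient_profile` while
#'   non-reversed perturbed genes stay on.
#' @param transient_profile numeric vector of active fractions in
#'   \[0, 1\], one per time point; default a triangular profile peaking
#'   at `ceiling(0.4 * length(timepoints))`.
#' @return validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_genes = 2000L,
                             seed = 1L,
                             baseline_log2_mean = 3,
                             baseline_log2_sd = 2,
                             frac_perturbed_down = 0.12,
                             frac_perturbed_up = 0.12,
                             effect_log2_mean = 2.5,
                             effect_log2_sd = 0.3,
                             baseline_coupling = -0.8,
                             reversal_fraction = 0.5,
                             reversal_strength = 1,
                             noise_log2_sd = 0.2,
                             endpoint_mode = c("attractor", "independent", "none"),
                             endpoint_frac = 0.3,
                             timepoints = NULL,
                             transient_profile = NULL) {
  endpoint_mode <- match.arg(endpoint_mode)
  cfg <- list(n_genes = as.integer(n_genes), seed = as.integer(seed),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              frac_perturbed_down = frac_perturbed_down,
              frac_perturbed_up = frac_perturbed_up,
              effect_log2_mean = effect_log2_mean,
              effect_log2_sd = effect_log2_sd,
              baseline_coupling = baseline_coupling,
              reversal_fraction = reversal_fraction,
              reversal_strength = reversal_strength,
              noise_log2_sd = noise_log2_sd,
              endpoint_mode = endpoint_mode,
              endpoint_frac = endpoint_frac,
              timepoints = timepoints,
              transient_profile = transient_profile)
  if (cfg$n_genes < 10L)
    rt_abort("n_genes must be at least 10", "revtraj_error_bad_config")
  fr <- c(cfg$frac_perturbed_down, cfg$frac_perturbed_up,
          cfg$reversal_fraction, cfg$endpoint_frac)
  if (any(fr < 0 | fr > 1))
    rt_abort("fractions must lie in [0, 1]", "revtraj_error_bad_config")
  if (cfg$frac_perturbed_down + cfg$frac_perturbed_up > 1)
    rt_abort("frac_perturbed_down + frac_perturbed_up must be <= 1",
             "revtraj_error_bad_config")
  if (cfg$baseline_coupling < -1 || cfg$baseline_coupling > 1)
    rt_abort("baseline_coupling must lie in [-1, 1]",
             "revtraj_error_bad_config")
  if (cfg$reversal_strength <= 0 || cfg$reversal_strength > 1)
    rt_abort("reversal_strength must lie in (0, 1]",
             "revtraj_error_bad_config")
  if (cfg$noise_log2_sd < 0 || cfg$baseline_log2_sd < 0 ||
      cfg$effect_log2_sd < 0)
    rt_abort("standard deviations must be non-negative",
             "revtraj_error_bad_config")
  if (!is.null(cfg$timepoints)) {
    k <- length(cfg$timepoints)
    if (k < 2L)
      rt_abort("timepoints needs at least 2 labels", "revtraj_error_bad_config")
    if (is.null(cfg$transient_profile)) {
      peak <- ceiling(0.4 * k)
      t <- seq_len(k)
      cfg$transient_profile <- ifelse(
        t <= peak, t / peak,
        1 - 0.9 * (t - peak) / max(1L, k - peak))
    }
    if (length(cfg$transient_profile) != k ||
        any(cfg$transient_profile < 0 | cfg$transient_profile > 1))
      rt_abort("transient_profile must match timepoints and lie in [0, 1]",
               "revtraj_error_bad_config")
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic expression matrix with ground truth
#'
#' Emits conditions `baseline`, `perturbed`, `treated`, plus `endpoint`
#' and `pre_endpoint` unless `endpoint_mode = "none"`, and one
#' `perturbed_<label>` column per requested time point. In noiseless
#' terms, `perturbed = baseline * 2^effect` for perturbed genes, and the
#' treated column undoes `reversal_strength * effect` for the reversed
#' subset; log-normal measurement noise then multiplies every value.
#'
#' @param config a [generator_config()].
#' @return list with `matrix` (an [expr_matrix()]), `truth` (per-gene
#'   data frame: `gene_id`, `perturbed`, `direction`, `effect_log2`,
#'   `reversed`, `endpoint_log2`, `activation_u`) and `config`.
#' @export
simulate_expression <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))

  base_l2 <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

  n_pert <- round(n * (config$frac_perturbed_down + config$frac_perturbed_up))
  pert_idx <- sort(sample.int(n, n_pert))
  perturbed <- seq_len(n) %in% pert_idx

  # Direction coupling: probability of down-regulation is logistic in the
  # centered baseline-expression rank; slope 4 * |coupling| spans weak to
  # near-deterministic coupling over [-1, 1].
  p0 <- if (n_pert > 0)
    config$frac_perturbed_down /
      (config$frac_perturbed_down + config$frac_perturbed_up) else 0.5
  s <- 2 * rank(base_l2, ties.method = "first") / (n + 1) - 1
  p_down <- stats::plogis(stats::qlogis(min(max(p0, 1e-6), 1 - 1e-6)) -
                            4 * config$baseline_coupling * s)
  direction <- rep(0L, n)
  direction[perturbed] <- ifelse(
    stats::rbinom(n_pert, 1L, p_down[perturbed]) == 1L, -1L, 1L)

  effect <- rep(0, n)
  effect[perturbed] <- direction[perturbed] *
    abs(stats::rnorm(n_pert, config$effect_log2_mean, config$effect_log2_sd))

  reversed <- rep(FALSE, n)
  reversed[perturbed] <- stats::rbinom(n_pert, 1L,
                                       config$reversal_fraction) == 1L

  pert_l2 <- base_l2 + effect
  treat_l2 <- pert_l2 - config$reversal_strength * effect * reversed

  endpoint_l2 <- NULL
  endpoint_effect <- rep(NA_real_, n)
  if (config$endpoint_mode == "attractor") {
    # Endpoint needs exactly the non-reversed perturbation changes:
    # reversed genes are transient (endpoint change 0).
    endpoint_effect <- effect * as.numeric(!reversed)
  } else if (config$endpoint_mode == "independent") {
    has_ep <- stats::rbinom(n, 1L, config$endpoint_frac) == 1L
    endpoint_effect <- ifelse(
      has_ep,
      sample(c(-1, 1), n, replace = TRUE) *
        abs(stats::rnorm(n, config$effect_log2_mean, config$effect_log2_sd)),
      0)
  }
  if (config$endpoint_mode != "none") {
    endpoint_l2 <- base_l2 + endpoint_effect
    # pre-endpoint: the partially reprogrammed state drifts around the
    # endpoint on the log2 scale
    pre_endpoint_l2 <- endpoint_l2 + stats::rnorm(n, 0, 0.3)
  }

  # Time course: non-reversed perturbed genes keep their full effect;
  # transient (reversed-class) genes are active at time t iff their
  # fixed uniform draw falls below the profile's active fraction, so
  # they switch on in a nested order and off in reverse.
  activation_u <- stats::runif(n)
  time_l2 <- NULL
  if (!is.null(config$timepoints)) {
    time_l2 <- vapply(seq_along(config$timepoints), function(t) {
      active <- !reversed | (activation_u <= config$transient_profile[[t]])
      base_l2 + effect * as.numeric(perturbed & active)
    }, numeric(n))
    colnames(time_l2) <- paste0("perturbed_", config$timepoints)
  }

  cols <- cbind(baseline = base_l2, perturbed = pert_l2, treated = treat_l2)
  if (!is.null(endpoint_l2))
    cols <- cbind(cols, endpoint = endpoint_l2, pre_endpoint = pre_endpoint_l2)
  if (!is.null(time_l2)) cols <- cbind(cols, time_l2)
  noise <- matrix(stats::rnorm(length(cols), 0, config$noise_log2_sd),
                  nrow = n)
  m <- 2^(cols + noise)
  rownames(m) <- gene_id

  truth <- data.frame(gene_id = gene_id, perturbed = perturbed,
                      direction = direction, effect_log2 = effect,
                      reversed = reversed, endpoint_log2 = endpoint_effect,
                      activation_u = activation_u,
                      stringsAsFactors = FALSE)
  list(matrix = expr_matrix(m), truth = truth, config = config)
}

#' Confusion table between generator truth and response labels
#'
#' Cross-tabulates, over the truly perturbed genes, the generator's
#' reversed flag against the pipeline's response interpretation, and
#' derives the sensitivity and specificity of "reversed" labeling.
#'
#' @param labels output of [classify_t20_response()].
#' @param truth the `truth` data frame from [simulate_expression()].
#' @return list with `table` (2 rows: truth reversed TRUE/FALSE; columns
#'   `reversed`, `consistent`, `unaffected`, `not_applicable`),
#'   `sensitivity`, `specificity`.
#' @export
truth_confusion <- function(labels, truth) {
  common <- intersect(labels$gene_id, truth$gene_id)
  if (nrow(labels) > 0 && length(common) != nrow(labels))
    rt_abort("labels contain genes absent from the truth table",
             "revtraj_error_gene_mismatch")
  interp_levels <- c("reversed", "consistent", "unaffected", "not_applicable")
  tl <- labels[match(common, labels$gene_id), , drop = FALSE]
  tt <- truth[match(common, truth$gene_id), , drop = FALSE]
  keep <- tt$perturbed
  tab <- table(
    factor(ifelse(tt$reversed[keep], "TRUE", "FALSE"), c("TRUE", "FALSE")),
    factor(tl$interpretation[keep], interp_levels))
  tab <- unclass(tab)
  n_rev <- sum(tab["TRUE", ])
  n_not <- sum(tab["FALSE", ])
  list(table = tab,
       sensitivity = if (n_rev > 0) tab["TRUE", "reversed"] / n_rev else NA_real_,
       specificity = if (n_not > 0)
         sum(tab["FALSE", colnames(tab) != "reversed"]) / n_not else NA_real_)
}
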