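# Fixtures are built in code at test time; nothing binary is stored.

# Small hand-written matrix used by the IO tests.
fixture_matrix <- function() {
  m <- matrix(c(10, 20, 5,
                0,  4,  1,
                100, 50, 80),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("Actb", "Nanog", "Gapdh"),
                              c("MEF", "OKS", "OKS_T20")))
  expr_matrix(m)
}

write_fixture_tsv <- function(m, path = withr::local_tempfile(fileext = ".tsv",
                                                              .local_envir = parent.frame())) {
  write_expr_matrix(m, path)
  path
}

# Build a ratio_table directly from linear-scale ratios, bypassing the
# matrix route, for classifier unit tests.
make_ratio_table <- function(ratio, gene_id = sprintf("g%04d", seq_along(ratio)),
                             numerator = "num", denominator = "den") {
  out <- data.frame(gene_id = gene_id, ratio = ratio,
                    log2_ratio = log2(ratio), stringsAsFactors = FALSE)
  attr(out, "numerator_condition") <- numerator
  attr(out, "denominator_condition") <- denominator
  class(out) <- c("ratio_table", "data.frame")
  out
}

# Random positive expression matrix for property tests.
random_matrix <- function(n_genes, conditions = c("MEF", "OKS", "OKS_T20"),
                          seed = 42) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_genes * length(conditions), 3, 2),
              nrow = n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)), conditions))
  expr_matrix(m)
}

# Straight-line independent re-implementation of the treatment-response
# rules, evaluated gene by gene; the oracle for classify_t20_response.
oracle_t20 <- function(r1, rT, cfg) {
  t(vapply(seq_along(r1), function(i) {
    stratum <- if (r1[i] < cfg$down_stratum_max_ratio) "down"
      else if (r1[i] > cfg$up_stratum_min_ratio) "up" else "neither"
    category <- if (rT[i] >= cfg$ns_lower && rT[i] <= cfg$ns_upper) "not_significant"
      else if (rT[i] > cfg$ns_upper) "increased" else "decreased"
    interp <- if (stratum == "neither") "not_applicable"
      else if (category == "not_significant") "unaffected"
      else if (stratum == "down" && category == "increased") "reversed"
      else if (stratum == "up" && category == "decreased") "reversed"
      else "consistent"
    c(stratum, category, interp)
  }, character(3)))
}

# Independent per-gene evaluation of the four-way trajectory rule.
oracle_trajectory <- function(d1, d2, cfg) {
  vapply(seq_along(d1), function(i) {
    if (abs(d2[i]) < cfg$endpoint_change_min_log2) "un_necessary"
    else if (sign(d1[i]) != sign(d2[i])) "opposite"
    else if (abs(d1[i]) > abs(d2[i]) + cfg$overshoot_margin_log2) "over_regulated"
    else "consistent"
  }, character(1))
}

# Response-label table built from stratum/interpretation counts, for
# arithmetic checks on published-style count summaries.
labels_from_counts <- function(down_counts, up_counts) {
  mk <- function(stratum, counts) {
    interp <- rep(c("unaffected", "reversed", "consistent"), counts)
    data.frame(gene_id = sprintf("%s%05d", stratum, seq_along(interp)),
               stratum = rep(stratum, length(interp)),
               interpretation = interp, stringsAsFactors = FALSE)
  }
  rbind(mk("down", down_counts), mk("up", up_counts))
}

# Trajectory-label table from per-category counts.
trajectory_labels_from_counts <- function(counts) {
  category <- rep(names(counts), unlist(counts))
  n <- length(category)
  out <- data.frame(gene_id = sprintf("g%05d", seq_len(n)),
                    r1_log2 = rep(NA_real_, n), r2_log2 = rep(NA_real_, n),
                    r3_log2 = rep(NA_real_, n),
                    category = category, stringsAsFactors = FALSE)
  class(out) <- c("trajectory_labels", "data.frame")
  out
}
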