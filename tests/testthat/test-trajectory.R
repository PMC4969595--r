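test_that("responsive-gene selection uses strict 2-fold bounds", {
  rt <- make_ratio_table(c(2.5, 2.0, 0.4, 1.0))
  expect_identical(select_responsive_genes(rt, 2),
                   rt$gene_id[c(1, 3)])
  expect_length(select_responsive_genes(make_ratio_table(rep(1, 10)), 1.0001), 0)

  set.seed(12)
  r <- 2^runif(500, -3, 3)
  rt2 <- make_ratio_table(r)
  got <- select_responsive_genes(rt2, 2)
  want <- rt2$gene_id[vapply(r, function(x) x > 2 || x < 0.5, logical(1))]
  expect_identical(got, want)
  expect_error(select_responsive_genes(rt2, 1), class = "revtraj_error_bad_input")
})

test_that("trajectory categories match an independent rule evaluation", {
  cfg <- classification_config()
  mk <- function(d1, d2) {
    g <- sprintf("g%05d", seq_along(d1))
    classify_trajectory(make_ratio_table(2^d1, g), make_ratio_table(2^d2, g),
                        config = cfg, genes = g)
  }
  expect_identical(mk(2, 2)$category, "consistent")
  expect_identical(mk(2, -2)$category, "opposite")
  expect_identical(mk(3.5, 2)$category, "over_regulated")
  expect_identical(mk(2, 0.5)$category, "un_necessary")

  set.seed(17)
  n <- 10000
  d1 <- runif(n, -4, 4)
  d2 <- runif(n, -4, 4)
  got <- mk(d1, d2)
  expect_identical(got$category, oracle_trajectory(d1, d2, cfg))

  # sign symmetry: negating all changes leaves every category unchanged
  expect_identical(mk(-d1, -d2)$category, got$category)

  # genes missing from a table become unclassified
  g <- c("a", "b")
  lab <- classify_trajectory(make_ratio_table(c(4, 4), g),
                             make_ratio_table(4, "a"),
                             config = cfg, genes = g)
  expect_identical(lab$category, c("consistent", "unclassified"))
})

test_that("favorability report counts, percentages and pooling are correct", {
  labels <- trajectory_labels_from_counts(list(
    consistent = 693, opposite = 572, un_necessary = 572,
    over_regulated = 203, unclassified = 168))
  rep <- favorability_report(labels)
  expect_identical(rep$total_genes, 2208L)
  expect_equal(rep$percentages$consistent, 31)
  expect_equal(rep$opposite_or_unnecessary$count, 1144L)
  expect_equal(rep$opposite_or_unnecessary$percentage, 52)
  expect_equal(rep$percentages$over_regulated, 9)
  expect_equal(rep$unfavorable_count, 1347L)
  expect_equal(rep$unfavorable_percentage, 61)

  all_cons <- trajectory_labels_from_counts(list(consistent = 50))
  expect_equal(favorability_report(all_cons)$unfavorable_percentage, 0)

  set.seed(23)
  cats <- sample(c("consistent", "un_necessary", "opposite",
                   "over_regulated", "unclassified"), 500, replace = TRUE)
  labs <- trajectory_labels_from_counts(as.list(table(cats)))
  r <- favorability_report(labs)
  for (k in names(r$counts))
    expect_identical(r$counts[[k]], sum(cats == k))
  expect_identical(Reduce(`+`, r$counts), 500L)

  expect_error(favorability_report(trajectory_labels_from_counts(list())),
               class = "revtraj_error_empty_input")
})

test_that("time-course unfavorable percentages track the programmed dynamics", {
  # single time point reduces to classify + report
  set.seed(6)
  g <- sprintf("g%04d", 1:300)
  r1 <- make_ratio_table(2^runif(300, -3, 3), g)
  r2 <- make_ratio_table(2^runif(300, -3, 3), g)
  tc <- timecourse_unfavorable(list(t1 = r1), r2)
  direct <- favorability_report(classify_trajectory(r1, r2))
  expect_equal(tc$reports$t1$counts, direct$counts)
  expect_equal(tc$summary$unfavorable_percentage, direct$unfavorable_percentage)

  # convergence of the perturbation onto the endpoint forces consistency
  d2 <- runif(300, 1.5, 3) * sample(c(-1, 1), 300, TRUE)
  conv <- timecourse_unfavorable(
    list(early = make_ratio_table(2^(-d2), g),
         late = make_ratio_table(2^d2, g)),
    make_ratio_table(2^d2, g))
  expect_equal(conv$summary$unfavorable_percentage, c(100, 0))

  # programmed rise-then-fall of transient changes: the unfavorable
  # percentage peaks at the generator's programmed peak time
  tp <- paste0("d", 1:7)
  sim <- simulate_expression(generator_config(n_genes = 2000, seed = 3,
                                              timepoints = tp))
  programmed_peak <- which.max(sim$config$transient_profile)
  md <- filter_detectable(sim$matrix)
  series <- lapply(paste0("perturbed_", tp),
                   function(cn) compute_ratio(md, cn, "baseline"))
  names(series) <- tp
  r2s <- compute_ratio(md, "endpoint", "baseline")
  r3s <- compute_ratio(md, "pre_endpoint", "endpoint")
  tcs <- timecourse_unfavorable(series, r2s, r3s)
  expect_identical(which.max(tcs$summary$unfavorable_percentage),
                   as.integer(programmed_peak))
  # and decreases monotonically after the peak
  after <- tcs$summary$unfavorable_percentage[programmed_peak:7]
  expect_true(all(diff(after) <= 0))

  expect_error(
    timecourse_unfavorable(list(a = r1, b = make_ratio_table(1:3)), r2),
    class = "revtraj_error_gene_mismatch")
})
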