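test_that("TSV round-trip preserves the matrix and its identifiers", {
  m <- fixture_matrix()
  path <- write_fixture_tsv(m)
  m2 <- read_expr_matrix(path)
  expect_s3_class(m2, "expr_matrix")
  expect_identical(dim(m2), c(3L, 3L))
  expect_identical(rownames(m2), rownames(m))
  expect_identical(colnames(m2), colnames(m))
  expect_equal(unclass(m2), unclass(m))

  big <- random_matrix(200, seed = 7)
  p2 <- write_fixture_tsv(big)
  expect_equal(unclass(read_expr_matrix(p2)), unclass(big), tolerance = 1e-12)
})

test_that("matrix validation rejects malformed inputs with named errors", {
  expect_error(read_expr_matrix("no/such/file.tsv"),
               class = "revtraj_error_missing_file")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tMEF\tOKS", "Actb\t1\t2", "Actb\t3\t4"), path)
  expect_error(read_expr_matrix(path), class = "revtraj_error_duplicate_id")

  writeLines(c("gene_id\tMEF\tOKS", "Actb\t1\tlow"), path)
  expect_error(read_expr_matrix(path), class = "revtraj_error_non_numeric")

  writeLines(c("gene_id\tMEF\tOKS", "Actb\t1\t-2"), path)
  expect_error(read_expr_matrix(path), class = "revtraj_error_bad_value")

  writeLines("gene_id\tMEF", path)
  expect_error(read_expr_matrix(path), class = "revtraj_error_empty_matrix")

  m <- unclass(fixture_matrix())
  m[1, 1] <- NA
  expect_error(expr_matrix(m), class = "revtraj_error_bad_value")
})

test_that("detectability filter matches a per-gene scan and is idempotent", {
  m <- expr_matrix(matrix(c(0, 0, 0,
                            5, 0, 0),
                          nrow = 2, byrow = TRUE,
                          dimnames = list(c("off", "on"), c("a", "b", "c"))))
  kept <- filter_detectable(m, min_tpm = 1, min_conditions = 1)
  expect_identical(rownames(kept), "on")
  expect_identical(rownames(filter_detectable(m, min_tpm = 0)),
                   rownames(m))

  big <- random_matrix(100, seed = 11)
  for (mc in 1:2) {
    f <- filter_detectable(big, min_tpm = 5, min_conditions = mc)
    # brute-force per-gene scan oracle
    expected <- rownames(big)[vapply(seq_len(nrow(big)), function(i)
      sum(unclass(big)[i, ] >= 5) >= mc, logical(1))]
    expect_identical(rownames(f), expected)
    expect_identical(colnames(f), colnames(big))
    f2 <- filter_detectable(f, min_tpm = 5, min_conditions = mc)
    expect_equal(unclass(f2), unclass(f))
  }

  expect_warning(filter_detectable(big, min_tpm = 1e9),
                 "no genes pass")
})

test_that("pseudo-counted ratios are correct, antisymmetric and monotone", {
  m <- expr_matrix(matrix(c(10, 10,
                            4, 1),
                          nrow = 2, byrow = TRUE,
                          dimnames = list(c("flat", "up"), c("den", "num"))))
  rt <- compute_ratio(m, "num", "den", pseudocount = 1)
  expect_equal(rt$ratio[1], 1)
  expect_equal(rt$log2_ratio[1], 0)
  rt0 <- compute_ratio(m, "num", "den", pseudocount = 0)
  expect_equal(rt0$ratio[2], 1 / 4)
  expect_equal(rt0$log2_ratio[2], -2)

  big <- random_matrix(50, seed = 3)
  ab <- compute_ratio(big, "MEF", "OKS")
  ba <- compute_ratio(big, "OKS", "MEF")
  expect_equal(ab$log2_ratio, -ba$log2_ratio, tolerance = 1e-12)
  expect_identical(ab$gene_id, rownames(big))
  expect_true(all(ab$ratio > 0))
  expect_equal(ab$log2_ratio, log2(ab$ratio))

  # strict monotonicity in numerator and denominator values
  set.seed(5)
  for (i in 1:20) {
    x <- runif(2, 0, 50)
    p <- runif(1, 0.1, 2)
    delta <- runif(1, 0.1, 5)
    expect_gt((x[1] + delta + p) / (x[2] + p), (x[1] + p) / (x[2] + p))
    m2 <- expr_matrix(matrix(c(x[1], x[2], x[2] + delta),
                             nrow = 1,
                             dimnames = list("g", c("n", "d1", "d2"))))
    expect_lt(compute_ratio(m2, "n", "d2", p)$ratio,
              compute_ratio(m2, "n", "d1", p)$ratio)
  }

  expect_error(compute_ratio(big, "nope", "MEF"),
               class = "revtraj_error_unknown_condition")
  zero <- expr_matrix(matrix(c(1, 0), nrow = 1,
                             dimnames = list("g", c("n", "d"))))
  expect_error(compute_ratio(zero, "n", "d", pseudocount = 0),
               class = "revtraj_error_zero_denominator")
})

test_that("GMT parsing preserves membership and round-trips", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines("OX\tKEGG:00190\tNdufa1\tCox5a", path)
  sets <- read_gmt(path)
  expect_length(sets, 1)
  expect_identical(sets$OX$members, c("Ndufa1", "Cox5a"))

  fixture <- system.file("extdata", "kegg_ox_glycolysis_synthetic.gmt",
                         package = "revtraj")
  sets <- read_gmt(fixture)
  expect_length(sets$OX_synthetic$members, 116)
  expect_length(sets$glycolysis_synthetic$members, 60)

  set.seed(9)
  rand_sets <- lapply(1:5, function(i) {
    structure(list(name = paste0("set", i), description = "random",
                   members = sprintf("g%03d", sample.int(500, sample(3:30, 1)))),
              class = "gene_set")
  })
  names(rand_sets) <- vapply(rand_sets, `[[`, character(1), "name")
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(rand_sets, p2)
  expect_equal(read_gmt(p2), rand_sets)

  writeLines("OX\tonly-two-fields", path)
  expect_error(read_gmt(path), class = "revtraj_error_malformed_line")
  writeLines(character(0), path)
  expect_error(read_gmt(path), class = "revtraj_error_empty_file")
})

test_that("condition averaging collapses replicate columns", {
  m <- random_matrix(20, conditions = c("a1", "a2", "b"), seed = 2)
  avg <- average_conditions(m, list(a = c("a1", "a2"), b = "b"))
  expect_identical(colnames(avg), c("a", "b"))
  expect_equal(avg[, "a"], (unclass(m)[, "a1"] + unclass(m)[, "a2"]) / 2)
  expect_error(average_conditions(m, list(x = "missing")),
               class = "revtraj_error_unknown_condition")
})
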