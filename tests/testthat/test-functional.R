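test_that("super-class classification follows the COG letter sets", {
  expect_equal(classify_super_class(c("J", "E", "KT", "")),
               c("informational", "operational", "mixed", "unassigned"))
  expect_equal(classify_super_class("AKL"), "informational")
  expect_equal(classify_super_class("ji"), "mixed")
  expect_equal(classify_super_class(NA_character_), "unassigned")
  # classification is total over single letters: no letter is in both sets
  single <- classify_super_class(LETTERS)
  expect_true(all(single %in% c("informational", "operational")))
  expect_equal(sum(single == "informational"), 5L)
  # L's membership is configurable
  expect_equal(classify_super_class("L"), "informational")
  expect_equal(classify_super_class("L", l_superclass = "operational"),
               "operational")
})

test_that("annotation and location tables are read tolerantly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tcog_id\tletters\tdescription",
               "p1\tCOG0001\tJ\tribosomal protein",
               "p2\tCOG0002\tE\tamino-acid transport",
               "p3\tCOG0003\tKT\ttwo categories"), path)
  ann <- read_annotation(path)
  expect_equal(ann$id, c("p1", "p2", "p3"))
  expect_equal(ann$super_class, c("informational", "operational", "mixed"))
  # two-column dialect without header
  writeLines(c("p1\tJ", "p2\tE"), path)
  ann2 <- read_annotation(path)
  expect_equal(ann2$super_class, c("informational", "operational"))

  loc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\tCytoplasmic", "p2\tCytoplasmic Membrane",
               "p3\tExtracellular"), loc)
  ldf <- read_locations(loc)
  expect_equal(ldf$location,
               c("cytoplasmic", "cytoplasmic membrane", "other"))
})

test_that("the two-group t-test matches the pooled-variance oracle", {
  set.seed(22)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1), mean = -0.4, sd = 0.3)
    y <- rnorm(sample(5:40, 1), mean = -0.05, sd = 0.3)
    res <- compare_metric(x, y, "gravy")
    ref <- ttest_brute(x, y)
    expect_equal(res$t, ref$t, tolerance = 1e-12)
    expect_equal(res$p, ref$p, tolerance = 1e-12)
    expect_equal(res$mean_informational, mean(x))
  }
})

test_that("group comparison is antisymmetric and handles degenerate input", {
  set.seed(23)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  ab <- compare_metric(x, y)
  ba <- compare_metric(y, x)
  expect_equal(ab$t, -ba$t, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- compare_metric(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # constant but different groups: undefined, flagged
  deg <- compare_metric(c(1, 1), c(2, 2))
  expect_true(is.na(deg$t))
  expect_match(deg$note, "degenerate")
  expect_error(compare_metric(1, rnorm(5)), "at least 2")
})

test_that("well-separated synthetic groups give the expected direction", {
  set.seed(31)
  info <- rnorm(500, mean = -0.4, sd = 0.3)
  op <- rnorm(500, mean = -0.05, sd = 0.3)
  res <- compare_metric(info, op, "gravy")
  expect_lt(res$mean_informational, res$mean_operational)
  expect_lt(res$p, 1e-10)
})

test_that("Welch's variant is available behind the flag", {
  set.seed(24)
  x <- rnorm(20, sd = 2); y <- rnorm(40, 1, sd = 0.3)
  welch <- compare_metric(x, y, var_equal = FALSE)
  ref <- t.test(x, y)
  expect_equal(welch$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(welch$p, ref$p.value, tolerance = 1e-12)
})

test_that("location chi-square matches the explicit formula and edge cases", {
  set.seed(33)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 40) + 1, 2)
    res <- location_chi2(tab)
    ref <- chisq_brute(tab)
    expect_equal(res$chi2, ref$chi2, tolerance = 1e-12)
    expect_equal(res$p, ref$p, tolerance = 1e-12)
  }
  # proportional rows: no association at all
  prop <- location_chi2(matrix(c(10, 10, 20, 20), 2, byrow = TRUE))
  expect_equal(prop$chi2, 0)
  expect_equal(prop$p, 1)
  # zero margin: undefined
  zero <- location_chi2(matrix(c(0, 0, 5, 7), 2, byrow = TRUE))
  expect_true(zero$degenerate)
  expect_true(is.na(zero$p))
  expect_error(location_chi2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(location_chi2(matrix(1:6, 2)), "2x2")
})

test_that("compare_super_classes joins metrics with annotations", {
  sim <- simulate_genome(sim_config(n_genes = 300, len_mean = 150,
                                    seed = 41))
  m <- gene_metrics(sim$genes)
  cmp <- compare_super_classes(m, sim$annotation)
  expect_equal(cmp$metric, c("gravy", "t2_a2"))
  expect_equal(cmp$n_informational + cmp$n_operational,
               rep(nrow(sim$genes), 2))
  expect_error(compare_super_classes(m,
    data.frame(id = "zzz", super_class = "informational")), "overlap")
})
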