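test_that("the catalogue report writes the full tables with manifests", {
  dir <- withr::local_tempdir()
  res <- run_catalogue(dir)
  expect_equal(nrow(read_assoc_table(res$paths[["catalogue"]])), 2886L)
  expect_equal(nrow(read_assoc_table(res$paths[["best"]])), 39L)
  expect_equal(nrow(res$summary), 13L)
  manifest <- jsonlite::read_json(file.path(dir, "catalogue.manifest.json"))
  expect_equal(manifest$subcommand, "catalogue")
  expect_true(all(file.exists(unlist(manifest$outputs))))
})

test_that("restricted catalogue runs honour property and position filters", {
  dir <- withr::local_tempdir()
  one <- run_catalogue(dir, properties = "hydropathy index")
  expect_equal(nrow(one$catalogue), 222L)
  two <- run_catalogue(dir, properties = "hydropathy index", positions = 2)
  expect_equal(nrow(two$catalogue), 74L)
  expect_error(run_catalogue(dir, properties = "nope"), "unknown property")
})

test_that("the genome report recovers the strong synthetic association", {
  dir <- withr::local_tempdir()
  sim_dir <- withr::local_tempdir()
  paths <- write_simulation(
    simulate_genome(sim_config(n_genes = 700, len_mean = 200, seed = 7)),
    sim_dir)
  res <- run_genome(paths[["genes"]], dir)
  expect_equal(nrow(res$summaries), 1L)
  expect_gt(res$summaries$r, 0.9)
  expect_lt(res$summaries$r, 1.0)
  # two identical inputs give identical summaries and a cumulative table
  f2 <- file.path(sim_dir, "copy.ffn")
  file.copy(paths[["genes"]], f2)
  multi <- run_genome(c(paths[["genes"]], f2), dir)
  expect_equal(multi$summaries$r[1], multi$summaries$r[2])
  expect_true(file.exists(multi$paths[["cumulative"]]))
})

test_that("single-gene input fails the minimum-gene threshold", {
  dir <- withr::local_tempdir()
  one <- local_fasta(c(g1 = "ATGAAATTTTAA"))
  expect_error(run_genome(one, dir), "at least 3")
})

test_that("the comparison report reproduces the super-class contrast", {
  sim_dir <- withr::local_tempdir()
  out <- withr::local_tempdir()
  paths <- write_simulation(
    simulate_genome(sim_config(n_genes = 600, len_mean = 200, seed = 9)),
    sim_dir)
  res <- run_compare(paths[["genes"]], paths[["annotation"]], out,
                     location_path = paths[["locations"]])
  cmp <- res$comparison
  gr <- cmp[cmp$metric == "gravy", ]
  expect_lt(gr$mean_informational, gr$mean_operational)
  expect_lt(gr$p, 0.05)
  expect_false(is.null(res$chi2))
  expect_true(file.exists(res$paths[["location"]]))
  # swapping groups negates t and preserves p
  swapped <- run_compare(paths[["genes"]], paths[["annotation"]], out,
                         swap_groups = TRUE)
  expect_equal(swapped$comparison$t, -cmp$t, tolerance = 1e-12)
  expect_equal(swapped$comparison$p, cmp$p, tolerance = 1e-12)
})

test_that("comparison fails cleanly when annotations do not match", {
  sim_dir <- withr::local_tempdir()
  out <- withr::local_tempdir()
  paths <- write_simulation(
    simulate_genome(sim_config(n_genes = 50, seed = 2)), sim_dir)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("unknown1\tJ", bad)
  expect_error(run_compare(paths[["genes"]], bad, out), "overlap")
})

test_that("run_simulate writes the three artifacts plus manifest", {
  out <- withr::local_tempdir()
  sim <- run_simulate(out, n_genes = 40, seed = 12)
  expect_true(all(file.exists(sim$paths)))
  expect_true(file.exists(file.path(out, "simulate.manifest.json")))
  expect_equal(nrow(sim$genes), 40L)
})
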