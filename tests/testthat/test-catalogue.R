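test_that("pearson_assoc matches the explicit-formula oracle on random pairs", {
  set.seed(101)
  scales <- load_all_scales()
  aas <- amino_acids()
  for (i in 1:50) {
    pos <- sample(1:3, 1)
    a <- sample(enumerate_assignments(pos), 1)[[1]]
    sc <- scales[[sample(13, 1)]]
    rec <- pearson_assoc(a, sc)
    x <- vapply(aas, aa_position_value, numeric(1), assignment = a)
    ref <- pearson_brute(x, sc$values[aas])
    expect_equal(rec$r, ref$r, tolerance = 1e-12)
    expect_equal(rec$p, ref$p, tolerance = 1e-12)
    expect_equal(rec$n, 20L)
  }
})

test_that("negating an assignment negates r and preserves p", {
  kd <- load_property_scale("hydropathy index")
  for (a in enumerate_assignments(2)[c(3, 17, 40, 70)]) {
    neg <- find_assignment(2, format_assignment(-a$values))
    r1 <- pearson_assoc(a, kd)
    r2 <- pearson_assoc(neg, kd)
    expect_equal(r1$r, -r2$r, tolerance = 1e-12)
    expect_equal(r1$p, r2$p, tolerance = 1e-12)
  }
})

test_that("r is invariant (up to sign) under affine rescaling of the scale", {
  kd <- load_property_scale("hydropathy index")
  a <- find_assignment(2, "A:-1,T:1,GC:0")
  r0 <- pearson_assoc(a, kd)$r
  up <- make_scale(3.2 * kd$values + 11)
  down <- make_scale(-0.7 * kd$values + 2)
  expect_equal(pearson_assoc(a, up)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_assoc(a, down)$r, -r0, tolerance = 1e-12)
})

test_that("a constant scale yields a degenerate record", {
  # zero variance on the property side is the realizable degenerate case
  # (every enumerated assignment varies over realized nucleotides)
  flat <- make_scale(setNames(rep(1, 20), amino_acids()))
  a <- find_assignment(2, "A:-1,T:1,GC:0")
  rec <- suppressWarnings(pearson_assoc(a, flat))
  expect_true(is.na(rec$r))
})

test_that("the full catalogue has 2886 deterministic records", {
  ctl <- build_catalogue()
  expect_equal(nrow(ctl), 2886L)
  expect_equal(nrow(build_catalogue(load_all_scales()["hydropathy index"])),
               222L)
  expect_equal(nrow(build_catalogue(list())), 0L)
  # deterministic: rebuilding gives identical rows
  expect_identical(ctl, build_catalogue())
  # catalogue r/p agree with the single-record route
  idx <- c(5L, 333L, 1500L, 2886L)
  for (i in idx) {
    a <- find_assignment(ctl$position[i], ctl$assignment[i])
    sc <- load_property_scale(ctl$property[i])
    rec <- pearson_assoc(a, sc)
    expect_equal(ctl$r[i], rec$r, tolerance = 1e-12)
    expect_equal(ctl$p[i], rec$p, tolerance = 1e-12)
  }
})

test_that("best-per-cell picks 39 positively oriented maxima", {
  ctl <- build_catalogue()
  best <- best_per_cell(ctl)
  expect_equal(nrow(best), 39L)
  expect_true(all(best$r > 0))
  # each cell's r is the max |r| in the catalogue cell, invariant to
  # orientation by construction
  for (i in c(1L, 10L, 25L, 39L)) {
    cell <- ctl[ctl$property == best$property[i] &
                  ctl$position == best$position[i] & !ctl$degenerate, ]
    expect_equal(best$r[i], max(abs(cell$r)), tolerance = 1e-12)
  }
  # the hydropathy/position-2 winner is the classic middle-base scheme
  hyd2 <- best[best$property == "hydropathy index" & best$position == 2, ]
  expect_equal(hyd2$assignment, "A:-1,CG:0,T:1")
  expect_equal(hyd2$r, 0.8635, tolerance = 1e-4)
})

test_that("the second position dominates among the well-sourced properties", {
  # of the scales with unambiguous published values, hydropathy, polarity,
  # polar requirement, composition and molecular volume peak at position 2
  best <- best_per_cell(build_catalogue())
  winners <- vapply(split(best, best$property), function(df) {
    df$position[which.max(df$r)]
  }, integer(1))
  for (nm in c("hydropathy index", "polarity", "polar requirement",
               "chemical composition of the side chain",
               "molecular volume")) {
    expect_equal(unname(winners[nm]), 2L, label = nm)
  }
})

test_that("combined association behaves like an OLS multiple correlation", {
  best <- best_per_cell(build_catalogue())
  comb <- combined_assoc("hydropathy index", best)
  # combined R^2 can never fall below the best single position's r^2
  hyd <- best[best$property == "hydropathy index", ]
  expect_gte(comb$r2 + 1e-12, max(hyd$r)^2)
  expect_true(comb$r >= 0 && comb$r <= 1)
  expect_error(combined_assoc("hydropathy index", hyd[1:2, ]),
               "three per-position winners")
})

test_that("association tables round-trip through TSV", {
  ctl <- build_catalogue(load_all_scales()["polarity"], positions = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assoc_table(ctl, path)
  back <- read_assoc_table(path)
  expect_equal(back$assignment, ctl$assignment)
  expect_equal(back$r, ctl$r, tolerance = 1e-12)
})
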