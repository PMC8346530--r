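test_that("CDS FASTA reading normalizes headers and sequences", {
  path <- local_fasta(c("g1 some description" = "atgaaattt",
                        "g2" = "AUGUUUUAA"))
  df <- read_cds_fasta(path)
  expect_equal(df$id, c("g1", "g2"))
  expect_equal(df$cds, c("ATGAAATTT", "ATGTTTTAA"))
  expect_equal(nchar(df$cds), c(9L, 9L))
  empty <- withr::local_tempfile(fileext = ".ffn")
  file.create(empty)
  expect_warning(e <- read_cds_fasta(empty), "empty")
  expect_equal(nrow(e), 0L)
  expect_error(read_cds_fasta(file.path(tempdir(), "nope.ffn")), "no such file")
})

test_that("t2_a2 counts second-position T and A over sense codons", {
  expect_equal(t2_a2("ATGAAATTT"), 1 / 3)
  # trailing stop excluded
  expect_equal(t2_a2("ATGAAATTTTAA"), t2_a2("ATGAAATTT"))
  # (GCx)^k has C at every second position
  expect_equal(t2_a2(strrep("GCA", 7)), 0)
  # extremes: all-T2 and all-A2 genes
  expect_equal(t2_a2(strrep("ATG", 5)), 1)
  expect_equal(t2_a2(strrep("GAT", 5)), -1)
  # N codons are skipped in numerator and denominator
  expect_equal(t2_a2("ATGNNNAAA"), 0)
  # internal stop invalidates by default
  expect_true(is.na(t2_a2("ATGTAATTTTAA")))
  expect_equal(t2_a2("ATGTAATTTTAA", internal_stop = "truncate"), 1)
})

test_that("gravy is the mean hydropathy with non-standard residues excluded", {
  expect_equal(gravy("MKF"), (1.9 - 3.9 + 2.8) / 3, tolerance = 1e-12)
  expect_equal(gravy(strrep("I", 30)), 4.5)
  expect_equal(gravy("MXKXF"), gravy("MKF"))
  expect_true(is.na(gravy("XXX")))
  expect_true(is.na(gravy("")))
  # permutation invariance and weighted-mean concatenation law
  set.seed(5)
  p <- paste(sample(amino_acids(), 25, replace = TRUE), collapse = "")
  q <- paste(sample(amino_acids(), 40, replace = TRUE), collapse = "")
  perm <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
  expect_equal(gravy(perm), gravy(p), tolerance = 1e-12)
  expect_equal(gravy(paste0(p, q)),
               (25 * gravy(p) + 40 * gravy(q)) / 65, tolerance = 1e-12)
  expect_true(gravy(q) >= -4.5 && gravy(q) <= 4.5)
})

test_that("gene_metrics flags invalid records and fills metrics", {
  genes <- data.frame(
    id = c("ok", "stop", "frame"),
    cds = c("ATGAAATTTTAA", "ATGTAATTTTAA", "ATGAA"),
    stringsAsFactors = FALSE)
  m <- gene_metrics(genes)
  expect_equal(m$valid, c(TRUE, FALSE, FALSE))
  expect_equal(m$n_codons[1], 3L)
  expect_equal(m$t2_a2[1], 1 / 3)
  expect_equal(m$gravy[1], gravy("MKF"))
  expect_match(m$reason[2], "internal stop")
  expect_match(m$reason[3], "frame")
  mt <- gene_metrics(genes, internal_stop = "truncate")
  expect_true(mt$valid[2])
  expect_equal(mt$n_codons[2], 1L)
})

test_that("genome_assoc equals the brute-force Pearson over gene pairs", {
  sim <- simulate_genome(sim_config(n_genes = 120, len_mean = 120,
                                    seed = 11))
  m <- gene_metrics(sim$genes)
  ga <- suppressWarnings(genome_assoc(m, genome = "sim"))
  ref <- pearson_brute(m$t2_a2[m$valid], m$gravy[m$valid])
  expect_equal(ga$r, ref$r, tolerance = 1e-12)
  expect_equal(ga$p, ref$p, tolerance = 1e-12)
  expect_equal(ga$n_genes, sum(m$valid))
  expect_warning(genome_assoc(m), "fewer than 500")
})

test_that("genome_assoc guards degenerate inputs", {
  same <- data.frame(id = c("a", "b", "c"),
                     cds = rep("ATGAAATTT", 3), stringsAsFactors = FALSE)
  m <- gene_metrics(same)
  ga <- suppressWarnings(genome_assoc(m))
  expect_true(is.na(ga$r))
  expect_error(suppressWarnings(genome_assoc(m[1:2, ])), "at least 3")
})

test_that("translation cross-check reports mismatching proteins", {
  genes <- data.frame(id = c("g1", "g2"),
                      cds = c("ATGAAATTT", "ATGTTT"),
                      stringsAsFactors = FALSE)
  faa <- local_fasta(c(g1 = "MKF", g2 = "MW"))
  expect_equal(check_against_proteins(genes, faa), "g2")
})

test_that("the cumulative-proportion table counts genomes above thresholds", {
  summaries <- data.frame(r = c(0.95, 0.92, 0.85, NA))
  tab <- r_cumulative_table(summaries, thresholds = c(0.8, 0.9))
  expect_equal(tab$n_above, c(3L, 2L))
  expect_equal(tab$proportion, c(1, 2 / 3))
})
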