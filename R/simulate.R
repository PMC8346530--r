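#' Configuration for the synthetic genome simulator
#'
#' The generator emulates one genome's worth of coding sequences with a
#' controllable second-codon-position composition structure. Each gene g gets
#' a bias parameter beta_g in \[-1, 1\]: its codons are drawn uniformly from
#' the 61 sense codons, except that with probability |beta_g| a codon is
#' forced to carry T (beta_g > 0) or A (beta_g < 0) at the second position.
#' beta_g = +1 therefore forces T at every second position (t2_a2 = 1), and
#' beta_g = -1 forces A. A fraction of genes is labelled informational and
#' has its bias shifted by `delta` (negative: A2-enriched, hence more
#' hydrophilic), the rest operational; subcellular-location labels correlate
#' with the super-class through the two `p_cyto_*` probabilities.
#'
#' @param n_genes Number of genes.
#' @param len_min,len_mean,len_max Gene length distribution in codons
#'   (gamma-distributed around `len_mean`, clamped to
#'   `[len_min, len_max]`; minimum 10).
#' @param beta_mean,beta_sd Per-gene bias beta drawn from
#'   Normal(`beta_mean`, `beta_sd`) and truncated to \[-1, 1\];
#'   `beta_sd = 0` gives every gene the same bias.
#' @param frac_informational Fraction of genes labelled informational.
#' @param delta Additive bias shift for informational genes (< 0 enriches A
#'   at the second position).
#' @param p_cyto_informational,p_cyto_operational Probability that a gene of
#'   each super-class is labelled cytoplasmic (otherwise cytoplasmic
#'   membrane).
#' @param seed Mandatory integer seed; identical configurations reproduce
#'   byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, len_min = 50L, len_mean = 300L,
                       len_max = 1500L, beta_mean = 0, beta_sd = 0.25,
                       frac_informational = 0.2, delta = -0.1,
                       p_cyto_informational = 0.984,
                       p_cyto_operational = 0.755, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility",
                          call. = FALSE)
  cfg <- list(n_genes = as.integer(n_genes), len_min = as.integer(len_min),
              len_mean = len_mean, len_max = as.integer(len_max),
              beta_mean = beta_mean, beta_sd = beta_sd,
              frac_informational = frac_informational, delta = delta,
              p_cyto_informational = p_cyto_informational,
              p_cyto_operational = p_cyto_operational,
              seed = as.integer(seed))
  probs <- c(cfg$frac_informational, cfg$p_cyto_informational,
             cfg$p_cyto_operational)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_genes < 1L) stop("n_genes must be positive", call. = FALSE)
  if (cfg$len_min < 10L || cfg$len_min > cfg$len_max ||
      cfg$len_mean < cfg$len_min || cfg$len_mean > cfg$len_max) {
    stop("need 10 <= len_min <= len_mean <= len_max", call. = FALSE)
  }
  if (abs(cfg$beta_mean) > 1 || cfg$beta_sd < 0) {
    stop("beta_mean in [-1, 1] and beta_sd >= 0 required", call. = FALSE)
  }
  if (abs(cfg$beta_mean + cfg$delta) > 1) {
    stop("beta_mean + delta must stay in [-1, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Expected T2-A2 under a given bias
#'
#' Closed form implied by the simulator's mixture construction: a body codon
#' contributes beta + (1 - |beta|) * 2/61 in expectation (2/61 is the T2
#' excess among the 61 sense codons under uniform sampling), and the fixed
#' ATG start codon contributes +1.
#'
#' @param beta Bias parameter in \[-1, 1\].
#' @param n_codons Gene length in sense codons (including the ATG start);
#'   `Inf` gives the body-only limit.
#' @return Expected value of [t2_a2()] for a simulated gene.
#' @export
expected_t2a2 <- function(beta, n_codons = Inf) {
  body <- beta + (1 - abs(beta)) * 2 / 61
  ifelse(is.infinite(n_codons), body,
         ((n_codons - 1) * body + 1) / n_codons)
}

#' Simulate a synthetic annotated genome
#'
#' Draws coding genes codon-by-codon from the 61 sense codons (no internal
#' stops by construction; every gene starts with ATG and ends with a stop
#' codon), with the per-gene second-position bias described in
#' [sim_config()], and emits matching functional-annotation and
#' subcellular-location tables in the same dialects the real-data readers
#' consume.
#'
#' @param config A `sim_config`.
#' @return A list with `genes` (data.frame `id`, `cds`), `annotation`
#'   (data.frame `id`, `cog_id`, `letters`, `description`, `super_class`),
#'   `locations` (data.frame `id`, `label`), `beta` (per-gene bias used) and
#'   `config`.
#' @examples
#' sim <- simulate_genome(sim_config(n_genes = 20, seed = 1))
#' nrow(sim$genes)  # 20
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_genome_impl(config))
}

.simulate_genome_impl <- function(config) {
  code <- genetic_code()
  sense <- names(code$codon_to_aa)
  t2_set <- sense[substr(sense, 2, 2) == "T"]
  a2_set <- sense[substr(sense, 2, 2) == "A"]
  n <- config$n_genes

  informational <- stats::runif(n) < config$frac_informational
  beta <- stats::rnorm(n, config$beta_mean, config$beta_sd)
  beta[informational] <- beta[informational] + config$delta
  beta <- pmin(1, pmax(-1, beta))

  # gene lengths in codons: gamma around the mean, clamped
  shape <- 4
  lens <- round(stats::rgamma(n, shape = shape,
                              scale = config$len_mean / shape))
  lens <- pmin(config$len_max, pmax(config$len_min, lens))

  cds <- character(n)
  for (i in seq_len(n)) {
    nb <- lens[i] - 1L  # body codons after the ATG start
    body <- sample(sense, nb, replace = TRUE)
    forced <- stats::runif(nb) < abs(beta[i])
    nf <- sum(forced)
    if (nf > 0L) {
      pool <- if (beta[i] > 0) t2_set else a2_set
      body[forced] <- sample(pool, nf, replace = TRUE)
    }
    stop_codon <- sample(code$stop_codons, 1L)
    cds[i] <- paste(c("ATG", body, stop_codon), collapse = "")
  }

  ids <- sprintf("gene%05d", seq_len(n))
  sets <- superclass_sets("informational")
  letters_vec <- character(n)
  letters_vec[informational] <- sample(sets$informational,
                                       sum(informational), replace = TRUE)
  letters_vec[!informational] <- sample(sets$operational,
                                        sum(!informational), replace = TRUE)
  annotation <- data.frame(
    id = ids,
    cog_id = sprintf("COG%04d", seq_len(n)),
    letters = letters_vec,
    description = "synthetic annotation",
    super_class = ifelse(informational, "informational", "operational"),
    stringsAsFactors = FALSE)

  p_cyto <- ifelse(informational, config$p_cyto_informational,
                   config$p_cyto_operational)
  locations <- data.frame(
    id = ids,
    label = ifelse(stats::runif(n) < p_cyto, "Cytoplasmic",
                   "Cytoplasmic Membrane"),
    stringsAsFactors = FALSE)

  list(genes = data.frame(id = ids, cds = cds, stringsAsFactors = FALSE),
       annotation = annotation, locations = locations, beta = beta,
       config = config)
}

#' Write a simulated genome to disk
#'
#' Emits `genes.ffn` (CDS FASTA), `annotation.tsv` (id, cog_id, letters,
#' description) and `locations.tsv` (id, label) under `out_dir` — the same
#' dialects [read_cds_fasta()], [read_annotation()] and [read_locations()]
#' consume.
#'
#' @param sim Output of [simulate_genome()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes = file.path(out_dir, "genes.ffn"),
             annotation = file.path(out_dir, "annotation.tsv"),
             locations = file.path(out_dir, "locations.tsv"))
  write_fasta(sim$genes, paths[["genes"]])
  utils::write.table(sim$annotation[c("id", "cog_id", "letters",
                                      "description")],
                     paths[["annotation"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$locations, paths[["locations"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
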