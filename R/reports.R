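# Every report writer drops a JSON manifest next to its outputs so each file
# is traceable to the command, inputs, parameters and package version that
# produced it.
write_manifest <- function(out_dir, subcommand, inputs, params,
                           outputs, seed = NULL) {
  manifest <- list(
    subcommand = subcommand,
    inputs = as.list(inputs),
    params = params,
    outputs = as.list(outputs),
    seed = seed,
    tool = "codonassoc",
    version = as.character(utils::packageVersion("codonassoc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, paste0(subcommand, ".manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Compute and write the association catalogue
#'
#' Builds the full (or restricted) catalogue, the strongest-per-cell summary
#' and the wide per-property reporting table, writing each as TSV with a
#' manifest sidecar.
#'
#' @param out_dir Output directory (created if needed).
#' @param properties Property names to include (default: all 13).
#' @param positions Codon positions to include (default 1:3).
#' @return Invisibly, a list with the `catalogue`, `best` and (full runs
#'   only) `summary` data.frames and the output `paths`.
#' @export
run_catalogue <- function(out_dir, properties = property_names(),
                          positions = 1:3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scales <- load_all_scales()[properties]
  if (any(vapply(scales, is.null, logical(1)))) {
    stop("unknown property among: ", paste(properties, collapse = ", "),
         call. = FALSE)
  }
  catalogue <- build_catalogue(scales, positions)
  best <- best_per_cell(catalogue)
  paths <- c(catalogue = file.path(out_dir, "catalogue.tsv"),
             best = file.path(out_dir, "best_per_cell.tsv"))
  write_assoc_table(catalogue, paths[["catalogue"]])
  write_assoc_table(best, paths[["best"]])
  summary_df <- NULL
  if (identical(sort(positions), 1:3)) {
    summary_df <- summarize_catalogue(best, scales)
    paths <- c(paths, summary = file.path(out_dir, "summary.tsv"))
    write_assoc_table(summary_df, paths[["summary"]])
  }
  write_manifest(out_dir, "catalogue", inputs = character(0),
                 params = list(properties = properties,
                               positions = positions),
                 outputs = paths)
  invisible(list(catalogue = catalogue, best = best, summary = summary_df,
                 paths = paths))
}

#' Per-genome T2-A2 / GRAVY association report
#'
#' For each CDS FASTA, computes per-gene metrics and the genome-level
#' correlation between T2-A2 and GRAVY; writes one per-gene TSV per input, a
#' combined per-genome summary TSV and, for multi-genome runs, the
#' cumulative-proportion table of correlation strengths.
#'
#' @param cds_paths Character vector of CDS FASTA paths.
#' @param out_dir Output directory.
#' @param min_genes Minimum valid genes per genome (default 3).
#' @param internal_stop Passed to [gene_metrics()].
#' @return Invisibly, a list with `summaries` (per-genome data.frame),
#'   `per_gene` (list of per-gene data.frames) and `paths`.
#' @export
run_genome <- function(cds_paths, out_dir, min_genes = 3L,
                       internal_stop = "invalid") {
  stopifnot(length(cds_paths) >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_gene <- list()
  summaries <- list()
  paths <- character(0)
  for (path in cds_paths) {
    genome <- tools::file_path_sans_ext(basename(path))
    genes <- read_cds_fasta(path)
    metrics <- gene_metrics(genes, internal_stop)
    gp <- file.path(out_dir, paste0(genome, ".genes.tsv"))
    write_assoc_table(metrics, gp)
    paths <- c(paths, stats::setNames(gp, paste0("genes_", genome)))
    per_gene[[genome]] <- metrics
    summaries[[genome]] <- genome_assoc(metrics, min_genes, genome)
  }
  summaries <- do.call(rbind, summaries)
  sp <- file.path(out_dir, "genome_summary.tsv")
  write_assoc_table(summaries, sp)
  paths <- c(paths, summary = sp)
  if (length(cds_paths) > 1L) {
    cp <- file.path(out_dir, "r_cumulative.tsv")
    write_assoc_table(r_cumulative_table(summaries), cp)
    paths <- c(paths, cumulative = cp)
  }
  write_manifest(out_dir, "genome", inputs = cds_paths,
                 params = list(min_genes = min_genes,
                               internal_stop = internal_stop),
                 outputs = paths)
  invisible(list(summaries = summaries, per_gene = per_gene, paths = paths))
}

#' Informational vs operational comparison report
#'
#' Joins a CDS FASTA with a functional-annotation table, tests GRAVY and
#' T2-A2 between the informational and operational super-classes, and
#' (optionally) runs the 2x2 location chi-square; writes Table-3-style TSVs.
#'
#' @param cds_path CDS FASTA path.
#' @param annotation_path Functional-annotation TSV path.
#' @param out_dir Output directory.
#' @param location_path Optional subcellular-location TSV path.
#' @param var_equal Student's pooled-variance t-test (default `TRUE`);
#'   `FALSE` for Welch.
#' @param l_superclass Super-class of COG letter L (see
#'   [classify_super_class()]).
#' @param swap_groups Swap the two groups (negates t, preserves p).
#' @param internal_stop Passed to [gene_metrics()].
#' @return Invisibly, a list with `comparison` (data.frame), `chi2`
#'   (`location_chi2` or `NULL`) and `paths`.
#' @export
run_compare <- function(cds_path, annotation_path, out_dir,
                        location_path = NULL, var_equal = TRUE,
                        l_superclass = "informational", swap_groups = FALSE,
                        internal_stop = "invalid") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- read_cds_fasta(cds_path)
  metrics <- gene_metrics(genes, internal_stop)
  annotation <- read_annotation(annotation_path, l_superclass)
  comparison <- compare_super_classes(metrics, annotation,
                                      var_equal = var_equal)
  if (swap_groups) {
    comparison <- within(comparison, {
      tmp <- mean_informational
      mean_informational <- mean_operational
      mean_operational <- tmp
      tmp <- n_informational
      n_informational <- n_operational
      n_operational <- tmp
      t <- -t
      rm(tmp)
    })
    names(comparison) <- sub("informational", "group1",
                             sub("operational", "group2", names(comparison)))
  }
  paths <- c(comparison = file.path(out_dir, "comparison.tsv"))
  write_assoc_table(comparison, paths[["comparison"]])
  chi2 <- NULL
  if (!is.null(location_path)) {
    locations <- read_locations(location_path)
    tab <- location_table(annotation, locations)
    chi2 <- location_chi2(tab)
    ldf <- data.frame(
      super_class = rownames(tab)[c(1, 1, 2, 2)],
      location = colnames(tab)[c(1, 2, 1, 2)],
      count = as.vector(t(tab)),
      chi2 = chi2$chi2, p = chi2$p, stringsAsFactors = FALSE)
    paths <- c(paths, location = file.path(out_dir, "location_chi2.tsv"))
    write_assoc_table(ldf, paths[["location"]])
  }
  write_manifest(out_dir, "compare",
                 inputs = c(cds_path, annotation_path, location_path),
                 params = list(var_equal = var_equal,
                               l_superclass = l_superclass,
                               swap_groups = swap_groups,
                               internal_stop = internal_stop),
                 outputs = paths)
  invisible(list(comparison = comparison, chi2 = chi2, paths = paths))
}

#' Simulate a genome and write it to disk
#'
#' Thin wrapper over [simulate_genome()] + [write_simulation()] with a
#' manifest sidecar.
#'
#' @param out_dir Output directory.
#' @param ... Passed to [sim_config()] (a `seed` is mandatory).
#' @return Invisibly, the simulation list with `paths` attached.
#' @export
run_simulate <- function(out_dir, ...) {
  config <- sim_config(...)
  sim <- simulate_genome(config)
  paths <- write_simulation(sim, out_dir)
  write_manifest(out_dir, "simulate", inputs = character(0),
                 params = unclass(config), outputs = paths,
                 seed = config$seed)
  sim$paths <- paths
  invisible(sim)
}

#' Scatter plot of T2-A2 against GRAVY
#'
#' Optional diagnostic plot of the per-gene association underlying a genome
#' summary (base graphics).
#'
#' @param metrics Per-gene data.frame from [gene_metrics()].
#' @param main Plot title.
#' @return The fitted `lm` object, invisibly.
#' @export
plot_t2a2_gravy <- function(metrics, main = "T2-A2 vs GRAVY") {
  ok <- metrics[metrics$valid, ]
  plot(ok$t2_a2, ok$gravy, pch = 16, cex = 0.4,
       col = grDevices::rgb(0, 0, 0, 0.3),
       xlab = expression(T[2] - A[2]), ylab = "GRAVY", main = main)
  fit <- stats::lm(gravy ~ t2_a2, data = ok)
  graphics::abline(fit, col = "red3", lwd = 2)
  invisible(fit)
}
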