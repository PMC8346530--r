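#' Read a CDS FASTA file
#'
#' Reads a nucleotide FASTA of coding sequences (the classic `.ffn` dialect:
#' one record per coding gene, frame 0, optionally with a terminal stop
#' codon). IDs are the first whitespace-delimited token of each header;
#' sequences are upper-cased and U is normalized to T.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `cds`.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA ", sQuote(path), ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(0), cds = character(0)))
  }
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, "", 1L)
  seqs <- chartr("Uu", "Tt", toupper(as.character(set)))
  data.frame(id = unname(ids), cds = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param df Data.frame with columns `id` and a sequence column.
#' @param path Output path.
#' @param seq_col Name of the sequence column (default `"cds"`).
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(df, path, seq_col = "cds", width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(paste0(">", df$id[i]), con)
    s <- df[[seq_col]][i]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

# Sense codons of a CDS: trailing stop trimmed, N codons dropped. Internal
# stops either invalidate (NULL + reason) or truncate.
sense_codons <- function(cds, internal_stop = c("invalid", "truncate")) {
  internal_stop <- match.arg(internal_stop)
  codons <- split_codons(cds)
  code <- genetic_code()
  k <- length(codons)
  if (k > 0L && codons[k] %in% code$stop_codons) codons <- codons[-k]
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  is_stop <- codons %in% code$stop_codons
  if (any(is_stop)) {
    if (internal_stop == "invalid") {
      return(structure(list(), reason = "internal stop codon"))
    }
    codons <- codons[seq_len(which(is_stop)[1] - 1L)]
  }
  codons
}

#' T2-A2 relative frequency difference of a CDS
#'
#' The gene-level summary of the strongest codon-level association: T at the
#' second codon position scores +1, A scores -1, G and C score 0, and the
#' scores are averaged over the gene's sense codons. Equivalently,
#' `(nT2 - nA2) / n_codons`, the difference of the relative frequencies of T
#' and A at the second codon position. The trailing stop codon is excluded
#' and N-containing codons are skipped.
#'
#' @param cds Nucleotide CDS string (frame 0).
#' @param internal_stop `"invalid"` (default) or `"truncate"`, as in
#'   [translate_cds()].
#' @return Numeric in \[-1, 1\], or `NA` (with attribute `reason`) when no
#'   usable codon remains or an internal stop invalidates the record.
#' @examples
#' t2_a2("ATGAAATTT")  # (2 - 1) / 3: second positions T, A, T
#' @export
t2_a2 <- function(cds, internal_stop = c("invalid", "truncate")) {
  codons <- sense_codons(cds, internal_stop)
  if (length(codons) == 0L) {
    reason <- attr(codons, "reason")
    if (is.null(reason)) reason <- "no usable codons"
    return(structure(NA_real_, reason = reason))
  }
  p2 <- substr(codons, 2L, 2L)
  (sum(p2 == "T") - sum(p2 == "A")) / length(codons)
}

#' GRAVY score of a protein
#'
#' Grand Average of Hydropathy: the arithmetic mean of the Kyte-Doolittle
#' hydropathy index over a protein's residues. Residues outside the 20
#' standard letters (e.g. X) are excluded from both numerator and
#' denominator, following the convention of the classic codon-analysis tools.
#'
#' @param protein Amino-acid string.
#' @param scale Hydropathy scale (default: the bundled Kyte-Doolittle index).
#' @return Numeric GRAVY score in \[-4.5, 4.5\], or `NA` if no standard
#'   residue is present.
#' @examples
#' gravy("MKF")  # (1.9 - 3.9 + 2.8) / 3
#' @export
gravy <- function(protein, scale = load_property_scale("hydropathy index")) {
  if (is.na(protein) || !nzchar(protein)) return(NA_real_)
  res <- strsplit(toupper(protein), "")[[1]]
  vals <- scale$values[res]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Per-gene codon-composition metrics
#'
#' Computes, for every CDS, the number of sense codons, the T2-A2 statistic,
#' the translated protein's GRAVY score, and a validity flag. GRAVY is
#' computed from this package's own translation of the CDS so that both
#' metrics share one source of truth; [check_against_proteins()] can
#' cross-check against a supplied protein FASTA.
#'
#' @param genes Data.frame with columns `id` and `cds`
#'   (e.g. from [read_cds_fasta()]).
#' @param internal_stop `"invalid"` drops genes with internal stops (default),
#'   `"truncate"` keeps the prefix before the stop.
#' @return A data.frame with columns `id`, `n_codons`, `t2_a2`, `gravy`,
#'   `valid`, `reason`.
#' @export
gene_metrics <- function(genes, internal_stop = c("invalid", "truncate")) {
  internal_stop <- match.arg(internal_stop)
  stopifnot(is.data.frame(genes), all(c("id", "cds") %in% names(genes)))
  kd <- load_property_scale("hydropathy index")
  out <- lapply(seq_len(nrow(genes)), function(i) {
    cds <- genes$cds[i]
    rec <- data.frame(id = genes$id[i], n_codons = 0L, t2_a2 = NA_real_,
                      gravy = NA_real_, valid = FALSE,
                      reason = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      prot <- translate_cds(cds, internal_stop)
      ta <- t2_a2(cds, internal_stop)
      list(prot = prot, ta = ta)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rec$reason <- res
      return(rec)
    }
    if (!attr(res$prot, "valid") || is.na(res$ta)) {
      rec$reason <- if (!attr(res$prot, "valid")) attr(res$prot, "reason")
                    else attr(res$ta, "reason")
      return(rec)
    }
    rec$n_codons <- attr(res$prot, "n_codons")
    rec$t2_a2 <- as.numeric(res$ta)
    rec$gravy <- gravy(as.character(res$prot), kd)
    rec$valid <- !is.na(rec$gravy)
    if (!rec$valid) rec$reason <- "no standard residues"
    rec
  })
  do.call(rbind, out)
}

#' Cross-check translations against a protein FASTA
#'
#' Compares this package's CDS translations with a supplied `.faa` file and
#' reports mismatching IDs (IDs present in both inputs only).
#'
#' @param genes Data.frame with `id`, `cds`.
#' @param faa_path Path to a protein FASTA.
#' @return Character vector of IDs whose translation differs.
#' @export
check_against_proteins <- function(genes, faa_path) {
  prot <- read_cds_fasta(faa_path)  # same parsing rules; column is the seq
  shared <- intersect(genes$id, prot$id)
  bad <- character(0)
  for (id in shared) {
    ours <- translate_cds(genes$cds[match(id, genes$id)])
    theirs <- sub("\\*$", "", toupper(prot$cds[match(id, prot$id)]))
    if (is.na(ours) || !identical(as.character(ours), theirs)) {
      bad <- c(bad, id)
    }
  }
  bad
}

#' Genome-level association between T2-A2 and GRAVY
#'
#' Pearson correlation, across a genome's valid genes, between the per-gene
#' T2-A2 frequency difference and the GRAVY score, with a two-sided p-value.
#' The association is reported per genome; it is unstable for genomes with
#' few genes, so a warning is issued below 500 genes.
#'
#' @param metrics Per-gene data.frame from [gene_metrics()].
#' @param min_genes Minimum number of valid genes required (default 3).
#' @param genome Genome identifier carried into the summary.
#' @return A one-row data.frame: `genome`, `n_genes` (valid genes used),
#'   `n_invalid`, `r`, `p`. `r` and `p` are `NA` when either metric has zero
#'   variance across genes.
#' @export
genome_assoc <- function(metrics, min_genes = 3L, genome = "genome") {
  ok <- metrics[metrics$valid, ]
  n <- nrow(ok)
  if (n < min_genes) {
    stop("only ", n, " valid genes; need at least ", min_genes, call. = FALSE)
  }
  if (n < 500L) {
    warning("genome has fewer than 500 genes (", n,
            "); the T2-A2/GRAVY association is unstable at small gene counts")
  }
  if (stats::sd(ok$t2_a2) == 0 || stats::sd(ok$gravy) == 0) {
    return(data.frame(genome = genome, n_genes = n,
                      n_invalid = sum(!metrics$valid),
                      r = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
  }
  ct <- stats::cor.test(ok$t2_a2, ok$gravy, method = "pearson")
  data.frame(genome = genome, n_genes = n, n_invalid = sum(!metrics$valid),
             r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
}

#' Cumulative proportion of genomes by correlation strength
#'
#' For a set of per-genome summaries, tabulates the proportion of genomes
#' whose T2-A2/GRAVY correlation exceeds each threshold — the table
#' underlying "X% of genomes have R above 0.9"-style statements.
#'
#' @param summaries Data.frame of [genome_assoc()] rows.
#' @param thresholds Numeric thresholds (default `seq(0, 1, by = 0.05)`).
#' @return Data.frame with columns `threshold`, `n_above`, `proportion`.
#' @export
r_cumulative_table <- function(summaries, thresholds = seq(0, 1, by = 0.05)) {
  r <- summaries$r[!is.na(summaries$r)]
  data.frame(threshold = thresholds,
             n_above = vapply(thresholds, function(t) sum(r > t), integer(1)),
             proportion = vapply(thresholds, function(t) mean(r > t),
                                 numeric(1)))
}
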