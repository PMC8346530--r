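# COG/KOG functional category letters. The informational ("information
# storage and processing") super-class is the standard {A, B, J, K, L}
# grouping; every other category letter is operational. L's membership is
# configurable because some published listings place it inconsistently.
INFORMATIONAL_LETTERS <- c("A", "B", "J", "K", "L")

superclass_sets <- function(l_superclass = c("informational", "operational")) {
  l_superclass <- match.arg(l_superclass)
  info <- INFORMATIONAL_LETTERS
  if (l_superclass == "operational") info <- setdiff(info, "L")
  list(informational = info, operational = setdiff(LETTERS, info))
}

#' Classify COG/KOG letters into functional super-classes
#'
#' A protein annotated only with letters from \{A, B, J, K, L\} is
#' informational (genetic-information storage and processing); a protein
#' annotated only with the remaining category letters is operational
#' (metabolism, transport, regulation and other housekeeping roles).
#' Proteins carrying letters from both super-classes are flagged `"mixed"`
#' and excluded from group comparisons; an empty annotation is
#' `"unassigned"`.
#'
#' @param letters Character vector; each element is a string of one-letter
#'   category codes (e.g. `"J"`, `"KT"`).
#' @param l_superclass Which super-class letter L belongs to
#'   (default `"informational"`, the standard COG grouping).
#' @return Character vector over \{"informational", "operational", "mixed",
#'   "unassigned"\}.
#' @examples
#' classify_super_class(c("J", "E", "KT", ""))
#' @export
classify_super_class <- function(letters,
                                 l_superclass = c("informational",
                                                  "operational")) {
  sets <- superclass_sets(match.arg(l_superclass))
  vapply(letters, function(s) {
    if (is.na(s) || !nzchar(s)) return("unassigned")
    ls <- unique(strsplit(toupper(s), "")[[1]])
    if (!all(ls %in% LETTERS)) return("unassigned")
    in_info <- ls %in% sets$informational
    if (all(in_info)) "informational"
    else if (all(!in_info)) "operational"
    else "mixed"
  }, character(1), USE.NAMES = FALSE)
}

#' Read a functional-annotation table
#'
#' Tab-separated mapping of protein IDs to COG/KOG category letters. The
#' reader is tolerant of the common dialects: with or without a header, and
#' with the letters in the second or third column (`protein_id, letters` or
#' `protein_id, cog_id, letters[, description]`).
#'
#' @param path File path.
#' @return Data.frame with columns `id`, `letters` and `super_class`.
#' @param l_superclass Passed to [classify_super_class()].
#' @export
read_annotation <- function(path, l_superclass = "informational") {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  # drop a header row if the letters column is not all category letters
  is_letters <- function(x) grepl("^[A-Za-z]+$", x)
  lcol <- if (ncol(df) >= 3L) 3L else 2L
  if (ncol(df) < 2L) stop("annotation table needs at least 2 columns",
                          call. = FALSE)
  if (nrow(df) > 0L && (!is_letters(df[1, lcol]) ||
                        tolower(df[1, 1]) %in% c("protein_id", "id"))) {
    df <- df[-1, , drop = FALSE]
  }
  out <- data.frame(id = df[[1]], letters = toupper(df[[lcol]]),
                    stringsAsFactors = FALSE)
  out$super_class <- classify_super_class(out$letters, l_superclass)
  out
}

#' Read a subcellular-location table
#'
#' Tab-separated `protein_id, location_label`. Labels are mapped onto
#' \{"cytoplasmic", "cytoplasmic membrane", "other"\} via `label_map`;
#' unmapped labels become `"other"`.
#'
#' @param path File path.
#' @param label_map Named character vector mapping raw labels (lower-cased)
#'   to canonical location classes.
#' @return Data.frame with columns `id`, `label`, `location`.
#' @export
read_locations <- function(path,
                           label_map = c("cytoplasmic" = "cytoplasmic",
                                         "cytoplasm" = "cytoplasmic",
                                         "cytoplasmic membrane" =
                                           "cytoplasmic membrane",
                                         "inner membrane" =
                                           "cytoplasmic membrane")) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("location table needs 2 columns", call. = FALSE)
  if (tolower(df[1, 1]) %in% c("protein_id", "id")) df <- df[-1, , drop = FALSE]
  loc <- unname(label_map[tolower(df[[2]])])
  loc[is.na(loc)] <- "other"
  data.frame(id = df[[1]], label = df[[2]], location = loc,
             stringsAsFactors = FALSE)
}

#' Two-group comparison of a per-gene metric
#'
#' Unpaired two-sample t-test (equal-variance Student's test by default,
#' Welch's variant by flag) comparing a metric between informational and
#' operational genes, with two-sided p-value and group means.
#'
#' When both groups are constant the usual test is undefined: identical
#' group means give t = 0, p = 1; different constant means leave the test
#' undefined (`NA` statistics, flagged in `note`).
#'
#' @param values_info,values_op Numeric metric values for the informational
#'   and operational groups (each of size >= 2 after NA removal).
#' @param metric Metric name carried into the output.
#' @param var_equal Use the pooled-variance Student's test (default `TRUE`).
#' @return One-row data.frame: `metric`, `mean_informational`,
#'   `mean_operational`, `n_informational`, `n_operational`, `t`, `p`,
#'   `note`.
#' @export
compare_metric <- function(values_info, values_op, metric = "metric",
                           var_equal = TRUE) {
  values_info <- values_info[!is.na(values_info)]
  values_op <- values_op[!is.na(values_op)]
  if (length(values_info) < 2L || length(values_op) < 2L) {
    stop("both groups need at least 2 values (got ", length(values_info),
         " and ", length(values_op), ")", call. = FALSE)
  }
  base <- data.frame(metric = metric,
                     mean_informational = mean(values_info),
                     mean_operational = mean(values_op),
                     n_informational = length(values_info),
                     n_operational = length(values_op),
                     t = NA_real_, p = NA_real_, note = NA_character_,
                     stringsAsFactors = FALSE)
  if (stats::sd(values_info) == 0 && stats::sd(values_op) == 0) {
    if (mean(values_info) == mean(values_op)) {
      base$t <- 0; base$p <- 1
    } else {
      base$note <- "degenerate: zero variance in both groups, test undefined"
    }
    return(base)
  }
  tt <- stats::t.test(values_info, values_op, var.equal = var_equal,
                      alternative = "two.sided")
  base$t <- unname(tt$statistic)
  base$p <- tt$p.value
  base
}

#' Compare informational vs operational genes on GRAVY and T2-A2
#'
#' Joins per-gene metrics with a functional annotation, splits genes into the
#' two super-classes (mixed and unassigned genes are excluded), and runs the
#' two-group test for each metric.
#'
#' @param metrics Per-gene data.frame from [gene_metrics()].
#' @param annotation Data.frame from [read_annotation()] (columns `id`,
#'   `super_class`).
#' @param metrics_cols Metric columns to test (default `c("gravy","t2_a2")`).
#' @param var_equal Passed to [compare_metric()].
#' @return Data.frame with one row per metric (Table-3-style columns).
#' @export
compare_super_classes <- function(metrics, annotation,
                                  metrics_cols = c("gravy", "t2_a2"),
                                  var_equal = TRUE) {
  merged <- merge(metrics[metrics$valid, ], annotation, by = "id")
  if (nrow(merged) == 0L) {
    stop("annotation IDs do not overlap the gene IDs", call. = FALSE)
  }
  info <- merged[merged$super_class == "informational", ]
  op <- merged[merged$super_class == "operational", ]
  if (nrow(info) < 2L || nrow(op) < 2L) {
    stop("a super-class is (nearly) empty after classification: ",
         nrow(info), " informational, ", nrow(op), " operational",
         call. = FALSE)
  }
  do.call(rbind, lapply(metrics_cols, function(mc) {
    compare_metric(info[[mc]], op[[mc]], metric = mc, var_equal = var_equal)
  }))
}

#' Chi-square test on a 2x2 super-class by location table
#'
#' Tests whether subcellular location (cytoplasmic vs cytoplasmic membrane)
#' is distributed differently between informational and operational proteins.
#' Pearson's chi-square without continuity correction by default.
#'
#' @param counts 2x2 matrix of non-negative integer counts; rows are
#'   super-classes, columns location types.
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @return A list of class `location_chi2`: `counts`, `chi2`, `df`, `p`,
#'   `degenerate`. A zero row or column margin leaves the test undefined
#'   (`NA` statistics, `degenerate = TRUE`).
#' @examples
#' location_chi2(matrix(c(63, 1, 514, 167), nrow = 2, byrow = TRUE))
#' @export
location_chi2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be a 2x2 non-negative integer table", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    return(structure(list(counts = counts, chi2 = NA_real_, df = 1L,
                          p = NA_real_, degenerate = TRUE),
                     class = "location_chi2"))
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  structure(list(counts = counts, chi2 = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 degenerate = FALSE),
            class = "location_chi2")
}

#' @export
print.location_chi2 <- function(x, ...) {
  cat("2x2 location chi-square\n")
  print(x$counts)
  if (x$degenerate) cat("degenerate margin: test undefined\n")
  else cat(sprintf("X-squared = %.4g, df = %d, p = %.4g\n",
                   x$chi2, x$df, x$p))
  invisible(x)
}

#' Build the 2x2 location table from annotated locations
#'
#' @param annotation Data.frame from [read_annotation()].
#' @param locations Data.frame from [read_locations()].
#' @return Integer 2x2 matrix (informational/operational x
#'   cytoplasmic/cytoplasmic membrane); proteins with `"other"` or unknown
#'   locations, or mixed/unassigned function, are excluded.
#' @export
location_table <- function(annotation, locations) {
  merged <- merge(annotation, locations, by = "id")
  merged <- merged[merged$super_class %in% c("informational", "operational") &
                     merged$location %in% c("cytoplasmic",
                                            "cytoplasmic membrane"), ]
  tab <- table(factor(merged$super_class,
                      levels = c("informational", "operational")),
               factor(merged$location,
                      levels = c("cytoplasmic", "cytoplasmic membrane")))
  mat <- matrix(as.integer(tab), nrow = 2,
                dimnames = dimnames(tab))
  mat
}
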