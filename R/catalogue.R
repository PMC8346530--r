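#' Pearson association between one assignment and one property scale
#'
#' Correlates the 20 codon-averaged amino-acid position values under a
#' grouping/value assignment with a physicochemical property scale. The
#' sample is the 20 standard amino acids; the two-sided p-value comes from
#' the t distribution with n - 2 = 18 degrees of freedom.
#'
#' @param assignment A `value_assignment`.
#' @param scale A `property_scale`.
#' @param code Genetic code, as returned by [genetic_code()].
#' @return A one-row data.frame with columns `property`, `position`,
#'   `group_type`, `n_groups`, `assignment`, `r`, `p`, `n`, `degenerate`.
#'   When the assignment yields zero variance over the realized nucleotides,
#'   the correlation is undefined: `r` and `p` are `NA` and `degenerate` is
#'   `TRUE` (such records are excluded from per-cell maxima).
#' @examples
#' a <- enumerate_assignments(2)
#' kd <- load_property_scale("hydropathy index")
#' recs <- do.call(rbind, lapply(a, pearson_assoc, scale = kd))
#' max(abs(recs$r), na.rm = TRUE)  # 0.8635, the hydropathy headline
#' @export
pearson_assoc <- function(assignment, scale, code = genetic_code()) {
  stopifnot(inherits(assignment, "value_assignment"),
            inherits(scale, "property_scale"))
  x <- position_values(assignment, code)
  y <- scale$values
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_; p <- NA_real_; degenerate <- TRUE
  } else {
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    r <- unname(ct$estimate); p <- ct$p.value; degenerate <- FALSE
  }
  data.frame(property = scale$name, position = assignment$position,
             group_type = assignment$group_type,
             n_groups = assignment$n_groups,
             assignment = format_assignment(assignment$values),
             r = r, p = p, n = length(y), degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Build the full association catalogue
#'
#' Computes the Pearson association of every (position, property, assignment)
#' triple: 74 assignments per position, 3 positions, and the bundled 13
#' property scales give 74 x 3 x 13 = 2886 candidate associations. Rows are
#' ordered deterministically by position, property, grouping family, and
#' lexicographic assignment string.
#'
#' @param scales Named list of `property_scale` objects
#'   (default: all 13 bundled scales).
#' @param positions Codon positions to include (default 1:3).
#' @param code Genetic code.
#' @return A data.frame with one row per record (columns as in
#'   [pearson_assoc()]).
#' @examples
#' cat_hyd <- build_catalogue(scales = load_all_scales()["hydropathy index"])
#' nrow(cat_hyd)  # 222 = 74 x 3
#' @export
build_catalogue <- function(scales = load_all_scales(), positions = 1:3,
                            code = genetic_code()) {
  if (length(scales) == 0L) {
    return(data.frame(property = character(0), position = integer(0),
                      group_type = character(0), n_groups = integer(0),
                      assignment = character(0), r = numeric(0),
                      p = numeric(0), n = integer(0),
                      degenerate = logical(0)))
  }
  stopifnot(all(vapply(scales, inherits, logical(1), "property_scale")))
  S <- vapply(scales, `[[`, numeric(20), "values")  # 20 x n_scales
  rows <- vector("list", length(positions))
  for (k in seq_along(positions)) {
    pos <- positions[k]
    assigns <- enumerate_assignments(pos)
    X <- vapply(assigns, position_values, numeric(20), code = code)
    sds <- apply(X, 2, stats::sd)
    R <- suppressWarnings(stats::cor(X, S))          # 74 x n_scales
    R[sds == 0, ] <- NA_real_
    tstat <- R * sqrt(18 / (1 - R^2))
    P <- 2 * stats::pt(-abs(tstat), df = 18)
    rows[[k]] <- data.frame(
      property = rep(colnames(S), each = length(assigns)),
      position = as.integer(pos),
      group_type = rep(vapply(assigns, `[[`, "", "group_type"),
                       times = ncol(S)),
      n_groups = rep(vapply(assigns, `[[`, integer(1), "n_groups"),
                     times = ncol(S)),
      assignment = rep(vapply(assigns, function(a)
        format_assignment(a$values), character(1)), times = ncol(S)),
      r = as.vector(R), p = as.vector(P), n = 20L,
      degenerate = rep(sds == 0, times = ncol(S)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  # order: position, property (bundled order), family, lexicographic string
  prop_order <- match(out$property, names(scales))
  fam <- factor(out$group_type, levels = c("four_group", "three_group",
                                           "two_group_1v3", "two_group_2v2"))
  out <- out[order(out$position, prop_order, fam, out$assignment), ]
  rownames(out) <- NULL
  out
}

#' Strongest association per (property, position) cell
#'
#' For each property and each codon position, selects the assignment with the
#' largest absolute correlation among the 74 candidates, and reports it in
#' the sign orientation that makes the correlation positive (the orientation
#' is a pure relabelling: negating all assignment values negates r and leaves
#' p unchanged). Ties are broken toward fewer groups, then lexicographically
#' smaller assignment string. Degenerate (zero-variance) records are excluded.
#'
#' @param catalogue A catalogue data.frame from [build_catalogue()].
#' @return A data.frame with one row per (property, position) cell
#'   (39 rows for the full catalogue), columns as in the catalogue with `r`
#'   always positive.
#' @export
best_per_cell <- function(catalogue) {
  ok <- catalogue[!catalogue$degenerate & !is.na(catalogue$r), ]
  cells <- split(ok, list(ok$property, ok$position), drop = TRUE)
  picked <- lapply(cells, function(df) {
    df <- df[order(-abs(df$r), df$n_groups, df$assignment), ]
    rec <- df[1, ]
    if (rec$r < 0) {
      rec$assignment <- format_assignment(-parse_assignment(rec$assignment))
      rec$r <- -rec$r
    }
    rec
  })
  out <- do.call(rbind, picked)
  prop_order <- match(out$property, property_names())
  prop_order[is.na(prop_order)] <- length(property_names()) + 1L
  out <- out[order(prop_order, out$position), ]
  rownames(out) <- NULL
  out
}

#' Combined (multi-position) association for one property
#'
#' Regresses a property's 20 amino-acid values on the three per-position
#' winning value vectors by ordinary least squares and reports the multiple
#' correlation coefficient R, R-squared, and the overall F-test p-value.
#'
#' @param property Property name.
#' @param best Data.frame from [best_per_cell()] (must contain the three
#'   positions for `property`).
#' @param scales Named list of property scales containing `property`.
#' @param code Genetic code.
#' @return A one-row data.frame with columns `property`, `r`, `r2`, `p`.
#' @examples
#' best <- best_per_cell(build_catalogue())
#' combined_assoc("hydropathy index", best)  # R^2 ~ 0.79
#' @export
combined_assoc <- function(property, best, scales = load_all_scales(),
                           code = genetic_code()) {
  rows <- best[best$property == property, ]
  if (nrow(rows) != 3L) {
    stop("need the three per-position winners for ", sQuote(property),
         call. = FALSE)
  }
  rows <- rows[order(rows$position), ]
  X <- vapply(seq_len(3), function(i) {
    a <- new_assignment(rows$position[i], parse_assignment(rows$assignment[i]),
                        rows$group_type[i])
    position_values(a, code)
  }, numeric(20))
  colnames(X) <- paste0("pos", rows$position)
  if (all(apply(X, 2, stats::sd) == 0)) {
    warning("all three predictors are constant; combined association undefined")
    return(data.frame(property = property, r = NA_real_, r2 = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE))
  }
  y <- scales[[property]]$values
  fit <- stats::lm(y ~ X)
  if (any(is.na(stats::coef(fit)))) {
    warning("collinear position-value predictors; rank-deficient fit for ",
            sQuote(property))
  }
  sm <- summary(fit)
  f <- sm$fstatistic
  p <- stats::pf(f[["value"]], f[["numdf"]], f[["dendf"]], lower.tail = FALSE)
  data.frame(property = property, r = sqrt(sm$r.squared), r2 = sm$r.squared,
             p = p, stringsAsFactors = FALSE)
}

#' Wide per-property summary of the catalogue
#'
#' Assembles the reporting table: one row per property with the winning
#' assignment, r and p for each codon position, plus the combined
#' multi-position R, R-squared and p. Rows are ordered by the property's
#' highest single-position correlation, descending.
#'
#' @param best Data.frame from [best_per_cell()].
#' @param scales Named list of property scales.
#' @param code Genetic code.
#' @return A data.frame with 13 rows (for the full catalogue).
#' @export
summarize_catalogue <- function(best, scales = load_all_scales(),
                                code = genetic_code()) {
  props <- unique(best$property)
  rows <- lapply(props, function(pr) {
    sub <- best[best$property == pr, ]
    sub <- sub[order(sub$position), ]
    wide <- data.frame(property = pr, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sub))) {
      pos <- sub$position[i]
      wide[[paste0("combination_", pos)]] <- sub$assignment[i]
      wide[[paste0("r", pos)]] <- sub$r[i]
      wide[[paste0("p", pos)]] <- sub$p[i]
    }
    if (nrow(sub) == 3L && pr %in% names(scales)) {
      comb <- combined_assoc(pr, best, scales, code)
      wide$general_r <- comb$r
      wide$general_r2 <- comb$r2
      wide$general_p <- comb$p
    }
    wide
  })
  out <- do.call(rbind, rows)
  rcols <- intersect(c("r1", "r2", "r3"), names(out))
  out <- out[order(-apply(out[rcols], 1, max, na.rm = TRUE)), ]
  rownames(out) <- NULL
  out
}

#' Write / read association tables as TSV
#'
#' Tab-separated, with header; the `assignment` column uses the canonical
#' string of [format_assignment()] and round-trips bit-exactly.
#'
#' @param df An association data.frame ([build_catalogue()],
#'   [best_per_cell()] or [summarize_catalogue()] output).
#' @param path File path.
#' @return `write_assoc_table` returns `path` invisibly; `read_assoc_table`
#'   returns the data.frame.
#' @export
write_assoc_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_assoc_table
#' @export
read_assoc_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
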