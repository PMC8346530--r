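NUCLEOTIDES <- c("A", "C", "G", "T")

# Fixed value sets per grouping family, read off the published assignment
# strings: two groups use {-1,+1}, three groups {-1,0,+1}, four groups
# {-2,-1,+1,+2}.
new_assignment <- function(position, values, group_type) {
  stopifnot(position %in% 1:3, setequal(names(values), NUCLEOTIDES))
  values <- values[NUCLEOTIDES]
  structure(list(position = as.integer(position), values = values,
                 group_type = group_type,
                 n_groups = length(unique(values))),
            class = "value_assignment")
}

#' @export
print.value_assignment <- function(x, ...) {
  cat(sprintf("Assignment (position %d, %s): %s\n",
              x$position, x$group_type, format_assignment(x$values)))
  invisible(x)
}

#' Canonical assignment string
#'
#' Formats a nucleotide-to-value map in the grouped style used for reporting,
#' e.g. `"A:-1,CG:0,T:1"`: nucleotides sharing a value are concatenated, and
#' groups are listed by their first nucleotide in A, C, G, T order. The format
#' round-trips exactly through [parse_assignment()].
#'
#' @param values Named numeric vector over the nucleotides A, C, G, T.
#' @return A character scalar.
#' @export
format_assignment <- function(values) {
  if (inherits(values, "value_assignment")) values <- values$values
  values <- values[NUCLEOTIDES]
  groups <- split(names(values), factor(values, levels = unique(values[order(
    match(names(values), NUCLEOTIDES))])))
  # order groups by first nucleotide in A,C,G,T order
  first <- vapply(groups, function(g) min(match(g, NUCLEOTIDES)), numeric(1))
  groups <- groups[order(first)]
  vals <- vapply(names(groups), function(v) as.numeric(v), numeric(1))
  paste(vapply(seq_along(groups), function(i) {
    paste0(paste(sort(groups[[i]]), collapse = ""), ":",
           format(vals[i], trim = TRUE, scientific = FALSE))
  }, character(1)), collapse = ",")
}

#' @rdname format_assignment
#' @param x An assignment string produced by [format_assignment()].
#' @return `parse_assignment` returns the named numeric vector over
#'   A, C, G, T.
#' @export
parse_assignment <- function(x) {
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  values <- numeric(0)
  for (p in parts) {
    nts <- strsplit(p[[1]], "")[[1]]
    values[nts] <- as.numeric(p[[2]])
  }
  if (!setequal(names(values), NUCLEOTIDES)) {
    stop("assignment string must cover A, C, G, T exactly: ", x,
         call. = FALSE)
  }
  values[NUCLEOTIDES]
}

# negate all values of an assignment (orientation flip)
negate_assignment <- function(a) {
  new_assignment(a$position, -a$values, a$group_type)
}

#' Enumerate all grouping/value assignments at one codon position
#'
#' Generates the complete family of nucleotide grouping schemes with their
#' numeric value assignments for a single codon position:
#' \itemize{
#'   \item `four_group`: the single 4-way partition, with the 24 permutations
#'     of the values \{-2, -1, 1, 2\};
#'   \item `three_group`: the 6 pairings of two nucleotides, each with the 6
#'     permutations of \{-1, 0, 1\} over the 3 groups (36 total);
#'   \item `two_group_1v3`: each of the 4 singleton-versus-rest splits in both
#'     sign orientations of \{-1, +1\} (8 total);
#'   \item `two_group_2v2`: the 3 balanced partitions in both orientations
#'     (6 total).
#' }
#' This yields exactly 74 assignments per position (24 + 36 + 8 + 6). Both
#' sign orientations of every scheme are present; orientations are only
#' collapsed later, when the strongest association per table cell is reported
#' in its positive-correlation orientation.
#'
#' @param position Codon position, 1, 2 or 3.
#' @return A list of 74 `value_assignment` objects, deterministically ordered
#'   by group family (four, three, two-1v3, two-2v2) and then lexicographic
#'   assignment string.
#' @examples
#' length(enumerate_assignments(2))  # 74
#' table(vapply(enumerate_assignments(1), `[[`, "", "group_type"))
#' @export
enumerate_assignments <- function(position) {
  if (length(position) != 1L || !position %in% 1:3) {
    stop("position must be 1, 2 or 3", call. = FALSE)
  }
  out <- list()
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  # four groups: 24 permutations of {-2,-1,1,2}
  vals4 <- c(-2, -1, 1, 2)
  perms4 <- list()
  for (i in 1:4) for (p in perms3) {
    perms4[[length(perms4) + 1L]] <- append(setdiff(1:4, i)[p], i, after = 0)
  }
  # append() above builds each permutation as (i, rest-permuted); collect all
  perms4 <- unique(lapply(perms4, function(p) p))
  for (p in perms4) {
    out[[length(out) + 1L]] <- new_assignment(
      position, stats::setNames(vals4[p], NUCLEOTIDES), "four_group")
  }
  # three groups: choose the merged pair, permute {-1,0,1} over the 3 groups
  pairs <- utils::combn(NUCLEOTIDES, 2, simplify = FALSE)
  vals3 <- c(-1, 0, 1)
  for (pair in pairs) {
    singles <- setdiff(NUCLEOTIDES, pair)
    for (p in perms3) {
      v <- vals3[p]
      values <- stats::setNames(numeric(4), NUCLEOTIDES)
      values[pair] <- v[1]
      values[singles[1]] <- v[2]
      values[singles[2]] <- v[3]
      out[[length(out) + 1L]] <- new_assignment(position, values,
                                                "three_group")
    }
  }
  # two groups, 1 vs 3: 4 singletons x 2 orientations
  for (nt in NUCLEOTIDES) {
    for (s in c(-1, 1)) {
      values <- stats::setNames(rep(-s, 4), NUCLEOTIDES)
      values[nt] <- s
      out[[length(out) + 1L]] <- new_assignment(position, values,
                                                "two_group_1v3")
    }
  }
  # two groups, 2 vs 2: 3 balanced partitions x 2 orientations
  balanced <- list(c("A", "C"), c("A", "G"), c("A", "T"))
  for (grp in balanced) {
    for (s in c(-1, 1)) {
      values <- stats::setNames(rep(-s, 4), NUCLEOTIDES)
      values[grp] <- s
      out[[length(out) + 1L]] <- new_assignment(position, values,
                                                "two_group_2v2")
    }
  }
  # deterministic order within each family: lexicographic assignment string
  fam <- vapply(out, `[[`, "", "group_type")
  lab <- vapply(out, function(a) format_assignment(a$values), character(1))
  fam <- factor(fam, levels = c("four_group", "three_group",
                                "two_group_1v3", "two_group_2v2"))
  out[order(fam, lab)]
}

# Fraction of each amino acid's sense codons carrying each nucleotide at
# `position`: a 20 x 4 matrix (rows = amino acids, cols = A,C,G,T). The
# codon-averaged position value of an assignment v is then simply F %*% v.
aa_nt_fractions <- function(position, code = genetic_code()) {
  stopifnot(position %in% 1:3)
  codons <- names(code$codon_to_aa)
  nt <- substr(codons, position, position)
  aa <- code$codon_to_aa
  tab <- table(factor(aa, levels = amino_acids()),
               factor(nt, levels = NUCLEOTIDES))
  mat <- unclass(tab / rowSums(tab))
  dimnames(mat) <- list(amino_acids(), NUCLEOTIDES)
  mat
}

#' Codon-averaged position value of an amino acid
#'
#' Under a given grouping/value assignment, each sense codon of an amino acid
#' contributes the value assigned to its nucleotide at the assignment's codon
#' position; the amino acid's position value is the unweighted mean over its
#' synonymous codons (no codon-usage weighting).
#'
#' @param aa One-letter amino-acid code.
#' @param assignment A `value_assignment` (see [enumerate_assignments()]).
#' @param code Genetic code, as returned by [genetic_code()].
#' @return Numeric scalar.
#' @examples
#' a <- structure(list(position = 2L,
#'                     values = c(A = -1, C = 0, G = 0, T = 1),
#'                     group_type = "three_group", n_groups = 3L),
#'                class = "value_assignment")
#' aa_position_value("S", a)  # 0: all six Ser codons have C or G at pos 2
#' @export
aa_position_value <- function(aa, assignment, code = genetic_code()) {
  stopifnot(inherits(assignment, "value_assignment"))
  if (!aa %in% amino_acids()) {
    stop(sQuote(aa), " is not a standard amino acid", call. = FALSE)
  }
  frac <- aa_nt_fractions(assignment$position, code)
  drop(frac[aa, ] %*% assignment$values)
}

# Position-value vector over all 20 amino acids (alphabetical order).
position_values <- function(assignment, code = genetic_code()) {
  frac <- aa_nt_fractions(assignment$position, code)
  drop(frac %*% assignment$values)
}
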