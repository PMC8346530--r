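# Standard genetic code (NCBI translation table 1), codons in alphabetical
# order over the DNA alphabet. Stops are retained here as "*" and separated
# by genetic_code().
.GENETIC_CODE_1 <- c(
  AAA = "K", AAC = "N", AAG = "K", AAT = "N",
  ACA = "T", ACC = "T", ACG = "T", ACT = "T",
  AGA = "R", AGC = "S", AGG = "R", AGT = "S",
  ATA = "I", ATC = "I", ATG = "M", ATT = "I",
  CAA = "Q", CAC = "H", CAG = "Q", CAT = "H",
  CCA = "P", CCC = "P", CCG = "P", CCT = "P",
  CGA = "R", CGC = "R", CGG = "R", CGT = "R",
  CTA = "L", CTC = "L", CTG = "L", CTT = "L",
  GAA = "E", GAC = "D", GAG = "E", GAT = "D",
  GCA = "A", GCC = "A", GCG = "A", GCT = "A",
  GGA = "G", GGC = "G", GGG = "G", GGT = "G",
  GTA = "V", GTC = "V", GTG = "V", GTT = "V",
  TAA = "*", TAC = "Y", TAG = "*", TAT = "Y",
  TCA = "S", TCC = "S", TCG = "S", TCT = "S",
  TGA = "*", TGC = "C", TGG = "W", TGT = "C",
  TTA = "L", TTC = "F", TTG = "L", TTT = "F"
)

#' The standard genetic code
#'
#' Returns the standard genetic code (translation table 1) split into the 61
#' sense codons and the 3 stop codons. Only the standard code is supported:
#' the association framework operates on the canonical codon-amino-acid map,
#' and alternative codes would change the codon-averaged position values.
#'
#' @return A list with components:
#'   \describe{
#'     \item{codon_to_aa}{named character vector of length 61 mapping each
#'       sense codon (alphabet A, C, G, T) to its one-letter amino acid.}
#'     \item{stop_codons}{character vector of the 3 stop codons
#'       (TAA, TAG, TGA).}
#'   }
#' @examples
#' code <- genetic_code()
#' length(code$codon_to_aa)  # 61
#' code$codon_to_aa[["ATG"]] # "M"
#' @export
genetic_code <- function() {
  stops <- names(.GENETIC_CODE_1)[.GENETIC_CODE_1 == "*"]
  list(
    codon_to_aa = .GENETIC_CODE_1[.GENETIC_CODE_1 != "*"],
    stop_codons = stops
  )
}

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order. This fixed ordering is the sample
#' ordering used throughout the association catalogue (n = 20).
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  sort(unique(.GENETIC_CODE_1[.GENETIC_CODE_1 != "*"]))
}

# Split a CDS into codons after normalization. Returns a character vector of
# triplets; errors if the length is not a multiple of 3.
split_codons <- function(cds) {
  cds <- normalize_nt(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length (", n, ") is not a multiple of 3: frame error",
         call. = FALSE)
  }
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

# Uppercase, U -> T. Validates the alphabet {A,C,G,T,N}.
normalize_nt <- function(x) {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  bad <- gsub("[ACGTN]", "", x)
  if (any(nchar(bad) > 0L)) {
    stop("invalid nucleotide character(s): ",
         paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
               collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Translate a coding sequence
#'
#' Translates a frame-0 CDS with the standard genetic code. A single terminal
#' stop codon is trimmed silently. Codons containing N are skipped (they yield
#' no residue and are excluded from the sense-codon count). An internal stop
#' codon marks the record invalid by default, or truncates translation at the
#' stop when `internal_stop = "truncate"`.
#'
#' @param cds Nucleotide string (alphabet A, C, G, T, N; U accepted and
#'   normalized to T). Length must be a multiple of 3 after trailing-stop
#'   trimming.
#' @param internal_stop `"invalid"` (default) marks records with an internal
#'   stop invalid and returns `NA`; `"truncate"` translates up to the stop.
#' @return A character scalar: the amino-acid string (or `NA_character_` for
#'   an invalid record), with attributes `n_codons` (sense codons translated),
#'   `skipped_codons` (N-containing codons skipped), `valid` (logical) and
#'   `reason` (why invalid, or `NA`).
#' @examples
#' translate_cds("ATGAAATTT")          # "MKF"
#' translate_cds("ATGTAA")             # "M" (trailing stop trimmed)
#' attr(translate_cds("ATGANNTTT"), "skipped_codons")  # 1
#' @export
translate_cds <- function(cds, internal_stop = c("invalid", "truncate")) {
  internal_stop <- match.arg(internal_stop)
  codons <- split_codons(cds)
  code <- genetic_code()
  # trim one terminal stop codon, silently
  k <- length(codons)
  if (k > 0L && codons[k] %in% code$stop_codons) {
    codons <- codons[-k]
  }
  has_n <- grepl("N", codons, fixed = TRUE)
  skipped <- sum(has_n)
  codons <- codons[!has_n]
  is_stop <- codons %in% code$stop_codons
  valid <- TRUE
  reason <- NA_character_
  if (any(is_stop)) {
    if (internal_stop == "truncate") {
      codons <- codons[seq_len(which(is_stop)[1] - 1L)]
      reason <- "internal stop codon (truncated)"
    } else {
      out <- NA_character_
      attr(out, "n_codons") <- 0L
      attr(out, "skipped_codons") <- skipped
      attr(out, "valid") <- FALSE
      attr(out, "reason") <- "internal stop codon"
      return(out)
    }
  }
  out <- paste(code$codon_to_aa[codons], collapse = "")
  attr(out, "n_codons") <- length(codons)
  attr(out, "skipped_codons") <- skipped
  attr(out, "valid") <- valid
  attr(out, "reason") <- reason
  out
}
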