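# The 13 physicochemical property scales. Nine are transcribed from their
# published primary references (citation in `source`); the four compositional
# indices (aromaticity, aliphaticity, hydrogenation, hydroxythiolation) are
# reconstructed here from side-chain atomic composition, since the cited
# source does not print per-residue values. The reconstructions count,
# respectively: aromatic rings, aliphatic side-chain carbons, side-chain
# hydrogen atoms, and hydroxyl/thiol(-thioether) groups.
.PROPERTY_SCALES <- list(
  "molecular weight" = list(
    source = "Fasman (1976) CRC Handbook of Biochemistry and Molecular Biology",
    values = c(A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.15,
               Q = 146.15, E = 147.13, G = 75.07, H = 155.16, I = 131.17,
               L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
               S = 105.09, T = 119.12, W = 204.24, Y = 181.19, V = 117.15)),
  "melting point" = list(
    source = "Fasman (1976) CRC Handbook of Biochemistry and Molecular Biology",
    values = c(A = 297, R = 238, N = 236, D = 270, C = 178,
               Q = 185, E = 249, G = 290, H = 277, I = 284,
               L = 337, K = 224, M = 283, F = 284, P = 222,
               S = 228, T = 253, W = 282, Y = 344, V = 293)),
  "isoelectric point" = list(
    source = "Zimmerman, Eliezer & Simha (1968) J Theor Biol 21:170-201",
    values = c(A = 6.00, R = 10.76, N = 5.41, D = 2.77, C = 5.05,
               Q = 5.65, E = 3.22, G = 5.97, H = 7.59, I = 6.02,
               L = 5.98, K = 9.74, M = 5.74, F = 5.48, P = 6.30,
               S = 5.68, T = 5.66, W = 5.89, Y = 5.66, V = 5.96)),
  "hydropathy index" = list(
    source = "Kyte & Doolittle (1982) J Mol Biol 157:105-132",
    values = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
               Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
               L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
               S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)),
  "chemical composition of the side chain" = list(
    source = "Grantham (1974) Science 185:862-864",
    values = c(A = 0, R = 0.65, N = 1.33, D = 1.38, C = 2.75,
               Q = 0.89, E = 0.92, G = 0.74, H = 0.58, I = 0,
               L = 0, K = 0.33, M = 0, F = 0, P = 0.39,
               S = 1.42, T = 0.71, W = 0.13, Y = 0.20, V = 0)),
  "molecular volume" = list(
    source = "Grantham (1974) Science 185:862-864",
    values = c(A = 31, R = 124, N = 56, D = 54, C = 55,
               Q = 85, E = 83, G = 3, H = 96, I = 111,
               L = 111, K = 119, M = 105, F = 132, P = 32.5,
               S = 32, T = 61, W = 170, Y = 136, V = 84)),
  "polarity" = list(
    source = "Grantham (1974) Science 185:862-864",
    values = c(A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5,
               Q = 10.5, E = 12.3, G = 9.0, H = 10.4, I = 5.2,
               L = 4.9, K = 11.3, M = 5.7, F = 5.2, P = 8.0,
               S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9)),
  "refractivity" = list(
    source = "McMeekin, Groves & Hipp (1964), as tabulated by Jones (1975)",
    values = c(A = 4.34, R = 26.66, N = 13.28, D = 12.00, C = 35.77,
               Q = 17.56, E = 17.26, G = 0.00, H = 21.81, I = 19.06,
               L = 18.78, K = 21.29, M = 21.64, F = 29.40, P = 10.93,
               S = 6.35, T = 11.01, W = 42.53, Y = 31.53, V = 13.92)),
  "aromaticity" = list(
    source = "reconstructed: number of aromatic rings in the side chain",
    values = c(A = 0, R = 0, N = 0, D = 0, C = 0,
               Q = 0, E = 0, G = 0, H = 1, I = 0,
               L = 0, K = 0, M = 0, F = 1, P = 0,
               S = 0, T = 0, W = 2, Y = 1, V = 0)),
  "aliphaticity" = list(
    source = "reconstructed: number of aliphatic carbons in the side chain",
    values = c(A = 1, R = 4, N = 2, D = 2, C = 1,
               Q = 3, E = 3, G = 0, H = 1, I = 4,
               L = 4, K = 4, M = 3, F = 1, P = 3,
               S = 1, T = 2, W = 1, Y = 1, V = 3)),
  "hydrogenation" = list(
    source = "reconstructed: number of hydrogen atoms in the side chain",
    values = c(A = 3, R = 10, N = 4, D = 3, C = 3,
               Q = 6, E = 5, G = 1, H = 5, I = 9,
               L = 9, K = 10, M = 7, F = 7, P = 6,
               S = 3, T = 5, W = 8, Y = 7, V = 7)),
  "hydroxythiolation" = list(
    source = "reconstructed: count of hydroxyl/thiol/thioether groups in the side chain",
    values = c(A = 0, R = 0, N = 0, D = 0, C = 1,
               Q = 0, E = 0, G = 0, H = 0, I = 0,
               L = 0, K = 0, M = 1, F = 0, P = 0,
               S = 1, T = 1, W = 0, Y = 1, V = 0)),
  "polar requirement" = list(
    source = "Woese (1973), chromatographic polar requirement",
    values = c(A = 7.0, R = 9.1, N = 10.0, D = 13.0, C = 5.5,
               Q = 8.6, E = 12.5, G = 7.9, H = 8.4, I = 4.9,
               L = 4.9, K = 10.1, M = 5.3, F = 5.0, P = 6.6,
               S = 7.5, T = 6.6, W = 5.3, Y = 5.7, V = 5.6))
)

#' Names of the bundled physicochemical property scales
#'
#' @return Character vector of the 13 bundled scale names.
#' @export
property_names <- function() names(.PROPERTY_SCALES)

new_property_scale <- function(name, values, source) {
  aa <- amino_acids()
  stopifnot(setequal(names(values), aa))
  values <- values[aa]
  if (any(!is.finite(values))) stop("non-finite scale value", call. = FALSE)
  structure(list(name = name, values = values, source = source),
            class = "property_scale")
}

#' Load a bundled physicochemical property scale
#'
#' The scales are packaged constants (never downloaded): one numeric value per
#' standard amino acid plus a provenance string. Values are returned in the
#' fixed alphabetical amino-acid order used throughout the catalogue.
#'
#' @param name One of [property_names()].
#' @return A `property_scale` object: list with `name`, `values` (named
#'   numeric, length 20) and `source` (citation string).
#' @examples
#' kd <- load_property_scale("hydropathy index")
#' kd$values[["I"]]  #  4.5
#' kd$values[["R"]]  # -4.5
#' @export
load_property_scale <- function(name) {
  if (length(name) != 1L || !name %in% names(.PROPERTY_SCALES)) {
    stop("unknown property scale ", sQuote(name), "; valid names are: ",
         paste(sQuote(names(.PROPERTY_SCALES)), collapse = ", "),
         call. = FALSE)
  }
  entry <- .PROPERTY_SCALES[[name]]
  new_property_scale(name, entry$values, entry$source)
}

#' Load all bundled property scales
#'
#' @return Named list of 13 `property_scale` objects.
#' @export
load_all_scales <- function() {
  out <- lapply(property_names(), load_property_scale)
  names(out) <- property_names()
  out
}

#' @export
print.property_scale <- function(x, ...) {
  cat("Property scale:", x$name, "\n")
  cat("Source:", x$source, "\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Z-standardize a property scale
#'
#' Centers and rescales the values to mean 0 and unit standard deviation.
#' Pearson correlations are invariant to this affine rescaling; the helper
#' exists so scales on very different units can be displayed together.
#'
#' @param scale A `property_scale`.
#' @return A `property_scale` with standardized values.
#' @export
standardize_scale <- function(scale) {
  stopifnot(inherits(scale, "property_scale"))
  v <- scale$values
  scale$values <- (v - mean(v)) / stats::sd(v)
  scale$source <- paste0(scale$source, " (z-standardized)")
  scale
}

#' Write / read a property scale as a two-column TSV
#'
#' The interchange format is a headerless tab-separated file with one row per
#' amino acid: one-letter code, numeric value. This lets users supply custom
#' scales for the same correlation analysis.
#'
#' @param scale A `property_scale`.
#' @param path File path.
#' @param name,source Name and provenance for the scale read from `path`.
#' @return `read_property_scale` returns a `property_scale`;
#'   `write_property_scale` returns `path` invisibly.
#' @export
write_property_scale <- function(scale, path) {
  stopifnot(inherits(scale, "property_scale"))
  utils::write.table(
    data.frame(aa = names(scale$values), value = scale$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_property_scale
#' @export
read_property_scale <- function(path, name = basename(path),
                                source = paste("read from", path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("aa", "value"),
                          colClasses = c("character", "numeric"))
  if (nrow(df) != 20L || anyDuplicated(df$aa)) {
    stop("a property scale needs exactly one value per standard amino acid",
         call. = FALSE)
  }
  new_property_scale(name, stats::setNames(df$value, df$aa), source)
}
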