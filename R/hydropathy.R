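#' Kyte-Doolittle hydropathy scale
#'
#' The published Kyte-Doolittle hydropathy values for the 20 standard amino
#' acids, as a named numeric vector in the package's canonical ordering
#' ([aa_order()]). Positive values are hydrophobic, negative hydrophilic.
#'
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' kyte_doolittle()[c("R", "V")]
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

check_hydropathy_scale <- function(kd) {
  if (!is.numeric(kd) || length(kd) != 20L || !all(is.finite(kd))) {
    abort("A hydropathy scale must be a numeric vector of 20 finite values.")
  }
  if (is.null(names(kd))) names(kd) <- aa_order()
  if (!setequal(names(kd), aa_order())) {
    abort("A hydropathy scale must be named by the 20 standard amino acids.")
  }
  kd[aa_order()]
}

#' Hydropathy value of each residue in a sequence
#'
#' Maps one-letter residue codes to their Kyte-Doolittle values. Non-standard
#' codes (B, Z, X, U, ...) map to 0 with a warning, since the scale is defined
#' only for the 20 common amino acids.
#'
#' @param sequence Character string of one-letter residue codes, or a
#'   character vector of single letters.
#' @param kd Hydropathy scale (named 20-vector); default [kyte_doolittle()].
#' @return Numeric vector, one value per residue.
#' @export
hydropathy_values <- function(sequence, kd = kyte_doolittle()) {
  kd <- check_hydropathy_scale(kd)
  letters1 <- if (length(sequence) == 1L && nchar(sequence[1L]) > 1L) {
    strsplit(sequence, "")[[1L]]
  } else {
    as.character(sequence)
  }
  vals <- unname(kd[letters1])
  bad <- is.na(vals)
  if (any(bad)) {
    warn(sprintf(
      "Non-standard residue code(s) %s mapped to hydropathy 0.",
      paste(sort(unique(letters1[bad])), collapse = ", ")
    ))
    vals[bad] <- 0
  }
  vals
}
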