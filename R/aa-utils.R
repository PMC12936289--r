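# Amino-acid alphabets and code tables shared across modules.

# canonical 20-letter alphabet (1-letter codes)
AA_CANONICAL <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# ambiguous / nonstandard codes rejected for peptide synthesis
AA_NONSTANDARD <- c("B", "Z", "X", "U", "O", "J")

AA_THREE_TO_ONE <- c(
  Ala = "A", Cys = "C", Asp = "D", Glu = "E", Phe = "F",
  Gly = "G", His = "H", Ile = "I", Lys = "K", Leu = "L",
  Met = "M", Asn = "N", Pro = "P", Gln = "Q", Arg = "R",
  Ser = "S", Thr = "T", Val = "V", Trp = "W", Tyr = "Y",
  # nonstandard: mapped so they can be named in rejection reasons
  Asx = "B", Glx = "Z", Xaa = "X", Sec = "U", Pyl = "O", Xle = "J"
)

#' Check that a string is a canonical amino-acid sequence
#'
#' @param x character vector of sequences.
#' @return logical vector, `TRUE` where every residue is one of the
#'   canonical 20 one-letter codes and the sequence is non-empty.
#' @keywords internal
is_canonical_aa <- function(x) {
  nzchar(x) & !is.na(x) & grepl(paste0("^[", paste(AA_CANONICAL, collapse = ""), "]+$"), x)
}

# round half up (the reporting convention for percentages; base round()
# is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
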