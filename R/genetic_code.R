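#' The genetic code and its synonymous-codon families
#'
#' Builds the codon table used throughout the package: the mapping from the 64
#' DNA codons to one-letter amino-acid symbols (\code{"*"} for stop), the
#' synonymous families (amino acid to codon set), and Wright's degeneracy
#' classes used by [enc()]. The standard code is taken from
#' \pkg{Biostrings}; alternative codes can be supplied as a named character
#' vector of the same shape.
#'
#' @param table named character vector mapping all 64 codons (DNA alphabet,
#'   e.g. \code{"ATG"}) to amino-acid symbols, \code{"*"} marking stops.
#'   Defaults to the standard genetic code.
#' @return An object of class \code{"genetic_code"}: a list with elements
#'   \code{codon_to_aa}, \code{families} (list, amino acid -> codons),
#'   \code{sense_codons}, \code{stop_codons}, and \code{degeneracy} (named
#'   integer vector, amino acid -> family size).
#' @examples
#' code <- genetic_code()
#' code$families[["K"]]   # the two lysine codons
#' @export
genetic_code <- function(table = NULL) {
  if (is.null(table)) {
    table <- Biostrings::GENETIC_CODE
    table <- stats::setNames(as.character(table), names(table))
  }
  if (length(table) != 64L || is.null(names(table))) {
    stop("genetic code must map exactly 64 named codons")
  }
  names(table) <- normalize_nt(names(table))
  stops <- names(table)[table == "*"]
  sense <- names(table)[table != "*"]
  aas <- sort(unique(table[sense]))
  families <- lapply(aas, function(a) sort(names(table)[table == a]))
  names(families) <- aas
  structure(
    list(
      codon_to_aa = table,
      families = families,
      sense_codons = sense,
      stop_codons = stops,
      degeneracy = vapply(families, length, integer(1))
    ),
    class = "genetic_code"
  )
}

#' Translate a coding sequence
#'
#' @param seq a CDS nucleotide string (DNA alphabet, length a multiple of 3).
#' @param code a [genetic_code()] object.
#' @return One-letter amino-acid string; stop codons appear as \code{"*"}.
#' @export
translate_cds <- function(seq, code = genetic_code()) {
  paste(code$codon_to_aa[split_codons(normalize_nt(seq))], collapse = "")
}
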