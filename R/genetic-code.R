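# Standard genetic code (translation table 1) and the codon sets every index
# in the package is defined over. Honeybee viruses are +ssRNA viruses using
# the standard code, so no alternative tables are supported.

.cubkit <- new.env(parent = emptyenv())

.build_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aa <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]], numcode = 1)
  }, character(1))
  data.frame(codon = codons, aa = unname(aa), stringsAsFactors = FALSE)
}

.code_table <- function() {
  if (is.null(.cubkit$code)) .cubkit$code <- .build_code()
  .cubkit$code
}

#' The standard genetic code
#'
#' @return A data frame with one row per codon (64 rows) and columns `codon`
#'   (DNA alphabet), `rna` (RNA alphabet) and `aa` (one-letter amino acid,
#'   `"*"` for stop).
#' @export
genetic_code <- function() {
  tab <- .code_table()
  data.frame(codon = tab$codon, rna = dna_to_rna(tab$codon), aa = tab$aa,
             stringsAsFactors = FALSE)
}

#' @rdname genetic_code
#' @export
stop_codons <- function() {
  tab <- .code_table()
  tab$codon[tab$aa == "*"]
}

#' Sense and synonymous codon sets
#'
#' `sense_codons()` returns the 61 codons that encode an amino acid.
#' `synonymous_codons()` returns the 59-codon set used by every synonymous
#' usage statistic: the sense codons minus ATG (Met) and TGG (Trp), whose
#' amino acids offer no synonymous choice.
#'
#' @return Character vector of codons in the DNA alphabet.
#' @export
sense_codons <- function() {
  tab <- .code_table()
  tab$codon[tab$aa != "*"]
}

#' @rdname sense_codons
#' @export
synonymous_codons <- function() {
  setdiff(sense_codons(), c("ATG", "TGG"))
}

#' Synonymous codon families
#'
#' @param synonymous_only drop the single-codon families (Met, Trp)?
#' @return Named list mapping one-letter amino acid to its codon set
#'   (DNA alphabet).
#' @export
codon_families <- function(synonymous_only = FALSE) {
  tab <- .code_table()
  tab <- tab[tab$aa != "*", ]
  fams <- split(tab$codon, tab$aa)
  if (synonymous_only) fams <- fams[lengths(fams) > 1L] else fams
  fams
}

#' Degeneracy of each amino-acid family
#'
#' Families are kept whole: Leu, Ser and Arg are single six-fold families,
#' giving the 9/1/5/3 family counts in Wright's degeneracy classes
#' (2-, 3-, 4- and 6-fold).
#'
#' @return Named integer vector, one entry per amino acid (20).
#' @export
family_degeneracy <- function() {
  lengths(codon_families())
}

#' Convert codons between DNA and RNA alphabets
#'
#' All internal computation uses the DNA alphabet; user-facing tables render
#' codons in RNA form.
#'
#' @param x character vector of codons or sequences.
#' @return `x` with T/U swapped (case preserved for upper case input).
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)
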