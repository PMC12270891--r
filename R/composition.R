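# Nucleotide content and positional base composition.
#
# All composition statistics are computed over the retained codons of a
# record (the same substrate as every other index), not the raw input
# string. Third-position statistics are defined on the 59-codon synonymous
# set: stops, ATG and TGG carry no synonymous choice and are excluded.
#
# The per-base third-position fractions (A3s, U3s, G3s, C3s) use per-base
# denominators: the X-ending codon count is divided by the count of
# synonymous codons belonging to families that possess at least one
# X-ending member. Under this convention the four values need not sum to 1.
# GC3s, by contrast, is taken over all synonymous codons, so GC3s is not
# G3s + C3s.

.third_base_tallies <- function(counts) {
  syn <- synonymous_codons()
  n <- unclass(counts)[syn]
  third <- substr(syn, 3L, 3L)
  list(codons = syn, counts = n, third = third, total = sum(n))
}

#' Overall nucleotide composition of a coding sequence
#'
#' @param record a `cds_record` (or nucleotide string).
#' @return Named list of percentages over the retained codon nucleotides:
#'   `a_pct`, `u_pct`, `g_pct`, `c_pct`, `au_pct`, `gc_pct`.
#' @export
nucleotide_composition <- function(record) {
  if (is.character(record)) record <- cds_record("(string)", record)
  chars <- strsplit(record$sequence, "")[[1]]
  if (length(chars) == 0L) stop("no retained codons")
  tab <- table(factor(chars, levels = c("A", "C", "G", "T")))
  pct <- 100 * as.numeric(tab) / length(chars)
  names(pct) <- c("A", "C", "G", "T")
  list(a_pct = pct[["A"]], u_pct = pct[["T"]], g_pct = pct[["G"]],
       c_pct = pct[["C"]],
       au_pct = pct[["A"]] + pct[["T"]],
       gc_pct = pct[["G"]] + pct[["C"]])
}

#' Positional GC content
#'
#' GC1 and GC2 are the G+C fractions at codon positions 1 and 2 over all
#' sense codons; GC3s is the G+C fraction at position 3 over synonymous
#' codons only; GC12 is the mean of GC1 and GC2.
#'
#' @param counts a `codon_counts` (or anything [count_codons()] accepts).
#' @return Named list `gc1`, `gc2`, `gc3s`, `gc12`, all fractions in
#'   `[0, 1]`; `gc3s` is `NA` when the sequence has no synonymous codons.
#' @export
positional_gc <- function(counts) {
  counts <- .as_counts(counts)
  sense <- sense_codons()
  n <- unclass(counts)[sense]
  if (sum(n) == 0L) stop("no sense codons")
  gc_at <- function(pos) {
    sum(n[substr(sense, pos, pos) %in% c("G", "C")]) / sum(n)
  }
  gc1 <- gc_at(1L)
  gc2 <- gc_at(2L)
  tb <- .third_base_tallies(counts)
  gc3s <- if (tb$total > 0L) {
    sum(tb$counts[tb$third %in% c("G", "C")]) / tb$total
  } else NA_real_
  list(gc1 = gc1, gc2 = gc2, gc3s = gc3s, gc12 = (gc1 + gc2) / 2)
}

#' Base composition at synonymous third positions
#'
#' For each base X, the fraction of synonymous codons ending in X among the
#' synonymous codons of families that contain at least one X-ending member
#' (per-base denominators). A base whose eligible-family denominator is zero
#' yields `NA`.
#'
#' @param counts a `codon_counts` (or anything [count_codons()] accepts).
#' @return Named list `a3s`, `u3s`, `g3s`, `c3s` (fractions).
#' @export
synonymous_third_bases <- function(counts) {
  counts <- .as_counts(counts)
  tb <- .third_base_tallies(counts)
  fams <- codon_families(synonymous_only = TRUE)
  out <- lapply(c(A = "A", T = "T", G = "G", C = "C"), function(base) {
    eligible <- names(fams)[vapply(fams, function(cods) {
      any(substr(cods, 3L, 3L) == base)
    }, logical(1))]
    denom_codons <- unlist(fams[eligible], use.names = FALSE)
    denom <- sum(tb$counts[tb$codons %in% denom_codons])
    if (denom == 0L) return(NA_real_)
    sum(tb$counts[tb$third == base]) / denom
  })
  list(a3s = out$A, u3s = out$T, g3s = out$G, c3s = out$C)
}

#' Full composition profile of one coding sequence
#'
#' Assembles the per-sequence composition row used by the pipeline's
#' composition table: overall base percentages, GC content (fraction),
#' third-position synonymous base fractions, GC3s, positional GC
#' percentages, AU/AU3 percentages, plus ENC, GRAVY and AROMA.
#'
#' Units mirror the conventional reporting layout: overall base content and
#' AU/AU3/GC1/GC2/GC12 as percentages, overall GC and the third-position
#' statistics as fractions.
#'
#' @param record a `cds_record`.
#' @return One-row data frame.
#' @export
composition_profile <- function(record) {
  if (is.character(record)) record <- cds_record("(string)", record)
  counts <- count_codons(record)
  comp <- nucleotide_composition(record)
  pgc <- positional_gc(counts)
  x3 <- synonymous_third_bases(counts)
  prot <- translate_cds(record)
  aa <- gsub("\\*", "", prot)
  data.frame(
    id = record$id,
    a_pct = comp$a_pct, u_pct = comp$u_pct,
    g_pct = comp$g_pct, c_pct = comp$c_pct,
    gc = comp$gc_pct / 100,
    u3s = x3$u3s, c3s = x3$c3s, a3s = x3$a3s, g3s = x3$g3s,
    gc3s = pgc$gc3s,
    enc = enc_observed(counts)$enc,
    au = comp$au_pct,
    au3 = if (is.na(pgc$gc3s)) NA_real_ else 100 * (1 - pgc$gc3s),
    gc1 = 100 * pgc$gc1, gc2 = 100 * pgc$gc2, gc12 = 100 * pgc$gc12,
    gravy = if (nchar(aa)) gravy(aa) else NA_real_,
    aroma = if (nchar(aa)) aroma(aa) else NA_real_,
    stringsAsFactors = FALSE)
}
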