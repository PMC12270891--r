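# Relative synonymous codon usage.
#
# RSCU_ij = x_ij / ((1/n_i) * sum_j x_ij): the observed count of codon j in
# family i relative to the count expected under equal use of the family's
# n_i synonyms. Families absent from a sequence yield NA (not 0): a zero
# would masquerade as "never used" and bias multi-sequence means.

#' Compute RSCU for one sequence
#'
#' @param counts a `codon_counts` (or anything [count_codons()] accepts).
#' @return An `rscu_table`: data frame with columns `aa`, `codon` (RNA
#'   alphabet), `dna` (DNA alphabet), `rscu` over the 59 synonymous codons;
#'   `rscu` is `NA` for codons of families absent from the sequence.
#' @export
compute_rscu <- function(counts) {
  counts <- .as_counts(counts)
  if (attr(counts, "n_sense") == 0L) stop("no sense codons")
  fams <- codon_families(synonymous_only = TRUE)
  rows <- lapply(names(fams), function(a) {
    cods <- fams[[a]]
    x <- unclass(counts)[cods]
    tot <- sum(x)
    rscu <- if (tot > 0L) x / (tot / length(cods)) else rep(NA_real_, length(cods))
    data.frame(aa = a, codon = dna_to_rna(cods), dna = cods,
               rscu = unname(rscu), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rscu_table", "data.frame")
  out
}

.check_rscu <- function(x) {
  stopifnot(is.data.frame(x), all(c("aa", "codon", "rscu") %in% names(x)))
  if (is.null(x$dna)) x$dna <- rna_to_dna(x$codon)
  x[order(match(x$dna, synonymous_codons())), ]
}

#' Mean RSCU across sequences
#'
#' Per-codon arithmetic mean over the tables in which the codon's family is
#' present; families missing from a table do not contribute to its mean.
#'
#' @param tables list of `rscu_table`.
#' @return An `rscu_table` of means.
#' @export
mean_rscu <- function(tables) {
  if (length(tables) == 0L) stop("empty list of RSCU tables")
  tables <- lapply(tables, .check_rscu)
  vals <- sapply(tables, function(t) t$rscu)
  out <- tables[[1]]
  out$rscu <- rowMeans(as.matrix(vals), na.rm = TRUE)
  out$rscu[is.nan(out$rscu)] <- NA_real_
  class(out) <- c("rscu_table", "data.frame")
  out
}

#' Classify codons by RSCU value
#'
#' Adds the two conventional label sets: `preference` (`preferred` for
#' RSCU > 1, `low` for RSCU < 1, `unbiased` at 1) and `representation`
#' (`over` above 1.6, `under` below 0.6, `normal` between). Inequalities
#' are strict.
#'
#' @param table an `rscu_table`.
#' @param over,under representation thresholds.
#' @return The table with `preference` and `representation` columns added.
#' @export
classify_rscu <- function(table, over = 1.6, under = 0.6) {
  table <- .check_rscu(table)
  r <- table$rscu
  table$preference <- ifelse(is.na(r), NA_character_,
    ifelse(abs(r - 1) < 1e-9, "unbiased", ifelse(r > 1, "preferred", "low")))
  table$representation <- ifelse(is.na(r), NA_character_,
    ifelse(r > over, "over", ifelse(r < under, "under", "normal")))
  table
}

#' Per-codon concordance between a virus and a host RSCU table
#'
#' A codon is concordant when both tables point the same way relative to the
#' no-bias value 1 (both above, or both below); values at exactly 1 form
#' their own `boundary` state and are never concordant with a non-boundary
#' value.
#'
#' @param virus,host `rscu_table`s over the same 59-codon set.
#' @return List with `per_codon` (data frame: codon, both directions,
#'   concordant flag) and `concordant` (count out of the comparable codons)
#'   and `n_compared`.
#' @export
compare_to_host <- function(virus, host) {
  virus <- .check_rscu(virus)
  host <- .check_rscu(host)
  stopifnot(identical(virus$dna, host$dna))
  dir <- function(r) ifelse(is.na(r), NA_character_,
    ifelse(abs(r - 1) < 1e-9, "boundary", ifelse(r > 1, "up", "down")))
  dv <- dir(virus$rscu)
  dh <- dir(host$rscu)
  conc <- !is.na(dv) & !is.na(dh) & dv == dh & dv != "boundary"
  conc[dv == "boundary" & dh == "boundary"] <- TRUE
  per <- data.frame(aa = virus$aa, codon = virus$codon,
                    virus = dv, host = dh, concordant = conc,
                    stringsAsFactors = FALSE)
  list(per_codon = per,
       concordant = sum(conc, na.rm = TRUE),
       n_compared = sum(!is.na(dv) & !is.na(dh)))
}

#' Published host codon-usage reference values
#'
#' RSCU reference values for four hosts/vectors of honeybee viruses — the
#' western honeybee (*Apis mellifera*), the eastern honeybee (*Apis
#' cerana*), the Asian hornet (*Vespa velutina*) and the mite *Varroa
#' destructor* — together with the published mean RSCU of the honeybee-virus
#' polyprotein coding sequences (`hv_mean`), shipped as a plain-text fixture.
#'
#' @return Data frame: `aa`, `codon` (RNA), `dna`, `hv_mean`, and one column
#'   per host species.
#' @export
host_rscu_table <- function() {
  path <- system.file("extdata", "host_rscu.tsv", package = "cubkit",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  tab$dna <- rna_to_dna(tab$codon)
  tab
}

#' Extract one host (or the virus-mean) column as an RSCU table
#'
#' @param species one of `"apis_mellifera"`, `"apis_cerana"`,
#'   `"vespa_velutina"`, `"varroa_destructor"`, `"hv_mean"`.
#' @return An `rscu_table`.
#' @export
host_rscu <- function(species = c("apis_mellifera", "apis_cerana",
                                  "vespa_velutina", "varroa_destructor",
                                  "hv_mean")) {
  species <- match.arg(species)
  tab <- host_rscu_table()
  out <- data.frame(aa = tab$aa, codon = tab$codon, dna = tab$dna,
                    rscu = tab[[species]], stringsAsFactors = FALSE)
  class(out) <- c("rscu_table", "data.frame")
  out
}
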