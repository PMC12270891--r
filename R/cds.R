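# Reading, validating and codon-decomposing coding sequences.
#
# Validation policy: the trailing partial codon of a CDS whose length is not
# a multiple of three is dropped with a warning note (deposited CDS sometimes
# include partial termini); `strict = TRUE` upgrades that to an error. Codons
# containing any symbol outside {A,C,G,T} after U->T normalisation are skipped
# from all counts and logged, because every downstream formula assumes
# unambiguous codons. Stop codons are retained in the codon list (and in the
# 64-codon count vector) but excluded from all sense-codon statistics.

.IUPAC <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")

#' Construct a validated coding-sequence record
#'
#' @param id sequence identifier.
#' @param sequence nucleotide string; DNA or RNA alphabet, any case.
#' @param desc optional description (rest of the FASTA header).
#' @param strict error (rather than warn) on a trailing partial codon.
#' @return An object of class `cds_record`: a list with elements `id`,
#'   `desc`, `sequence` (normalised, upper-case DNA), `codons` (retained
#'   unambiguous codons, including any stop codons), `n_skipped` (ambiguous
#'   codons dropped) and `warnings`.
#' @export
cds_record <- function(id, sequence, desc = "", strict = FALSE) {
  seq <- toupper(rna_to_dna(gsub("[[:space:]]", "", sequence)))
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), .IUPAC)
  if (length(bad)) {
    stop(sprintf("record '%s': non-nucleotide characters: %s",
                 id, paste(bad, collapse = ", ")))
  }
  warnings <- character(0)
  extra <- length(chars) %% 3L
  if (extra > 0L) {
    msg <- sprintf("trailing %d nt dropped", extra)
    if (strict) stop(sprintf("record '%s': %s (length %d not a multiple of 3)",
                             id, msg, length(chars)))
    warnings <- c(warnings, msg)
    chars <- chars[seq_len(length(chars) - extra)]
  }
  n_codons <- length(chars) %/% 3L
  codons <- if (n_codons > 0L) {
    substring(paste(chars, collapse = ""), 3L * seq_len(n_codons) - 2L,
              3L * seq_len(n_codons))
  } else character(0)
  clean <- grepl("^[ACGT]{3}$", codons)
  n_skipped <- sum(!clean)
  if (n_skipped > 0L) {
    warnings <- c(warnings, sprintf("%d ambiguous codon(s) skipped", n_skipped))
  }
  codons <- codons[clean]
  stops <- which(codons %in% stop_codons())
  if (length(stops) && any(stops < length(codons))) {
    warnings <- c(warnings, sprintf(
      "internal stop codon(s) at position(s) %s",
      paste(stops[stops < length(codons)], collapse = ", ")))
  }
  structure(list(id = id, desc = desc,
                 sequence = paste(codons, collapse = ""),
                 codons = codons, n_skipped = n_skipped,
                 warnings = warnings),
            class = "cds_record")
}

#' @export
print.cds_record <- function(x, ...) {
  cat(sprintf("<cds_record> %s: %d codon(s), %d skipped%s\n", x$id,
              length(x$codons), x$n_skipped,
              if (length(x$warnings))
                paste0(" [", paste(x$warnings, collapse = "; "), "]")
              else ""))
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' Multi-line FASTA, lower case and RNA alphabets are accepted; U is
#' normalised to T internally. Each entry is validated by [cds_record()].
#'
#' @param path FASTA file.
#' @param strict passed to [cds_record()].
#' @return List of `cds_record`.
#' @export
read_cds_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (!any(nzchar(trimws(readLines(path, warn = FALSE))))) {
    stop(sprintf("empty FASTA file: %s", path))
  }
  raw <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                       forceDNAtolower = FALSE, whole.header = TRUE),
    error = function(e) stop(sprintf("cannot parse FASTA '%s': %s",
                                     path, conditionMessage(e))))
  if (length(raw) == 0L) stop(sprintf("empty FASTA file: %s", path))
  unname(lapply(raw, function(s) {
    header <- attr(s, "Annot")
    header <- sub("^>", "", if (is.null(header)) attr(s, "name") else header)
    id <- strsplit(header, "[[:space:]]+")[[1]][1]
    desc <- sub("^[^[:space:]]+[[:space:]]*", "", header)
    cds_record(id, as.character(s), desc = desc, strict = strict)
  }))
}

#' Write coding-sequence records to FASTA
#'
#' @param records list of `cds_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path) {
  seqinr::write.fasta(
    sequences = lapply(records, function(r) strsplit(r$sequence, "")[[1]]),
    names = vapply(records, function(r) {
      if (nzchar(r$desc)) paste(r$id, r$desc) else r$id
    }, character(1)),
    file.out = path, nbchar = 70)
  invisible(path)
}

#' Count codons of a coding sequence
#'
#' @param x a `cds_record`, or a nucleotide string (validated on the fly).
#' @param ... passed on to methods.
#' @return An object of class `codon_counts`: a named integer vector over all
#'   64 codons (DNA alphabet, stop codons included), with attributes
#'   `n_sense` (total sense codons), `n_stop`, `n_skipped` and `id`.
#' @export
count_codons <- function(x, ...) UseMethod("count_codons")

#' @export
count_codons.character <- function(x, ...) {
  count_codons(cds_record("(string)", x), ...)
}

#' @export
count_codons.cds_record <- function(x, ...) {
  if (length(x$codons) == 0L) {
    stop(sprintf("record '%s': zero retained codons", x$id))
  }
  all64 <- genetic_code()$codon
  counts <- table(factor(x$codons, levels = all64))
  counts <- stats::setNames(as.integer(counts), all64)
  structure(counts,
            n_sense = sum(counts[sense_codons()]),
            n_stop = sum(counts[stop_codons()]),
            n_skipped = x$n_skipped,
            id = x$id,
            class = "codon_counts")
}

#' @export
count_codons.codon_counts <- function(x, ...) x

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf("<codon_counts> %s: %d sense codon(s), %d stop(s)\n",
              attr(x, "id"), attr(x, "n_sense"), attr(x, "n_stop")))
  print(unclass(x)[unclass(x) > 0])
  invisible(x)
}

.as_counts <- function(x) {
  if (inherits(x, "codon_counts")) x else count_codons(x)
}

#' Translate a coding sequence
#'
#' One residue per retained codon under the standard genetic code; stop
#' codons are rendered as `*`. The returned string carries attributes
#' `internal_stop` and `terminal_stop` flagging stop placement.
#'
#' @param record a `cds_record`.
#' @return Amino-acid string with stop flags as attributes.
#' @export
translate_cds <- function(record) {
  if (length(record$codons) == 0L) {
    stop(sprintf("record '%s': zero retained codons", record$id))
  }
  map <- stats::setNames(genetic_code()$aa, genetic_code()$codon)
  aa <- map[record$codons]
  stops <- which(aa == "*")
  structure(paste(aa, collapse = ""),
            internal_stop = any(stops < length(aa)),
            terminal_stop = length(stops) > 0 && stops[length(stops)] == length(aa))
}
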