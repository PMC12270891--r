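# Host-adaptation indices: CAI (geometric mean of relative adaptiveness
# weights) and RCDI (count-weighted mean of gene-to-host family-relative
# codon frequency ratios).
#
# Both indices depend on the host reference only through within-family
# relative codon frequencies, so a reference may be supplied as raw counts,
# Kazusa-style frequencies per thousand, or an RSCU table — all are reduced
# to the same family-relative form. Zero-valued reference codons receive a
# pseudocount of 0.5 before normalisation to keep log-weights and frequency
# ratios finite; the choice is recorded in the object.

#' Build a host codon-usage reference
#'
#' @param x named numeric vector (names are codons, DNA or RNA alphabet) or
#'   data frame with columns `codon` and a single value column, covering all
#'   61 sense codons (stop codons, if present, are ignored).
#' @param source label for the host/source.
#' @param kind how to read the values: raw `"counts"`, Kazusa
#'   `"per_thousand"`, or `"rscu"`. All reduce to within-family relative
#'   frequencies, so the choice only matters for documentation.
#' @param pseudocount value substituted for zeros before normalisation.
#' @return A `reference_usage`: list with `cif` (family-relative frequency
#'   per sense codon, DNA-named; Met and Trp are 1), `w` (CAI weights,
#'   max 1 per family), `rscu` (reference RSCU), `source`, `kind`,
#'   `pseudocount`.
#' @export
reference_usage <- function(x, source = "", kind = c("counts", "per_thousand",
                                                     "rscu"),
                            pseudocount = 0.5) {
  kind <- match.arg(kind)
  if (is.data.frame(x)) {
    value_col <- setdiff(names(x), "codon")[1]
    x <- stats::setNames(x[[value_col]], x$codon)
  }
  if (is.null(names(x))) stop("reference values must be named by codon")
  names(x) <- toupper(rna_to_dna(names(x)))
  x <- x[!names(x) %in% stop_codons()]
  # Met and Trp have no synonymous choice: their value is information-free,
  # so tables restricted to the 59 synonymous codons are accepted.
  for (single in c("ATG", "TGG")) {
    if (!single %in% names(x)) x[single] <- 1
  }
  missing <- setdiff(sense_codons(), names(x))
  if (length(missing)) {
    stop(sprintf("reference is missing %d codon(s): %s", length(missing),
                 paste(dna_to_rna(missing), collapse = ", ")))
  }
  x <- x[sense_codons()]
  if (any(!is.finite(x)) || any(x < 0)) stop("reference values must be finite and non-negative")
  if (sum(x) <= 0) stop("reference has non-positive total usage")
  x[x == 0] <- pseudocount
  fams <- codon_families()
  cif <- w <- rscu <- stats::setNames(numeric(length(x)), names(x))
  for (cods in fams) {
    v <- x[cods]
    cif[cods] <- v / sum(v)
    w[cods] <- v / max(v)
    rscu[cods] <- v / (sum(v) / length(v))
  }
  structure(list(source = source, kind = kind, pseudocount = pseudocount,
                 cif = cif, w = w, rscu = rscu),
            class = "reference_usage")
}

#' @export
print.reference_usage <- function(x, ...) {
  cat(sprintf("<reference_usage> %s (from %s; pseudocount %g)\n",
              if (nzchar(x$source)) x$source else "(unnamed)",
              x$kind, x$pseudocount))
  invisible(x)
}

#' Read a codon usage table from disk
#'
#' Accepts either the Kazusa-style layout (`UUU 17.6( 714298)` fields, any
#' number per line — the parenthesised counts are used) or a two-column
#' CSV `codon,count` with optional header.
#'
#' @param path file to read.
#' @param source label for the resulting reference (defaults to the file
#'   name).
#' @param ... passed to [reference_usage()].
#' @return A `reference_usage`.
#' @export
read_usage_table <- function(path, source = basename(path), ...) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  body <- trimws(lines)
  keep <- nzchar(body) & !startsWith(body, "#")
  if (!any(keep)) stop(sprintf("empty usage table: %s", path))
  kazusa <- any(grepl("\\(", body[keep]))
  counts <- c()
  if (kazusa) {
    pat <- "([ACGTUacgtu]{3})\\s+[0-9.]+\\s*\\(\\s*([0-9]+)\\s*\\)"
    for (i in which(keep)) {
      m <- regmatches(body[i], gregexpr(pat, body[i]))[[1]]
      if (length(m) == 0L) {
        stop(sprintf("%s: cannot parse line %d: '%s'", path, i, lines[i]))
      }
      cod <- sub(pat, "\\1", m)
      val <- as.numeric(sub(pat, "\\2", m))
      counts[toupper(cod)] <- val
    }
  } else {
    for (i in which(keep)) {
      fields <- trimws(strsplit(body[i], "[,\t]")[[1]])
      if (length(fields) < 2L) {
        stop(sprintf("%s: cannot parse line %d: '%s'", path, i, lines[i]))
      }
      if (grepl("^[ACGTUacgtu]{3}$", fields[1])) {
        val <- suppressWarnings(as.numeric(fields[2]))
        if (is.na(val)) {
          stop(sprintf("%s: non-numeric value on line %d: '%s'",
                       path, i, lines[i]))
        }
        counts[toupper(fields[1])] <- val
      } else if (i == which(keep)[1]) {
        next  # header line
      } else {
        stop(sprintf("%s: cannot parse line %d: '%s'", path, i, lines[i]))
      }
    }
  }
  reference_usage(counts, source = source, ...)
}

#' Host reference from the packaged RSCU fixture
#'
#' @inheritParams host_rscu
#' @param ... passed to [reference_usage()].
#' @return A `reference_usage` built from the published host RSCU values.
#' @export
host_reference <- function(species = c("apis_mellifera", "apis_cerana",
                                       "vespa_velutina", "varroa_destructor"),
                           ...) {
  species <- match.arg(species)
  tab <- host_rscu(species)
  reference_usage(stats::setNames(tab$rscu, tab$dna), source = species,
                  kind = "rscu", ...)
}

#' Codon adaptation index
#'
#' Geometric mean of the reference relative-adaptiveness weights of the
#' codons used by the query: CAI = exp((1/L) * sum over sense codons of
#' log w). Stop codons are excluded; AUG and UGG carry weight 1 (a no-op
#' that keeps L equal to the sense-codon count).
#'
#' @param counts query `codon_counts` (or anything [count_codons()]
#'   accepts).
#' @param ref a `reference_usage`.
#' @return CAI in (0, 1]; 1 iff every used codon has the maximum weight of
#'   its family.
#' @export
cai <- function(counts, ref) {
  stopifnot(inherits(ref, "reference_usage"))
  counts <- .as_counts(counts)
  n <- unclass(counts)[sense_codons()]
  L <- sum(n)
  if (L == 0L) stop("no sense codons")
  w <- ref$w[sense_codons()]
  if (any(n > 0 & (!is.finite(w) | w <= 0))) {
    stop("used codon(s) with undefined reference weight")
  }
  used <- n > 0
  exp(sum(n[used] * log(w[used])) / L)
}

#' Relative codon deoptimization index
#'
#' RCDI = sum over used codons j of (CiF_q(j) / CiF_h(j)) * N_j / N, where
#' CiF are within-family relative codon frequencies in the query (q) and
#' host (h), N_j the query's count of codon j and N its total sense-codon
#' count. Equals 1 when the query's family-relative usage matches the host
#' everywhere, and exceeds 1 otherwise.
#'
#' @inheritParams cai
#' @return RCDI `>= 1` (up to floating-point tolerance).
#' @export
rcdi <- function(counts, ref) {
  stopifnot(inherits(ref, "reference_usage"))
  counts <- .as_counts(counts)
  n <- unclass(counts)[sense_codons()]
  N <- sum(n)
  if (N == 0L) stop("no sense codons")
  fams <- codon_families()
  total <- 0
  for (cods in fams) {
    nf <- sum(n[cods])
    if (nf == 0L) next
    cif_q <- n[cods] / nf
    total <- total + sum((cif_q / ref$cif[cods]) * n[cods] / N)
  }
  total
}
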