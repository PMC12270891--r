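# Dinucleotide odds ratios (relative dinucleotide abundance).
#
# rho_xy = f_xy / (f_x * f_y), with f_x the mononucleotide frequencies over
# the retained codon string (all L bases) and f_xy the frequencies of the
# L - 1 overlapping dinucleotides of the same string (no wrap-around, never
# across sequence junctions). rho below 0.78 marks under-representation,
# above 1.23 over-representation.

.DINUCS <- as.vector(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             paste0)))

#' Dinucleotide odds ratios of one coding sequence
#'
#' For a `cds_record` the retained codon string is used; a raw nucleotide
#' string is used as given (after U/T and case normalisation), so partial
#' codons at its end still count.
#'
#' @param record a `cds_record` or nucleotide string.
#' @return A `dinucleotide_profile`: data frame with `dinucleotide` (RNA
#'   alphabet), `f_xy`, `rho` (NA when `f_x * f_y = 0`); attributes `mono`
#'   (mononucleotide frequencies) and `id`.
#' @export
dinucleotide_odds <- function(record) {
  if (is.character(record)) {
    s <- toupper(rna_to_dna(gsub("[[:space:]]", "", record)))
    if (grepl("[^ACGT]", s)) stop("string input must be unambiguous A/C/G/T(/U)")
    record <- list(id = "(string)", sequence = s)
  }
  s <- record$sequence
  L <- nchar(s)
  if (L < 2L) stop(sprintf("record '%s': retained sequence shorter than 2 nt",
                           record$id))
  chars <- strsplit(s, "")[[1]]
  mono <- as.vector(table(factor(chars, levels = c("A", "C", "G", "T")))) / L
  names(mono) <- c("A", "C", "G", "T")
  dins <- paste0(chars[-L], chars[-1L])
  fxy <- as.vector(table(factor(dins, levels = .DINUCS))) / (L - 1L)
  names(fxy) <- .DINUCS
  expected <- mono[substr(.DINUCS, 1L, 1L)] * mono[substr(.DINUCS, 2L, 2L)]
  rho <- ifelse(expected > 0, fxy / expected, NA_real_)
  out <- data.frame(dinucleotide = dna_to_rna(.DINUCS),
                    f_xy = unname(fxy), rho = unname(rho),
                    stringsAsFactors = FALSE)
  structure(out, mono = mono, id = record$id,
            class = c("dinucleotide_profile", "data.frame"))
}

#' Mean dinucleotide profile
#'
#' Per-dinucleotide arithmetic mean of rho (and f_xy) over profiles. When
#' `groups` is supplied the mean is two-level: mean within each group, then
#' the mean of the group means — the convention used for a grand mean over
#' several virus species with unequal sequence numbers.
#'
#' @param profiles list of `dinucleotide_profile`.
#' @param groups optional factor/character of length `length(profiles)`.
#' @return A `dinucleotide_profile` of means.
#' @export
mean_dinucleotide_profile <- function(profiles, groups = NULL) {
  if (length(profiles) == 0L) stop("empty list of profiles")
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(profiles))
    per_group <- lapply(split(profiles, groups), mean_dinucleotide_profile)
    return(mean_dinucleotide_profile(per_group))
  }
  rho <- rowMeans(sapply(profiles, function(p) p$rho), na.rm = TRUE)
  fxy <- rowMeans(sapply(profiles, function(p) p$f_xy), na.rm = TRUE)
  out <- profiles[[1]]
  out$rho <- rho
  out$f_xy <- fxy
  attr(out, "id") <- "(mean)"
  out
}

#' Classify dinucleotides by odds ratio
#'
#' @param profile a `dinucleotide_profile`.
#' @param over,under classification thresholds.
#' @return The profile with a `representation` column (`over`/`under`/
#'   `normal`).
#' @export
classify_dinucleotides <- function(profile, over = 1.23, under = 0.78) {
  r <- profile$rho
  profile$representation <- ifelse(is.na(r), NA_character_,
    ifelse(r > over, "over", ifelse(r < under, "under", "normal")))
  profile
}
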