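# Seeded synthetic coding-sequence generator.
#
# Sequences are generated codon-by-codon: an amino acid is drawn from a
# composition vector, then a codon from that family's probability vector.
# Family vectors can be set directly, derived from a Wright-null GC3s dial
# (probability theta spread evenly over G/C-ending synonyms), or copied
# from a host reference. A CpG-depletion multiplier reweights codons
# containing CG within each family; dinucleotide structure across codon
# boundaries is emergent, not controlled. Draws use R's default
# Mersenne-Twister generator, so a fixed seed gives bit-reproducible
# output on any platform.

.validate_family_probs <- function(probs) {
  fams <- codon_families()
  out <- list()
  for (a in names(fams)) {
    p <- probs[[a]]
    if (is.null(p)) {
      p <- stats::setNames(rep(1 / length(fams[[a]]), length(fams[[a]])),
                           fams[[a]])
    }
    names(p) <- toupper(rna_to_dna(names(p)))
    if (!setequal(names(p), fams[[a]])) {
      stop(sprintf("family '%s': probabilities must cover exactly %s", a,
                   paste(fams[[a]], collapse = ", ")))
    }
    p <- p[fams[[a]]]
    if (any(p < 0) || sum(p) <= 0) {
      stop(sprintf("family '%s': invalid probabilities", a))
    }
    out[[a]] <- p / sum(p)
  }
  out
}

.theta_family_probs <- function(theta) {
  stopifnot(theta >= 0, theta <= 1)
  fams <- codon_families()
  out <- list()
  for (a in names(fams)) {
    cods <- fams[[a]]
    gc_end <- substr(cods, 3L, 3L) %in% c("G", "C")
    p <- numeric(length(cods))
    if (any(gc_end) && any(!gc_end)) {
      p[gc_end] <- theta / sum(gc_end)
      p[!gc_end] <- (1 - theta) / sum(!gc_end)
    } else {
      p[] <- 1 / length(cods)  # family lacks one class: uniform fallback
    }
    out[[a]] <- stats::setNames(p, cods)
  }
  out
}

.host_family_probs <- function(ref) {
  stopifnot(inherits(ref, "reference_usage"))
  fams <- codon_families()
  lapply(fams, function(cods) ref$cif[cods])
}

.apply_cg_depletion <- function(probs, factor) {
  stopifnot(factor > 0)
  lapply(probs, function(p) {
    w <- p * ifelse(grepl("CG", names(p)), factor, 1)
    if (sum(w) <= 0) p else w / sum(w)
  })
}

#' Specify a synthetic CDS set
#'
#' Exactly one source of family codon probabilities applies, in order of
#' precedence: `family_probs` (explicit per-family vectors), `gc3_theta`
#' (Wright-null dial: probability mass `theta` on G/C-ending synonyms,
#' split evenly, families lacking one class fall back to uniform), `host`
#' (a [reference_usage()] to mimic), else uniform within every family.
#'
#' @param n_seq number of sequences.
#' @param length sequence length in codons.
#' @param seed integer seed; fixed seed means bit-reproducible output.
#' @param aa_freq named amino-acid composition vector (default uniform over
#'   the 20 standard amino acids).
#' @param family_probs named list: amino acid -> codon probability vector.
#' @param gc3_theta Wright-null GC3s dial in `[0, 1]`.
#' @param host a `reference_usage` whose family-relative frequencies are
#'   copied.
#' @param cg_depletion multiplicative down-weight for codons containing the
#'   CG dinucleotide (1 = none).
#' @param label prefix for sequence identifiers.
#' @return A `generator_spec`.
#' @export
generator_spec <- function(n_seq, length, seed = 1L, aa_freq = NULL,
                           family_probs = NULL, gc3_theta = NULL,
                           host = NULL, cg_depletion = 1,
                           label = "synth") {
  stopifnot(n_seq >= 1, length >= 1)
  fams <- codon_families()
  n_fam <- base::length(fams)
  if (is.null(aa_freq)) {
    aa_freq <- stats::setNames(rep(1 / n_fam, n_fam), names(fams))
  }
  if (is.null(names(aa_freq)) || !all(names(aa_freq) %in% names(fams))) {
    stop("aa_freq must be named by one-letter amino acid")
  }
  if (any(aa_freq < 0) || sum(aa_freq) <= 0) stop("invalid aa_freq")
  aa_freq <- aa_freq / sum(aa_freq)
  probs <- if (!is.null(family_probs)) {
    .validate_family_probs(family_probs)
  } else if (!is.null(gc3_theta)) {
    .theta_family_probs(gc3_theta)
  } else if (!is.null(host)) {
    .host_family_probs(host)
  } else {
    .validate_family_probs(list())
  }
  probs <- .apply_cg_depletion(probs, cg_depletion)
  structure(list(n_seq = as.integer(n_seq), length = as.integer(length),
                 seed = as.integer(seed), aa_freq = aa_freq,
                 family_probs = probs, gc3_theta = gc3_theta,
                 cg_depletion = cg_depletion, label = label),
            class = "generator_spec")
}

#' Generate a synthetic CDS set
#'
#' @param spec a [generator_spec()].
#' @param fasta optional path; when given, the set is also written as FASTA
#'   and the spec serialised as a `key = value` config next to it.
#' @return List of `cds_record`.
#' @export
generate_cds_set <- function(spec, fasta = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  aa_names <- names(spec$aa_freq)
  records <- vector("list", spec$n_seq)
  for (i in seq_len(spec$n_seq)) {
    aa <- sample(aa_names, spec$length, replace = TRUE, prob = spec$aa_freq)
    codons <- character(spec$length)
    for (a in unique(aa)) {
      idx <- which(aa == a)
      p <- spec$family_probs[[a]]
      codons[idx] <- if (length(p) == 1L) {
        names(p)
      } else {
        sample(names(p), length(idx), replace = TRUE, prob = p)
      }
    }
    records[[i]] <- cds_record(sprintf("%s_%03d", spec$label, i),
                               paste(codons, collapse = ""))
  }
  if (!is.null(fasta)) {
    write_cds_fasta(records, fasta)
    cfg <- c(sprintf("label = %s", spec$label),
             sprintf("n_seq = %d", spec$n_seq),
             sprintf("length = %d", spec$length),
             sprintf("seed = %d", spec$seed),
             sprintf("gc3_theta = %s",
                     if (is.null(spec$gc3_theta)) "NA" else spec$gc3_theta),
             sprintf("cg_depletion = %g", spec$cg_depletion))
    writeLines(cfg, paste0(fasta, ".cfg"))
  }
  records
}

#' Wright-null synthetic set
#'
#' Codon choice depends only on the third-base GC dial `theta`; the
#' resulting (GC3s, ENC) points track the [enc_expected()] null curve.
#'
#' @param theta GC3s dial in `[0, 1]`.
#' @param n number of sequences.
#' @param length sequence length in codons.
#' @param seed integer seed.
#' @param ... passed to [generator_spec()].
#' @return List of `cds_record`.
#' @export
wright_null_set <- function(theta, n, length, seed = 1L, ...) {
  generate_cds_set(generator_spec(n, length, seed = seed, gc3_theta = theta,
                                  label = sprintf("null%02.0f", 100 * theta),
                                  ...))
}

#' Host-matched synthetic set
#'
#' Codons are drawn with the host's family-relative frequencies, providing
#' ground truth for CAI and RCDI (RCDI -> 1, CAI -> its analytic
#' expectation).
#'
#' @param ref a `reference_usage`.
#' @inheritParams wright_null_set
#' @return List of `cds_record`.
#' @export
host_matched_set <- function(ref, n, length, seed = 1L, ...) {
  generate_cds_set(generator_spec(n, length, seed = seed, host = ref,
                                  label = "hostmatched", ...))
}

#' Virus-like preset generator specs
#'
#' Four presets mirroring the shape of the honeybee-virus polyprotein study
#' sets: A/U-rich coding sequences of ~2,800 codons with GC3s dials between
#' 0.23 and 0.54, CpG depletion 0.5, and set sizes 43 (ABPV-like), 57
#' (CBPV-like), 8 (KBV-like) and 96 (SBV-like).
#'
#' @param seed base seed; each preset uses `seed * 10 + k`.
#' @param n_seq,length optional overrides (scaling all four presets down is
#'   useful for quick runs).
#' @return Named list of `generator_spec`.
#' @export
virus_presets <- function(seed = 1L, n_seq = NULL, length = NULL) {
  base <- list(
    ABPV = list(n = 43L, L = 2780L, theta = 0.23),
    CBPV = list(n = 57L, L = 2800L, theta = 0.54),
    KBV  = list(n = 8L,  L = 2850L, theta = 0.31),
    SBV  = list(n = 96L, L = 2790L, theta = 0.31))
  out <- list()
  for (k in seq_along(base)) {
    b <- base[[k]]
    out[[names(base)[k]]] <- generator_spec(
      n_seq = if (is.null(n_seq)) b$n else n_seq,
      length = if (is.null(length)) b$L else length,
      seed = seed * 10L + k,
      gc3_theta = b$theta,
      cg_depletion = 0.5,
      label = names(base)[k])
  }
  out
}
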