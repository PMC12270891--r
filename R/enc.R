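# Wright's effective number of codons.
#
# For each amino-acid family with n codons observed, the homozygosity
# estimator is F = (n * sum(p^2) - 1) / (n - 1), with p the within-family
# codon proportions. Families are grouped by degeneracy (2-fold x9, 3-fold
# x1 [Ile], 4-fold x5, 6-fold x3 [Leu, Ser, Arg kept whole]) and
#
#   ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6
#
# with Fk the mean F of the class. Families with fewer than 2 codons or
# F <= 0 are excluded from their class mean; a missing 3-fold class (Ile
# absent) is imputed as (F2 + F4)/2; sampling noise can push ENC above 61,
# in which case it is capped at 61. Both repairs are logged in `notes`.

.degeneracy_classes <- function() {
  deg <- family_degeneracy()
  split(names(deg)[deg > 1L], deg[deg > 1L])
}

#' Observed effective number of codons
#'
#' @param counts a `codon_counts` (or anything [count_codons()] accepts).
#' @return List of class `enc_result`: `enc` (NA when a 2-, 4- or 6-fold
#'   class has no usable family), `fbar` (named mean homozygosity per
#'   degeneracy class), `notes` (imputation / capping / missing-class log).
#' @export
enc_observed <- function(counts) {
  counts <- .as_counts(counts)
  fams <- codon_families()
  notes <- character(0)
  fhat <- vapply(names(fams), function(a) {
    x <- unclass(counts)[fams[[a]]]
    n <- sum(x)
    if (length(x) == 1L || n < 2L) return(NA_real_)
    p <- x / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) NA_real_ else f
  }, numeric(1))
  classes <- .degeneracy_classes()
  fbar <- vapply(classes, function(members) {
    v <- fhat[members]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (is.na(fbar[["3"]])) {
    if (!is.na(fbar[["2"]]) && !is.na(fbar[["4"]])) {
      fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
      notes <- c(notes, "F3 imputed as (F2 + F4)/2")
    }
  }
  weights <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  enc <- if (anyNA(fbar)) {
    notes <- c(notes, sprintf("class(es) %s unusable; ENC missing",
                              paste(names(fbar)[is.na(fbar)], collapse = ",")))
    NA_real_
  } else {
    2 + sum(weights / fbar[names(weights)])
  }
  if (!is.na(enc) && enc > 61) {
    notes <- c(notes, sprintf("ENC %.4f capped at 61", enc))
    enc <- 61
  }
  structure(list(enc = enc, fbar = fbar, notes = notes),
            class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("<enc_result> ENC = %s\n",
              if (is.na(x$enc)) "NA" else sprintf("%.3f", x$enc)))
  if (length(x$notes)) cat(paste0("  note: ", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Expected ENC under third-position mutation pressure alone
#'
#' Wright's null curve: the ENC expected when synonymous codon choice is
#' driven solely by the G+C content at synonymous third positions,
#'
#'   ENC_exp(s) = 2 + s + 29 / (s^2 + (1 - s)^2).
#'
#' @param gc3s GC3s value(s) in `[0, 1]`; vectorised.
#' @return Expected ENC (maximum 61 at s ~ 0.5; 31 at s = 0; 32 at s = 1).
#' @export
enc_expected <- function(gc3s) {
  if (any(is.na(gc3s)) || any(gc3s < 0 | gc3s > 1)) {
    stop("gc3s must lie in [0, 1]")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}
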