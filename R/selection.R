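# Mutation-vs-selection analysis layer: PR2 coordinates, neutrality
# regression, correspondence analysis of RSCU profiles, protein GRAVY /
# AROMA, and the index correlation matrix.

#' PR2 (parity rule 2) coordinates
#'
#' Third-position base counts are tallied over synonymous codons (the
#' 59-codon set) and reported as x = G3/(G3+C3), y = A3/(A3+U3). A point at
#' (0.5, 0.5) means no bias between complementary bases at the third
#' position. The classical fourfold-degenerate-only variant is available
#' via `fourfold_only`.
#'
#' @param counts a `codon_counts` (or anything [count_codons()] accepts).
#' @param fourfold_only restrict the tally to fourfold-degenerate families.
#' @return Named list `x`, `y` (NA where the denominator is zero) plus the
#'   raw third-base counts `a3`, `u3`, `g3`, `c3`.
#' @export
pr2_point <- function(counts, fourfold_only = FALSE) {
  counts <- .as_counts(counts)
  fams <- codon_families(synonymous_only = TRUE)
  if (fourfold_only) fams <- fams[lengths(fams) == 4L]
  cods <- unlist(fams, use.names = FALSE)
  n <- unclass(counts)[cods]
  third <- substr(cods, 3L, 3L)
  tot <- function(b) sum(n[third == b])
  a3 <- tot("A"); u3 <- tot("T"); g3 <- tot("G"); c3 <- tot("C")
  list(x = if (g3 + c3 > 0) g3 / (g3 + c3) else NA_real_,
       y = if (a3 + u3 > 0) a3 / (a3 + u3) else NA_real_,
       a3 = a3, u3 = u3, g3 = g3, c3 = c3)
}

#' Neutrality regression of GC12 on GC3s
#'
#' Ordinary least squares of GC12 (mean of first- and second-position GC)
#' on GC3s. The slope estimates the share of codon-usage variation
#' attributable to mutation pressure; 1 - slope estimates the share due to
#' selection.
#'
#' @param gc3s,gc12 numeric vectors, or a data frame with columns `gc3s`
#'   and `gc12` passed as the first argument.
#' @return List of class `neutrality_fit`: `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided, for the slope), `slope_ci` (95%),
#'   `n`, `mutation_pct`, `selection_pct`.
#' @export
neutrality_fit <- function(gc3s, gc12 = NULL) {
  if (is.data.frame(gc3s)) {
    gc12 <- gc3s$gc12
    gc3s <- gc3s$gc3s
  }
  keep <- is.finite(gc3s) & is.finite(gc12)
  x <- gc3s[keep]; y <- gc12[keep]
  if (length(x) < 3L) stop("need at least 3 complete points")
  if (stats::var(x) == 0) stop("zero variance in GC3s: slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  # constant response: slope 0 with no explained (or explainable) variance
  r2 <- if (stats::var(y) == 0) 0 else sm$r.squared
  pval <- if (stats::var(y) == 0) 1 else sm$coefficients[2, 4]
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 p_value = pval,
                 slope_ci = unname(stats::confint(fit)[2, ]),
                 n = length(x),
                 mutation_pct = 100 * slope,
                 selection_pct = 100 * (1 - slope)),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "<neutrality_fit> n = %d: GC12 = %.4f + %.4f GC3s (R2 = %.4f, p = %.3g)\n",
    x$n, x$intercept, x$slope, x$r_squared, x$p_value))
  cat(sprintf("  mutation %.2f%% / selection %.2f%%\n",
              x$mutation_pct, x$selection_pct))
  invisible(x)
}

#' Correspondence analysis of an RSCU matrix
#'
#' Chi-square-metric decomposition of a sequences x codons RSCU matrix:
#' the matrix is scaled to proportions P, standardised residuals
#' S = Dr^(-1/2) (P - r c^T) Dc^(-1/2) are decomposed by SVD, and axis k
#' carries inertia sigma_k^2 / sum(sigma^2). Missing RSCU entries (absent
#' families in short sequences) are imputed with the neutral value 1 so
#' that absence does not create artificial inertia.
#'
#' @param x numeric matrix (or data frame), rows = sequences, columns =
#'   codons (typically the 59 RSCU values).
#' @param n_axes number of axes to return coordinates for.
#' @return List of class `coa_result`: `row_coords`, `col_coords`
#'   (principal coordinates, `n_axes` columns), `inertia_pct`
#'   (non-increasing, sums to 100 of the nonzero total), `total_inertia`,
#'   `singular_values`, `n_imputed`, `degenerate` (TRUE when total inertia
#'   is 0 and fractions are undefined).
#' @export
coa_rscu <- function(x, n_axes = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows for correspondence analysis")
  n_imputed <- sum(is.na(x))
  x[is.na(x)] <- 1
  if (any(x < 0)) stop("RSCU values must be non-negative")
  if (any(rowSums(x) == 0)) stop("row(s) with zero total usage")
  P <- x / sum(x)
  r <- rowSums(P)
  cc <- colSums(P)
  keep_col <- cc > 0
  S <- (P[, keep_col, drop = FALSE] - r %o% cc[keep_col]) /
    sqrt(r %o% cc[keep_col])
  sv <- svd(S)
  max_axes <- min(nrow(x), sum(keep_col)) - 1L
  d <- sv$d[seq_len(max_axes)]
  total <- sum(d^2)
  degenerate <- total < 1e-12
  inertia_pct <- if (degenerate) rep(NA_real_, length(d)) else 100 * d^2 / total
  k <- min(n_axes, length(d))
  row_coords <- sweep(sv$u[, seq_len(k), drop = FALSE], 2, d[seq_len(k)], `*`) /
    sqrt(r)
  col_coords <- matrix(NA_real_, ncol(x), k,
                       dimnames = list(colnames(x), paste0("axis", seq_len(k))))
  col_coords[keep_col, ] <-
    sweep(sv$v[, seq_len(k), drop = FALSE], 2, d[seq_len(k)], `*`) /
    sqrt(cc[keep_col])
  rownames(row_coords) <- rownames(x)
  colnames(row_coords) <- paste0("axis", seq_len(k))
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 inertia_pct = inertia_pct, total_inertia = total,
                 singular_values = d, n_imputed = n_imputed,
                 degenerate = degenerate),
            class = "coa_result")
}

#' @export
print.coa_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<coa_result> degenerate: total inertia 0 (identical profiles)\n")
  } else {
    cat(sprintf("<coa_result> total inertia %.4g; axes: %s\n",
                x$total_inertia,
                paste(sprintf("%.2f%%", utils::head(x$inertia_pct, 4)),
                      collapse = ", ")))
  }
  invisible(x)
}

# Kyte-Doolittle hydropathy scale
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

.residues <- function(protein) {
  chars <- strsplit(toupper(protein), "")[[1]]
  chars <- chars[chars %in% names(.KD)]
  if (length(chars) == 0L) stop("no standard residues after exclusions")
  chars
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the standard residues of a protein;
#' stops and unknown symbols are excluded. The mean is bounded by the scale
#' itself (-4.5 to 4.5); positive values indicate hydrophobic proteins.
#'
#' @param protein amino-acid string (one-letter code).
#' @return Mean hydropathy.
#' @export
gravy <- function(protein) {
  mean(.KD[.residues(protein)])
}

#' Aromaticity (AROMA)
#'
#' Fraction of aromatic residues (Phe, Tyr, Trp) among the standard
#' residues of a protein.
#'
#' @inheritParams gravy
#' @return Fraction in `[0, 1]`.
#' @export
aroma <- function(protein) {
  chars <- .residues(protein)
  mean(chars %in% c("F", "Y", "W"))
}

#' Pairwise Pearson correlation matrix of codon-usage indices
#'
#' Pearson r and two-sided p-value for every pair of the requested columns,
#' computed on pairwise-complete cases. Pairs involving a zero-variance
#' index are NA.
#'
#' @param data data frame of per-sequence indices.
#' @param rows,cols column names selecting the matrix rows and columns
#'   (default: all numeric columns for both).
#' @param alpha significance threshold recorded in the `significant`
#'   matrix.
#' @return List of class `correlation_matrix`: matrices `r`, `p`,
#'   `n`, and logical `significant` (`p < alpha`).
#' @export
correlation_matrix <- function(data, rows = NULL, cols = NULL, alpha = 0.05) {
  numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (is.null(rows)) rows <- numeric_cols
  if (is.null(cols)) cols <- numeric_cols
  stopifnot(all(c(rows, cols) %in% names(data)))
  r <- p <- n <- matrix(NA_real_, length(rows), length(cols),
                        dimnames = list(rows, cols))
  for (i in rows) {
    for (j in cols) {
      x <- data[[i]]; y <- data[[j]]
      keep <- is.finite(x) & is.finite(y)
      n[i, j] <- sum(keep)
      if (sum(keep) < 3L) next
      if (stats::var(x[keep]) == 0 || stats::var(y[keep]) == 0) next
      if (identical(i, j)) {
        r[i, j] <- 1; p[i, j] <- 0
      } else {
        ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
        r[i, j] <- unname(ct$estimate)
        p[i, j] <- ct$p.value
      }
    }
  }
  structure(list(r = r, p = p, n = n, significant = p < alpha, alpha = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<correlation_matrix> (* = p < %g)\n", x$alpha))
  disp <- matrix(sprintf("%.*f%s", digits, x$r,
                         ifelse(!is.na(x$significant) & x$significant,
                                "*", "")),
                 nrow(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "."
  print(disp, quote = FALSE)
  invisible(x)
}
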