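# Independent brute-force oracles. These deliberately re-derive each
# statistic from its definition with naive loops over the code table, so
# they share no code path with the implementation they check.

oracle_code <- local({
  bases <- c("T", "C", "A", "G")
  codons <- character(0)
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    codons <- c(codons, paste0(b1, b2, b3))
  }
  aa <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]], numcode = 1)
  }, character(1))
  data.frame(codon = codons, aa = unname(aa), stringsAsFactors = FALSE)
})

oracle_families <- local({
  tab <- oracle_code[oracle_code$aa != "*", ]
  split(tab$codon, tab$aa)
})

# random codon-count object built from a random codon sequence
random_counts <- function(n_codons = 60, include_rare = TRUE) {
  pool <- oracle_code$codon[oracle_code$aa != "*"]
  probs <- stats::runif(length(pool), 0.05, 1)
  if (include_rare) probs[sample(length(pool), 20)] <- 0
  codons <- sample(pool, n_codons, replace = TRUE, prob = probs)
  count_codons(paste(codons, collapse = ""))
}

# RSCU straight from the definition
oracle_rscu <- function(counts) {
  out <- list()
  for (a in names(oracle_families)) {
    cods <- oracle_families[[a]]
    if (length(cods) == 1L) next
    x <- unclass(counts)[cods]
    tot <- sum(x)
    for (j in seq_along(cods)) {
      out[[cods[j]]] <- if (tot == 0) NA_real_ else
        x[[j]] / (tot / length(cods))
    }
  }
  out
}

# Wright's ENC from the definition, written as an explicit per-class loop
oracle_enc <- function(counts) {
  deg <- lengths(oracle_families)
  class_f <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (a in names(oracle_families)) {
    k <- deg[[a]]
    if (k == 1L) next
    x <- unclass(counts)[oracle_families[[a]]]
    n <- sum(x)
    if (n < 2) next
    p2 <- sum((x / n)^2)
    f <- (n * p2 - 1) / (n - 1)
    if (f > 0) class_f[[as.character(k)]] <- c(class_f[[as.character(k)]], f)
  }
  fb <- sapply(class_f, function(v) if (length(v)) mean(v) else NA_real_)
  if (is.na(fb[["3"]]) && !is.na(fb[["2"]]) && !is.na(fb[["4"]])) {
    fb[["3"]] <- (fb[["2"]] + fb[["4"]]) / 2
  }
  if (anyNA(fb)) return(NA_real_)
  enc <- 2 + 9 / fb[["2"]] + 1 / fb[["3"]] + 5 / fb[["4"]] + 3 / fb[["6"]]
  min(enc, 61)
}

# per-base synonymous third-position fractions from the definition
oracle_x3s <- function(counts) {
  syn_fams <- oracle_families[lengths(oracle_families) > 1L]
  out <- list()
  for (b in c("A", "T", "G", "C")) {
    num <- 0
    den <- 0
    for (cods in syn_fams) {
      if (!any(substr(cods, 3, 3) == b)) next
      den <- den + sum(unclass(counts)[cods])
      num <- num + sum(unclass(counts)[cods[substr(cods, 3, 3) == b]])
    }
    out[[b]] <- if (den == 0) NA_real_ else num / den
  }
  out
}

# closed-form OLS
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = b, intercept = mean(y) - b * mean(x))
}

# expected dinucleotide profile of iid codon draws with codon distribution q
# (named over sense codons, summing to 1), for sequences of L codons
oracle_expected_dinucs <- function(q, L) {
  stopifnot(abs(sum(q) - 1) < 1e-9)
  bases <- c("A", "C", "G", "T")
  pos_p <- sapply(1:3, function(k) {
    sapply(bases, function(b) sum(q[substr(names(q), k, k) == b]))
  })  # 4 x 3
  mono <- rowMeans(pos_p)
  pair <- function(i, j) {
    m <- matrix(0, 4, 4, dimnames = list(bases, bases))
    for (cd in names(q)) {
      m[substr(cd, i, i), substr(cd, j, j)] <-
        m[substr(cd, i, i), substr(cd, j, j)] + q[[cd]]
    }
    m
  }
  within <- pair(1, 2) + pair(2, 3)          # per codon
  boundary <- pos_p[, 3] %o% pos_p[, 1]      # across codon junctions
  e_counts <- L * within + (L - 1) * boundary
  f_xy <- e_counts / (3 * L - 1)
  rho <- f_xy / (mono %o% mono)
  list(mono = mono, f_xy = f_xy, rho = rho)
}

# codon marginal distribution implied by a generator spec
spec_codon_probs <- function(spec) {
  q <- c()
  for (a in names(spec$family_probs)) {
    p <- spec$family_probs[[a]] * spec$aa_freq[[a]]
    q[names(p)] <- p
  }
  q / sum(q)
}
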