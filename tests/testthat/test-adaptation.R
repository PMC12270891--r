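equal_ref <- function() {
  reference_usage(stats::setNames(rep(10, 61), sense_codons()),
                  source = "flat")
}

test_that("reference normalisation yields family-relative frequencies", {
  ref <- equal_ref()
  deg <- family_degeneracy()
  for (a in names(deg)) {
    cods <- codon_families()[[a]]
    expect_equal(unname(ref$cif[cods]), rep(1 / deg[[a]], deg[[a]]))
    expect_equal(unname(ref$w[cods]), rep(1, deg[[a]]))
  }
  # family-relative frequencies sum to 1 within every family
  expect_true(all(abs(unlist(lapply(codon_families(), function(cods)
    sum(ref$cif[cods]))) - 1) < 1e-12))
})

test_that("CAI weights derived from the honeybee host reference are per-family maxima", {
  ref <- host_reference("apis_mellifera")
  expect_equal(unname(ref$w[["TTA"]]), 1)            # Leu max 3.07
  expect_equal(unname(ref$w[["AGA"]]), 1)            # Arg max 3.08
  expect_equal(unname(ref$w[["CGG"]]), 0.24 / 3.08)
  expect_equal(unname(ref$w[["TTC"]]), 0.42 / 1.58)  # Phe
  expect_true(all(ref$w > 0 & ref$w <= 1))
  # every family exposes exactly one maximal codon with weight 1
  for (cods in codon_families()) {
    expect_equal(max(ref$w[cods]), 1)
  }
})

test_that("usage tables parse from Kazusa-style and CSV dialects", {
  counts <- stats::setNames(sample(50:500, 61), dna_to_rna(sense_codons()))
  kaz <- withr::local_tempfile(fileext = ".txt")
  fields <- sprintf("%s %4.1f(%6d)", names(counts),
                    1000 * counts / sum(counts), counts)
  writeLines(tapply(fields, (seq_along(fields) - 1) %/% 4, paste,
                    collapse = "  "), kaz)
  ref <- read_usage_table(kaz)
  expect_equal(unname(ref$cif["AAA"]),
               counts[["AAA"]] / (counts[["AAA"]] + counts[["AAG"]]))

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("codon,count", paste(names(counts), counts, sep = ",")), csv)
  ref2 <- read_usage_table(csv)
  expect_equal(ref2$cif, ref$cif)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(fields[1:60], "not a codon line ???"), bad)
  expect_error(read_usage_table(bad), "line 61")

  short <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("codon,count", paste(names(counts)[1:50], counts[1:50],
                                    sep = ",")), short)
  expect_error(read_usage_table(short), "missing")
})

test_that("zero-count reference codons receive the pseudocount", {
  vals <- stats::setNames(rep(10, 61), sense_codons())
  vals["AAA"] <- 0
  ref <- reference_usage(vals)
  expect_equal(unname(ref$cif[["AAA"]]), 0.5 / 10.5)
  expect_gt(ref$w[["AAA"]], 0)
})

test_that("CAI matches its closed forms", {
  ref <- equal_ref()
  set.seed(171)
  gene <- paste(sample(sense_codons(), 100, replace = TRUE), collapse = "")
  expect_equal(cai(count_codons(gene), ref), 1)  # all weights are 1

  # one 2-fold family with weights (1, 0.5), used once each -> sqrt(0.5)
  vals <- stats::setNames(rep(10, 61), sense_codons())
  vals["AAA"] <- 20
  vals["AAG"] <- 10
  ref2 <- reference_usage(vals)
  expect_equal(cai(count_codons("AAAAAG"), ref2), sqrt(0.5))
  # AUG/UGG contribute log-weight 0 but still count toward L
  expect_equal(cai(count_codons("ATGAAAAAGTGG"), ref2), 0.5^(1 / 4))
})

test_that("CAI is order/scale invariant and monotone in codon optimality", {
  ref <- host_reference("apis_cerana")
  set.seed(181)
  codons <- sample(sense_codons(), 60, replace = TRUE)
  a <- cai(count_codons(paste(codons, collapse = "")), ref)
  b <- cai(count_codons(paste(sample(codons), collapse = "")), ref)
  expect_equal(a, b)
  c3 <- cai(count_codons(paste(rep(codons, 3), collapse = "")), ref)
  expect_equal(a, c3)

  # replacing a codon by a higher-weight synonym never decreases CAI
  for (i in 1:20) {
    codons2 <- codons
    j <- sample(seq_along(codons2), 1)
    fam <- codon_families()[[genetic_code()$aa[genetic_code()$codon ==
                                                 codons2[j]]]]
    best <- fam[which.max(ref$w[fam])]
    if (ref$w[[best]] >= ref$w[[codons2[j]]]) {
      codons2[j] <- best
      expect_gte(cai(count_codons(paste(codons2, collapse = "")), ref) + 1e-12,
                 a)
    }
  }
})

test_that("RCDI matches hand arithmetic and its lower bound", {
  # one 2-fold family: host (0.75, 0.25), query (0.5, 0.5) -> 4/3
  vals <- stats::setNames(rep(10, 61), sense_codons())
  vals["AAA"] <- 30
  vals["AAG"] <- 10
  ref <- reference_usage(vals)
  expect_equal(rcdi(count_codons("AAAAAG"), ref), 4 / 3)

  # query identical to host family frequencies -> exactly 1
  gene <- paste(c(rep("AAA", 3), "AAG"), collapse = "")
  expect_equal(rcdi(count_codons(gene), ref), 1)
})

test_that("concentrating on the host's rarest codons maximises RCDI as computed by brute force", {
  ref <- host_reference("vespa_velutina")
  fams <- codon_families(synonymous_only = TRUE)
  rare <- vapply(fams, function(cods) cods[which.min(ref$cif[cods])], "")
  gene <- paste(rep(rare, 3), collapse = "")
  got <- rcdi(count_codons(gene), ref)
  want <- mean(1 / ref$cif[rare])  # equal counts: N_j/N = 1/|families|
  expect_equal(got, want)
  expect_gt(got, 1)
})

test_that("RCDI never drops below 1 on random query/host pairs", {
  set.seed(191)
  for (i in 1:200) {
    query <- random_counts(n_codons = sample(30:150, 1))
    host_vals <- stats::setNames(stats::runif(61, 0, 100), sense_codons())
    ref <- reference_usage(host_vals)
    expect_gte(rcdi(query, ref), 1 - 1e-9)
  }
})

test_that("host-matched sampling recovers the analytic CAI expectation", {
  ref <- host_reference("apis_mellifera")
  recs <- host_matched_set(ref, 10, 2000, seed = 201)
  got <- mean(sapply(recs, function(r) cai(count_codons(r), ref)))
  spec <- generator_spec(1, 1, seed = 1, host = ref)
  q <- spec_codon_probs(spec)
  analytic <- exp(sum(q * log(ref$w[names(q)])))
  expect_equal(got, analytic, tolerance = 0.01)
})
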