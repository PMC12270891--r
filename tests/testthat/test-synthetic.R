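test_that("generation is bit-reproducible under a fixed seed", {
  spec <- generator_spec(4, 120, seed = 301, gc3_theta = 0.3,
                         cg_depletion = 0.7)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  generate_cds_set(spec, fasta = f1)
  generate_cds_set(spec, fasta = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(paste0(f1, ".cfg")))

  other <- generate_cds_set(generator_spec(4, 120, seed = 302,
                                           gc3_theta = 0.3))
  expect_false(identical(readLines(f1)[2], other[[1]]$sequence))
})

test_that("invalid generator inputs are rejected", {
  expect_error(generator_spec(2, 50, family_probs = list(K = c(AAA = 0.5))),
               "family 'K'")
  expect_error(generator_spec(2, 50,
                              family_probs = list(K = c(AAA = -1, AAG = 2))),
               "invalid")
  expect_error(generator_spec(2, 50, gc3_theta = 1.5))
  expect_error(generator_spec(2, 50, aa_freq = c(bogus = 1)), "aa_freq")
})

test_that("uniform family vectors give near-neutral RSCU and ENC near 61", {
  recs <- generate_cds_set(generator_spec(2, 10000, seed = 311))
  for (r in recs) {
    counts <- count_codons(r)
    tab <- compute_rscu(counts)
    expect_true(all(abs(tab$rscu - 1) < 0.3))
    expect_gt(enc_observed(counts)$enc, 59)
  }
})

test_that("single-codon family vectors give maximal bias", {
  fams <- codon_families()
  one <- lapply(fams, function(cods) {
    stats::setNames(c(1, rep(0, length(cods) - 1)), cods)
  })
  rec <- generate_cds_set(generator_spec(1, 3000, seed = 321,
                                         family_probs = one))[[1]]
  counts <- count_codons(rec)
  expect_equal(enc_observed(counts)$enc, 20)
  tab <- compute_rscu(counts)
  used <- tab$rscu[!is.na(tab$rscu) & tab$rscu > 0]
  deg <- family_degeneracy()
  expect_true(all(used %in% unname(deg)))  # RSCU = degeneracy for chosen codons
})

test_that("the Wright-null dial controls GC3s as designed", {
  rec0 <- wright_null_set(0, 1, 2000, seed = 331)[[1]]
  expect_equal(positional_gc(count_codons(rec0))$gc3s, 0)
  rec5 <- wright_null_set(0.5, 1, 5000, seed = 332)[[1]]
  expect_equal(positional_gc(count_codons(rec5))$gc3s, 0.5, tolerance = 0.03)
})

test_that("Wright-null sweeps track the expected-ENC curve", {
  for (theta in c(0.2, 0.5, 0.8)) {
    recs <- wright_null_set(theta, 5, 1500, seed = 341 + 10 * theta)
    dev <- sapply(recs, function(r) {
      counts <- count_codons(r)
      enc_observed(counts)$enc - enc_expected(positional_gc(counts)$gc3s)
    })
    expect_lt(mean(abs(dev)), 2.5)
  }
})

test_that("host-matched sets are better adapted than deoptimized ones", {
  ref <- host_reference("apis_mellifera")
  matched <- host_matched_set(ref, 5, 1200, seed = 351)
  inverted <- lapply(codon_families(), function(cods) {
    p <- 1 / ref$cif[cods]
    p / sum(p)
  })
  deopt <- generate_cds_set(generator_spec(5, 1200, seed = 352,
                                           family_probs = inverted))
  r_matched <- mean(sapply(matched, function(r) rcdi(count_codons(r), ref)))
  r_deopt <- mean(sapply(deopt, function(r) rcdi(count_codons(r), ref)))
  expect_gt(r_deopt, r_matched)
  expect_equal(r_matched, 1, tolerance = 0.05)
  c_matched <- mean(sapply(matched, function(r) cai(count_codons(r), ref)))
  c_deopt <- mean(sapply(deopt, function(r) cai(count_codons(r), ref)))
  expect_gt(c_matched, c_deopt)
})

test_that("virus-like presets have the study-shaped sizes and dials", {
  presets <- virus_presets(seed = 3)
  expect_named(presets, c("ABPV", "CBPV", "KBV", "SBV"))
  expect_equal(vapply(presets, `[[`, 0L, "n_seq"), c(ABPV = 43L, CBPV = 57L,
                                                     KBV = 8L, SBV = 96L))
  expect_equal(unname(vapply(presets, `[[`, 0, "gc3_theta")),
               c(0.23, 0.54, 0.31, 0.31))
  small <- virus_presets(seed = 3, n_seq = 2, length = 100)
  recs <- generate_cds_set(small$CBPV)
  expect_length(recs, 2)
  expect_equal(nchar(recs[[1]]$sequence), 300)
})
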