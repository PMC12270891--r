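test_that("PR2 coordinates match hand tallies", {
  p <- pr2_point(count_codons("GGGCCCAAATTT"))
  expect_equal(p$x, 0.5)
  expect_equal(p$y, 0.5)

  # A3 = 3, U3 = 1, G3 = 1, C3 = 3 -> (0.25, 0.75)
  seq <- paste(c("AAA", "CCA", "GGA", "TTT", "GGG", "CCC", "GCC", "TCC"),
               collapse = "")
  p <- pr2_point(count_codons(seq))
  expect_equal(p$x, 0.25)
  expect_equal(p$y, 0.75)

  # all third bases A: y = 1, x undefined
  p <- pr2_point(count_codons("AAAGGATTACCA"))
  expect_equal(p$y, 1)
  expect_true(is.na(p$x))
})

test_that("fourfold-only PR2 ignores two-fold families", {
  # Lys (2-fold, A-ending) plus balanced Gly (4-fold)
  counts <- count_codons("AAAAAAGGAGGTGGCGGG")
  full <- pr2_point(counts)
  ff <- pr2_point(counts, fourfold_only = TRUE)
  expect_gt(full$y, ff$y)
  expect_equal(ff$y, 0.5)
  expect_equal(ff$x, 0.5)
})

test_that("neutrality regression recovers exact lines and degenerate cases", {
  x <- seq(0.2, 0.6, length.out = 10)
  # exact data makes summary.lm warn about a perfect fit; that is the point
  fit <- suppressWarnings(neutrality_fit(x, 0.3 + 0.5 * x))
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 0.3)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$mutation_pct + fit$selection_pct, 100)

  flatfit <- suppressWarnings(neutrality_fit(x, rep(0.4, 10)))
  expect_equal(flatfit$slope, 0)
  expect_equal(flatfit$r_squared, 0)

  expect_error(neutrality_fit(rep(0.3, 5), stats::runif(5)), "variance")
  expect_error(neutrality_fit(c(0.1, 0.2), c(0.1, 0.2)), "at least 3")
})

test_that("neutrality slope equals the closed-form OLS estimate", {
  set.seed(211)
  for (i in 1:20) {
    x <- stats::runif(50, 0.2, 0.6)
    y <- 0.2 + 0.69 * x + stats::rnorm(50, 0, 0.02)
    fit <- neutrality_fit(x, y)
    want <- oracle_ols(x, y)
    expect_equal(fit$slope, want$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, want$intercept, tolerance = 1e-10)
  }
})

test_that("correspondence analysis handles known-answer matrices", {
  ident <- matrix(rep(c(1, 2, 1, 2), 3), nrow = 3, byrow = TRUE)
  res <- coa_rscu(ident)
  expect_true(res$degenerate)
  expect_equal(res$total_inertia, 0, tolerance = 1e-12)

  diag2 <- matrix(c(2, 0, 0, 2), 2, 2)
  res <- coa_rscu(diag2)
  expect_equal(res$inertia_pct[1], 100)
  expect_equal(res$total_inertia, 1)

  set.seed(221)
  m <- matrix(stats::runif(5 * 8, 0.1, 2), 5, 8)
  res <- coa_rscu(m)
  expect_equal(sum(res$inertia_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(res$inertia_pct) <= 1e-12))
  expect_lte(length(res$inertia_pct), min(dim(m)) - 1)
})

test_that("inertia fractions are reproduced by an independent eigendecomposition", {
  set.seed(231)
  m <- matrix(stats::runif(6 * 10, 0.05, 3), 6, 10)
  res <- coa_rscu(m)
  # independent route: eigenvalues of S'S with S rebuilt from scratch
  P <- m / sum(m)
  S <- (P - rowSums(P) %o% colSums(P)) /
    sqrt(rowSums(P) %o% colSums(P))
  ev <- sort(eigen(t(S) %*% S, symmetric = TRUE)$values, decreasing = TRUE)
  ev <- ev[seq_along(res$inertia_pct)]
  expect_equal(res$inertia_pct, 100 * ev / sum(ev), tolerance = 1e-8)
})

test_that("correspondence analysis agrees with vegan's CA on inertia shares", {
  set.seed(241)
  m <- matrix(stats::rpois(8 * 12, 20) + 1, 8, 12)
  res <- coa_rscu(m)
  ca <- vegan::cca(m)
  ref_pct <- 100 * ca$CA$eig / sum(ca$CA$eig)
  expect_equal(res$inertia_pct[1:4], unname(ref_pct[1:4]), tolerance = 1e-6)
})

test_that("COA axis 1 separates planted AU-rich and GC-rich clusters", {
  au <- wright_null_set(0.15, 5, 400, seed = 251)
  gc <- wright_null_set(0.85, 5, 400, seed = 252)
  tabs <- lapply(c(au, gc), function(r) compute_rscu(count_codons(r)))
  m <- t(sapply(tabs, function(t) t$rscu))
  res <- coa_rscu(m)
  expect_gt(res$inertia_pct[1], res$inertia_pct[2])
  side <- sign(res$row_coords[, 1])
  expect_true(all(side[1:5] == side[1]) && all(side[6:10] == -side[1]))
})

test_that("GRAVY and AROMA match the residue-scale definitions", {
  expect_equal(gravy("III"), 4.5)
  expect_equal(gravy("A"), 1.8)
  expect_equal(aroma("FWY"), 1)
  expect_equal(aroma("FA"), 0.5)
  expect_error(gravy("***"), "no standard residues")
  # stops and unknowns are excluded, not counted
  expect_equal(gravy("II*X"), 4.5)
})

test_that("GRAVY is linear in residue composition", {
  set.seed(261)
  aas <- names(family_degeneracy())
  s1 <- paste(sample(aas, 40, replace = TRUE), collapse = "")
  s2 <- paste(sample(aas, 60, replace = TRUE), collapse = "")
  mix <- (40 * gravy(s1) + 60 * gravy(s2)) / 100
  expect_equal(gravy(paste0(s1, s2)), mix, tolerance = 1e-12)
})

test_that("correlation matrices flag exact and null relationships", {
  x <- stats::runif(30)
  d <- data.frame(a = x, b = 2 * x, c = -x + 5, flat = rep(1, 30))
  cm <- correlation_matrix(d, rows = c("b", "c", "flat"), cols = "a")
  expect_equal(cm$r["b", "a"], 1)
  expect_equal(cm$r["c", "a"], -1)
  expect_true(is.na(cm$r["flat", "a"]))  # zero variance
  expect_true(cm$significant["b", "a"])
  # p-values agree with cor.test
  set.seed(271)
  d2 <- data.frame(u = stats::rnorm(40), v = stats::rnorm(40))
  cm2 <- correlation_matrix(d2)
  ct <- stats::cor.test(d2$u, d2$v)
  expect_equal(cm2$p["u", "v"], ct$p.value)
  expect_equal(cm2$r["u", "v"], unname(ct$estimate))
})
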