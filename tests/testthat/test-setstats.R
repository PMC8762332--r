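test_that("overlap of identical and disjoint sets gives the closed-form p", {
  uni <- letters[1:10]
  same <- overlapFisher(letters[1:5], letters[1:5], uni)
  expect_equal(same@nOverlap, 5L)
  expect_equal(same@pEnrich, 1 / choose(10, 5), tolerance = 1e-12)  # 1/252
  disj <- overlapFisher(letters[1:5], letters[6:10], uni)
  expect_equal(disj@nOverlap, 0L)
  expect_equal(disj@pEnrich, 1, tolerance = 1e-12)
  expect_error(overlapFisher(c("a", "zz"), letters[1:3], uni), "outside")
  expect_error(overlapFisher("a", "a", "a"), "at least 2")
})

test_that("Fisher p values agree with stats::fisher.test on random tables", {
  set.seed(71)
  for (i in 1:50) {
    N <- sample(5:80, 1)
    nA <- sample.int(N, 1)
    nB <- sample.int(N, 1)
    lo <- max(0, nA + nB - N)
    hi <- min(nA, nB)
    ov <- if (lo == hi) lo else sample(lo:hi, 1)
    got <- structTE:::fisherCounts(ov, nA, nB, N)
    tab <- matrix(c(ov, nA - ov, nB - ov, N - nA - nB + ov), 2)
    expect_equal(got$pTwoSided, fisher.test(tab)$p.value, tolerance = 1e-6)
    expect_equal(got$pEnrich,
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("odds ratio uses the Haldane correction only on zero cells", {
  ok <- overlapFisher(letters[1:4], letters[3:6], letters[1:12])
  # cells: 2, 2, 2, 6 -> OR = (2 * 6) / (2 * 2)
  expect_equal(ok@oddsRatio, 3)
  zero <- overlapFisher(letters[1:3], letters[4:6], letters[1:12])
  # cells 0,3,3,6 -> corrected (0.5 * 6.5) / (3.5 * 3.5)
  expect_equal(zero@oddsRatio, 0.5 * 6.5 / (3.5 * 3.5))
})

test_that("term enrichment reproduces hypergeometric closed forms", {
  uni <- sprintf("g%02d", 1:20)
  terms <- list(all = uni, tri = uni[1:3], other = uni[10:15])
  enr <- enrichTerms(uni[1:3], terms, uni)
  # whole-universe term can never be depleted or enriched
  expect_equal(enr$p[enr$term == "all"], 1, tolerance = 1e-12)
  # k genes all inside a size-k term: p = 1 / C(N, k) = 1/1140
  expect_equal(enr$p[enr$term == "tri"], 1 / choose(20, 3), tolerance = 1e-12)
  # zero-overlap terms report p = 1 unless dropped
  expect_equal(enr$p[enr$term == "other"], 1, tolerance = 1e-12)
  dropped <- enrichTerms(uni[1:3], terms, uni, dropZero = TRUE)
  expect_false("other" %in% dropped$term)
  expect_error(enrichTerms(c("g01", "nope"), terms, uni), "outside")
})

test_that("BH q values are monotone in p rank and bound p from above", {
  set.seed(3)
  uni <- sprintf("g%03d", 1:200)
  terms <- lapply(1:25, function(i) sample(uni, sample(10:60, 1)))
  names(terms) <- paste0("T", 1:25)
  enr <- enrichTerms(sample(uni, 40), terms, uni)
  expect_true(all(diff(enr$q) >= -1e-12))          # sorted by p
  expect_true(enr$q[1] >= enr$p[1])
  expect_equal(enr$q, p.adjust(enr$p, "BH"), tolerance = 1e-12)
})

test_that("rank selection takes floor(fraction * n) with the stated tie rule", {
  metric <- setNames(c(5, 4, 3, 2, 1, 0, -1, -2, -3, -4), paste0("g", 0:9))
  top <- rankSelect(metric, 0.3, "top")
  expect_identical(members(top), c("g0", "g1", "g2"))
  bottom <- rankSelect(metric, 0.3, "bottom")
  expect_identical(members(bottom), c("g9", "g8", "g7"))
  # all-equal metric: lexicographically first ids win
  ties <- setNames(rep(1, 10), paste0("g", 9:0))
  expect_identical(members(rankSelect(ties, 0.3, "top")), c("g0", "g1", "g2"))
  # matches a sort-then-slice oracle on random input
  set.seed(12)
  met <- setNames(rnorm(57), sprintf("m%02d", 1:57))
  got <- members(rankSelect(met, 0.30, "top"))
  orc <- names(sort(met, decreasing = TRUE))[seq_len(floor(0.30 * 57))]
  expect_setequal(got, orc)
  # missing values are excluded before the count
  met[1:7] <- NA
  expect_length(members(rankSelect(met, 0.30, "top")), floor(0.3 * 50))
  expect_error(rankSelect(met, 1.2), "fraction")
})

test_that("term-list overlap computes the Jaccard index over significant terms", {
  enrA <- data.frame(term = c("a", "b", "c"), q = c(0.01, 0.2, 0.04))
  enrB <- data.frame(term = c("a", "b", "c"), q = c(0.03, 0.01, 0.9))
  tlo <- termListOverlap(enrA, enrB, qCutoff = 0.05)
  # A significant: {a, c}; B significant: {a, b}; Jaccard = 1/3
  expect_equal(tlo$jaccard, 1 / 3)
  expect_identical(tlo$shared, "a")
  expect_equal(termListOverlap(enrA, enrA, 0.05)$jaccard, 1)
  enrC <- data.frame(term = c("a", "b", "c"), q = c(0.9, 0.01, 0.9))
  expect_equal(termListOverlap(enrA, enrC, 0.05)$jaccard, 0)
})

test_that("GMT files round-trip", {
  terms <- list(T1 = c("g1", "g2", "g3"), T2 = c("g2", "g9"))
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(terms, path, descriptions = c(T1 = "first", T2 = "second"))
  back <- readGmt(path)
  expect_identical(back$T1, terms$T1)
  expect_identical(back$T2, terms$T2)
  expect_identical(unname(attr(back, "description")["T1"]), "first")
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("onlyterm\tdesc", bad)
  expect_error(readGmt(bad), "malformed")
})
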