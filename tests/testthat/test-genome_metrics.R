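make_identical_pair <- function(n = 10, len = 60, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(ProkTax:::.AA20, len, TRUE), collapse = ""), "")
  list(a = Proteome("gA", stats::setNames(seqs, sprintf("a%02d", 1:n))),
       b = Proteome("gB", stats::setNames(seqs, sprintf("b%02d", 1:n))))
}

test_that("identical proteomes give AAI 100 and POCP 100", {
  p <- make_identical_pair()
  m <- computePairMetrics(p$a, p$b)
  expect_true(aaiDefined(m))
  expect_equal(aaiMean(m), 100)
  expect_equal(aaiNPairs(m), 10L)
  expect_equal(pocp(m), 100)
  expect_equal(unname(conservedCounts(m)), c(10L, 10L, 10L, 10L))
})

test_that("unrelated proteomes give empty RBH, undefined AAI, POCP 0", {
  set.seed(55)
  mk <- function(g, n) Proteome(g, stats::setNames(
    vapply(seq_len(n), function(i)
      paste(sample(ProkTax:::.AA20, 80, TRUE), collapse = ""), ""),
    sprintf("%s_p%02d", g, seq_len(n))))
  pa <- mk("gA", 8); pb <- mk("gB", 8)
  rbh <- reciprocalBestHits(pa, pb)
  expect_equal(nrow(rbh), 0L)
  m <- computePairMetrics(pa, pb)
  expect_false(aaiDefined(m))
  expect_true(is.na(aaiMean(m)))
  expect_equal(pocp(m), 0)
})

test_that("RBH recovers exactly the planted ortholog pairs", {
  sim <- simulateProteomePair(nA = 30, nB = 30, nOrth = 18,
                              targetIdentity = 75,
                              lengthRange = c(80L, 150L), seed = 13)
  rbh <- reciprocalBestHits(sim$a, sim$b)
  got <- sort(paste(rbh$id_a, rbh$id_b, sep = "|"))
  want <- sort(paste(sim$truth$id_a, sim$truth$id_b, sep = "|"))
  expect_identical(got, want)
  expect_identical(got, oracle_rbh_pairs(sim$a, sim$b))
})

test_that("AAI tracks the generator's realized ortholog identity", {
  sim <- simulateProteomePair(nA = 25, nB = 25, nOrth = 15,
                              targetIdentity = 80,
                              lengthRange = c(80L, 150L), seed = 17)
  m <- computeAAI(sim$a, sim$b)
  expect_lt(abs(aaiMean(m) - mean(sim$truth$realized_identity)), 2)
})

test_that("POCP matches its construction on a planted pair", {
  sim <- simulateProteomePair(nA = 30, nB = 30, nOrth = 18,
                              targetIdentity = 80,
                              lengthRange = c(80L, 150L), seed = 19)
  m <- computePOCP(sim$a, sim$b)
  cc <- conservedCounts(m)
  expect_equal(unname(cc["c1"]), 18L)
  expect_equal(unname(cc["c2"]), 18L)
  expect_equal(pocp(m), 100 * 36 / 60)
})

test_that("AAI and POCP are symmetric under swapping the genomes", {
  sim <- simulateProteomePair(nA = 15, nB = 12, nOrth = 8,
                              targetIdentity = 70,
                              lengthRange = c(60L, 110L), seed = 23)
  mab <- computePairMetrics(sim$a, sim$b)
  mba <- computePairMetrics(sim$b, sim$a)
  expect_equal(aaiMean(mab), aaiMean(mba))
  expect_equal(aaiNPairs(mab), aaiNPairs(mba))
  expect_equal(pocp(mab), pocp(mba))
  ca <- conservedCounts(mab); cb <- conservedCounts(mba)
  expect_equal(unname(ca["c1"]), unname(cb["c2"]))
  expect_equal(unname(ca["c2"]), unname(cb["c1"]))
})

test_that("POCP satisfies its arithmetic identity exactly", {
  sim <- simulateProteomePair(nA = 12, nB = 17, nOrth = 7,
                              targetIdentity = 60,
                              lengthRange = c(60L, 110L), seed = 29)
  m <- computePOCP(sim$a, sim$b)
  cc <- conservedCounts(m)
  expect_equal(pocp(m) * (cc[["t1"]] + cc[["t2"]]),
               100 * (cc[["c1"]] + cc[["c2"]]), tolerance = 1e-9)
})

test_that("POCP falls as ortholog identity drops below its 40% filter", {
  hi <- simulateProteomePair(nA = 20, nB = 20, nOrth = 12,
                             targetIdentity = 90,
                             lengthRange = c(80L, 120L), seed = 31)
  lo <- simulateProteomePair(nA = 20, nB = 20, nOrth = 12,
                             targetIdentity = 30,
                             lengthRange = c(80L, 120L), seed = 31)
  expect_gte(pocp(computePOCP(hi$a, hi$b)), pocp(computePOCP(lo$a, lo$b)))
  cc <- conservedCounts(computePOCP(lo$a, lo$b))
  expect_lt(cc[["c1"]], 12L)
})

test_that("all-pairs matrices are symmetric, diagonal 100, and match
           independent pairwise calls", {
  s1 <- simulateProteomePair(nA = 10, nB = 10, nOrth = 7,
                             targetIdentity = 80,
                             lengthRange = c(60L, 100L), seed = 41,
                             idA = "g1", idB = "g2")
  s2 <- simulateProteomePair(nA = 10, nB = 10, nOrth = 0,
                             targetIdentity = 80,
                             lengthRange = c(60L, 100L), seed = 43,
                             idA = "zz", idB = "g3")
  ps <- list(s1$a, s1$b, s2$b)
  ms <- allPairsMetrics(ps)
  A <- aaiMatrix(ms); P <- pocpMatrix(ms)
  expect_equal(A, t(A)); expect_equal(P, t(P))
  expect_equal(unname(diag(A)), rep(100, 3))
  expect_equal(unname(diag(P)), rep(100, 3))
  m12 <- computePairMetrics(s1$a, s1$b)
  expect_equal(A["g1", "g2"], aaiMean(m12))
  expect_equal(P["g1", "g2"], pocp(m12))
  expect_equal(nrow(metricsTable(ms)), 3L)
})

test_that("all-pairs metrics reject degenerate input", {
  sim <- simulateProteomePair(nA = 5, nB = 5, nOrth = 3,
                              targetIdentity = 80,
                              lengthRange = c(50L, 80L), seed = 47)
  expect_error(allPairsMetrics(list(sim$a)), "at least 2")
  expect_error(allPairsMetrics(list(sim$a, sim$a)), "duplicate genome id")
})
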