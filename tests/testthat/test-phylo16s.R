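test_that("pairwise 16S identity handles matches, mismatches and gaps", {
  expect_equal(pairwiseIdentity16S("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(pairwiseIdentity16S("ACGT", "ACGA"), 75)
  # aligned input: gap columns excluded from the denominator
  expect_equal(pairwiseIdentity16S("AC-GT", "ACCGT", aligned = TRUE), 100)
  expect_equal(pairwiseIdentity16S("ACGGT", "AC-GA", aligned = TRUE), 75)
  expect_error(pairwiseIdentity16S("AC--", "--GT", aligned = TRUE),
               "undefined identity")
  expect_error(pairwiseIdentity16S("ACG", "ACGT", aligned = TRUE),
               "equal length")
})

test_that("distance models match their closed forms", {
  s <- strrep("A", 99)
  aln <- c(t1 = paste0(s, "A"), t2 = paste0(s, "G"), t3 = paste0(s, "A"))
  # one transition among 100 sites: p = 0.01
  p <- as.matrix(distanceMatrix16S(aln, "p"))
  expect_equal(p["t1", "t2"], 0.01)
  expect_equal(p["t1", "t3"], 0)
  jc <- as.matrix(distanceMatrix16S(aln, "JC69"))
  expect_equal(jc["t1", "t2"], -0.75 * log(1 - 4 * 0.01 / 3),
               tolerance = 1e-12)
  k2 <- as.matrix(distanceMatrix16S(aln, "K2P"))
  expect_equal(k2["t1", "t2"], -0.5 * log((1 - 2 * 0.01) * sqrt(1)),
               tolerance = 1e-12)
  expect_false(any(isSaturated(distanceMatrix16S(aln, "K2P"))))
})

test_that("identical sequences give an all-zero matrix under every model", {
  aln <- stats::setNames(rep(random_dna(50), 3), paste0("t", 1:3))
  for (model in c("p", "JC69", "K2P"))
    expect_true(all(as.matrix(distanceMatrix16S(aln, model)) == 0))
})

test_that("saturated pairs are flagged, not silently numeric", {
  aln <- c(a = strrep("ACGT", 5), b = strrep("CATG", 5),
           c = strrep("ACGT", 5))
  dm <- distanceMatrix16S(aln, "JC69")   # p = 0.75 between a and b
  expect_true(isSaturated(dm)["a", "b"])
  expect_true(is.na(as.matrix(dm)["a", "b"]))
  expect_error(neighborJoining(dm), "different model")
})

test_that("distances agree with an independent implementation", {
  tr <- ape::read.tree(
    text = "((a:0.04,b:0.06):0.08,(c:0.05,d:0.07):0.09,e:0.1);")
  aln <- evolveAlignment(tr, 1500, model = "K2P", kappa = 2, seed = 5)
  bin <- ape::as.DNAbin(aln)
  for (pair in list(c("K2P", "K80"), c("JC69", "JC69"))) {
    got <- as.matrix(distanceMatrix16S(aln, pair[1]))
    want <- ape::dist.dna(bin, model = pair[2], as.matrix = TRUE)
    expect_equal(got, want[rownames(got), colnames(got)],
                 tolerance = 1e-12)
  }
})

test_that("unequal aligned lengths are rejected", {
  expect_error(distanceMatrix16S(c(a = "ACGT", b = "ACG", c = "ACGT")),
               "equal length")
})

test_that("three-taxon NJ solves the star lengths in closed form", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(d)
  cp <- stats::cophenetic(tr)
  expect_equal(cp[rownames(d), colnames(d)], d, tolerance = 1e-9)
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("A", "B", "C")]), c(0, 2, 3))
})

test_that("the additive four-taxon matrix recovers split AB|CD exactly", {
  ids <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- neighborJoining(d)
  # the AB|CD bipartition is present
  bp <- ape::prop.part(tr)
  tips <- attr(bp, "labels")
  sets <- lapply(bp, function(i) sort(tips[i]))
  expect_true(any(vapply(sets, identical, logical(1), y = c("A", "B"))) ||
              any(vapply(sets, identical, logical(1), y = c("C", "D"))))
  expect_equal(stats::cophenetic(tr)[ids, ids], d, tolerance = 1e-9)
})

test_that("NJ reconstructs random additive matrices exactly", {
  set.seed(91)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    ram <- random_additive_matrix(n)
    tr <- neighborJoining(ram$d)
    expect_true(topo_equal(ram$tree, tr))
    expect_equal(stats::cophenetic(tr)[rownames(ram$d), colnames(ram$d)],
                 ram$d, tolerance = 1e-9)
  }
})

test_that("NJ agrees with an independent implementation and taxon order", {
  set.seed(93)
  ram <- random_additive_matrix(7)
  t_pkg <- neighborJoining(ram$d)
  t_ape <- ape::nj(ram$d)
  expect_true(topo_equal(t_pkg, t_ape))
  perm <- sample(rownames(ram$d))
  t_perm <- neighborJoining(ram$d[perm, perm])
  expect_true(topo_equal(t_pkg, t_perm))
})

test_that("bootstrap supports are seeded, reproducible and flagged", {
  aln <- two_clade_alignment(seed = 3)
  pp <- phyloParams(model = "JC69", nBootstrap = 100, seed = 42)
  t1 <- bootstrapSupports(aln, pp)
  t2 <- bootstrapSupports(aln, pp)
  expect_identical(t1$node.label, t2$node.label)
  sup <- attr(t1, "supports")
  disp <- attr(t1, "supportDisplay")
  expect_true(all(disp[!is.na(sup) & sup >= 50]))
  expect_false(any(disp[is.na(sup)]))
  # central edge between the two clades is saturated with signal
  clade2 <- paste0("t", 6:10)
  bp <- ape::prop.part(t1)
  tips <- attr(bp, "labels")
  idx <- which(vapply(bp, function(i)
    setequal(tips[i], clade2) || setequal(tips[i], paste0("t", 1:5)),
    logical(1)))
  expect_true(length(idx) >= 1)
  node_sup <- sup[idx[1]]
  expect_gte(node_sup, 99)
})

test_that("nBootstrap = 0 yields a support-free tree", {
  aln <- two_clade_alignment(seed = 5)
  tr <- bootstrapSupports(aln, phyloParams(model = "JC69", nBootstrap = 0))
  expect_true(is.null(tr$node.label) || all(!nzchar(tr$node.label)))
})

test_that("Newick round-trip preserves the bipartition set", {
  aln <- two_clade_alignment(seed = 7)
  tr <- bootstrapSupports(aln, phyloParams(model = "JC69",
                                           nBootstrap = 50, seed = 1))
  rt <- readNewickTree(text = writeNewickTree(tr))
  expect_true(topo_equal(tr, rt))
  expect_identical(rt$node.label, tr$node.label)
})
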