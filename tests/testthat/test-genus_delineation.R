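test_that("group summaries cover inter and intra pairs correctly", {
  m2 <- matrix(c(100, 70, 70, 100), 2, 2,
               dimnames = list(c("x1", "y1"), c("x1", "y1")))
  s <- summarizeGroups(m2, m2, c(x1 = "X", y1 = "Y"))
  expect_equal(nrow(s), 2L)           # AAI + POCP inter, no intra
  expect_setequal(s$metric, c("AAI", "POCP"))
  expect_equal(s$n_pairs, c(1L, 1L))

  ids <- paste0("g", 1:3)
  m3 <- matrix(80, 3, 3, dimnames = list(ids, ids)); diag(m3) <- 100
  m3[1, 2] <- m3[2, 1] <- 76; m3[1, 3] <- m3[3, 1] <- 82
  s3 <- summarizeGroups(m3, m3, stats::setNames(rep("G", 3), ids))
  expect_equal(unique(s3$n_pairs), 3L)    # diagonal excluded
  expect_equal(s3$mean[s3$metric == "AAI"], mean(c(76, 82, 80)))
  expect_equal(s3$min[1], 76); expect_equal(s3$max[1], 82)
})

test_that("summaries equal a flat enumeration on a random two-genus matrix", {
  set.seed(61)
  bm <- block_matrix(list(X = 3, Y = 3), intra = 80, inter = 55)
  pm <- block_matrix(list(X = 3, Y = 3), intra = 75, inter = 40)$m
  dimnames(pm) <- dimnames(bm$m)
  s <- summarizeGroups(bm$m, pm, bm$labels)
  ids <- rownames(bm$m)
  # brute force: enumerate unordered pairs
  for (metric in c("AAI", "POCP")) {
    m <- if (metric == "AAI") bm$m else pm
    vals_inter <- c(); vals_x <- c()
    for (i in 1:5) for (j in (i + 1):6) {
      v <- m[ids[i], ids[j]]
      gi <- bm$labels[ids[i]]; gj <- bm$labels[ids[j]]
      if (gi != gj) vals_inter <- c(vals_inter, v)
      else if (gi == "X") vals_x <- c(vals_x, v)
    }
    row_inter <- s[s$metric == metric & s$genus_x != s$genus_y, ]
    expect_equal(row_inter$mean, mean(vals_inter))
    expect_equal(row_inter$min, min(vals_inter))
    expect_equal(row_inter$n_pairs, length(vals_inter))
    row_x <- s[s$metric == metric & s$genus_x == "X" & s$genus_y == "X", ]
    expect_equal(row_x$mean, mean(vals_x))
  }
})

test_that("unlabeled genomes are reported by name", {
  m <- matrix(c(100, 70, 70, 100), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(summarizeGroups(m, m, c(a = "X")), "b")
})

test_that("pair classification reproduces the published genus decisions", {
  expect_equal(classifyPair(72.0, 62.2), "congeneric")
  expect_equal(classifyPair(75.4, 64.8), "congeneric")
  expect_equal(classifyPair(60.2, 38.1), "distinct")
  expect_equal(classifyPair(65.0, 50.0), "congeneric")  # inclusive bound
  expect_equal(classifyPair(70.0, 45.0), "ambiguous")
  expect_equal(classifyPair(60.0, 55.0), "ambiguous")
})

test_that("merge proposal joins genera whose mean metrics clear thresholds", {
  set.seed(71)
  genera <- list(Ancylomarina = 2, Labilibaculum = 2, Marinifilum = 2)
  am <- block_matrix(genera, intra = 80, inter = 72, sd = 0.5)
  pm <- block_matrix(genera, intra = 75, inter = 62, sd = 0.5)$m
  dimnames(pm) <- dimnames(am$m)
  rep <- proposeMerges(am$m, pm, am$labels,
                       namePriority = "Marinifilum")
  expect_length(mergeComponents(rep), 1L)
  expect_setequal(mergeComponents(rep)[[1]],
                  c("Ancylomarina", "Labilibaculum", "Marinifilum"))
  expect_equal(targetNames(rep), "Marinifilum")
})

test_that("merging is single-linkage over congeneric edges only", {
  ids <- c("a1", "b1", "c1")
  lab <- c(a1 = "A", b1 = "B", c1 = "C")
  am <- matrix(55, 3, 3, dimnames = list(ids, ids)); diag(am) <- 100
  pm <- matrix(35, 3, 3, dimnames = list(ids, ids)); diag(pm) <- 100
  am["a1", "b1"] <- am["b1", "a1"] <- 72
  pm["a1", "b1"] <- pm["b1", "a1"] <- 62
  rep <- proposeMerges(am, pm, lab)
  expect_length(mergeComponents(rep), 1L)
  expect_setequal(mergeComponents(rep)[[1]], c("A", "B"))
  expect_equal(targetNames(rep), "A")   # lexicographic default
  ev <- mergeEvidence(rep)
  expect_equal(ev$decision[ev$genus_x == "A" & ev$genus_y == "B"],
               "congeneric")
  expect_equal(sort(ev$decision), c("congeneric", "distinct", "distinct"))
})

test_that("ambiguous genus pairs never create merge edges", {
  ids <- c("a1", "b1")
  am <- matrix(c(100, 72, 72, 100), 2, 2, dimnames = list(ids, ids))
  pm <- matrix(c(100, 45, 45, 100), 2, 2, dimnames = list(ids, ids))
  rep <- proposeMerges(am, pm, c(a1 = "A", b1 = "B"))
  expect_length(mergeComponents(rep), 0L)
  expect_equal(mergeEvidence(rep)$decision, "ambiguous")
})

test_that("no merges are proposed below both thresholds or within one genus", {
  set.seed(73)
  bm <- block_matrix(list(A = 2, B = 2), intra = 80, inter = 55)
  pm <- block_matrix(list(A = 2, B = 2), intra = 70, inter = 35)$m
  dimnames(pm) <- dimnames(bm$m)
  expect_length(mergeComponents(proposeMerges(bm$m, pm, bm$labels)), 0L)
  one <- block_matrix(list(A = 3), intra = 80, inter = 80)
  expect_length(mergeComponents(proposeMerges(one$m, one$m, one$labels)), 0L)
})

test_that("merge proposal is invariant to genome input order", {
  set.seed(79)
  bm <- block_matrix(list(A = 2, B = 2, C = 2), intra = 80, inter = 70)
  pm <- block_matrix(list(A = 2, B = 2, C = 2), intra = 75, inter = 61)$m
  dimnames(pm) <- dimnames(bm$m)
  r1 <- proposeMerges(bm$m, pm, bm$labels)
  perm <- sample(rownames(bm$m))
  r2 <- proposeMerges(bm$m[perm, perm], pm[perm, perm], bm$labels[perm])
  expect_identical(mergeComponents(r1), mergeComponents(r2))
})

test_that("block-structured matrices recover their true genus blocks", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    bm <- block_matrix(list(A = 2, B = 2, C = 2), intra = 80, inter = 55)
    pm <- block_matrix(list(A = 2, B = 2, C = 2), intra = 72, inter = 38)$m
    dimnames(pm) <- dimnames(bm$m)
    rep <- proposeMerges(bm$m, pm, bm$labels)
    if (length(mergeComponents(rep)) == 0L) hits <- hits + 1L
  }
  expect_equal(hits, 100L)
})

test_that("report files are written", {
  set.seed(83)
  bm <- block_matrix(list(A = 2, B = 2), intra = 80, inter = 72, sd = 0.5)
  pm <- block_matrix(list(A = 2, B = 2), intra = 75, inter = 62, sd = 0.5)$m
  dimnames(pm) <- dimnames(bm$m)
  rep <- proposeMerges(bm$m, pm, bm$labels)
  td <- tempfile(); dir.create(td)
  paths <- writeReclassificationReport(rep, td)
  expect_true(all(file.exists(paths)))
  expect_match(paste(readLines(file.path(td, "reclassification.txt")),
                     collapse = "\n"), "Proposed merge 1: A \\+ B")
})
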