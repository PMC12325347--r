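test_that("marker flags follow the marker-gene definition", {
  g <- genes_from_labels(c("GH", "GT", "OTHER"))
  expect_equal(flagMarkers(g), c(TRUE, FALSE, FALSE))
  expect_equal(flagMarkers(genes_from_labels(c("SUSD", "TBDT", "SULFATASE"))),
               rep(TRUE, 3))
  expect_equal(flagMarkers(genes_from_labels(rep("OTHER", 4))),
               rep(FALSE, 4))
})

test_that("chaining follows the ten-gene linkage rule", {
  # markers at ordinals 5, 9, 25: |5-9| = 4 <= 10 joins; |9-25| = 16 > 10
  # does not; the singleton at 25 is discarded
  g <- genes_with_markers(40, c(5, 9, 25))
  cl <- chainClusters(g)
  expect_length(cl, 1L)
  expect_equal(S4Vectors::mcols(cl)$member_ordinals[[1]], c(5L, 9L))
})

test_that("no markers means no clusters", {
  expect_length(chainClusters(genes_from_labels(rep("OTHER", 30))), 0L)
})

test_that("clusters never span contigs and require a degradative CAZyme", {
  g2 <- geneTable(data.frame(
    genome_id = "g1",
    contig_id = rep(c("c1", "c2"), each = 8),
    ordinal = rep(0:7, 2),
    start = rep(1:8 * 100 - 99, 2), end = rep(1:8 * 100 - 10, 2),
    strand = "+",
    label = c(rep("OTHER", 6), "GH", "GH", "GH", "GH", rep("OTHER", 6)),
    stringsAsFactors = FALSE))
  cl <- chainClusters(g2)
  # ordinals 6,7 on c1 and 0,1 on c2 are adjacent in file order but on
  # different contigs: two clusters, never one
  expect_length(cl, 2L)
  expect_equal(as.character(GenomicRanges::seqnames(cl)), c("c1", "c2"))

  no_caz <- genes_with_markers(20, c(3, 5), marker_labels = c("TBDT", "SUSD"))
  expect_length(chainClusters(no_caz), 0L)
  expect_length(chainClusters(no_caz, pulParams(requireCazyme = FALSE)), 1L)
})

test_that("cluster classes follow the susC/susD tandem convention", {
  pul <- genes_with_markers(15, c(7, 8, 10),
                            marker_labels = c("TBDT", "SUSD", "GH"))
  expect_equal(S4Vectors::mcols(detectGeneClusters(pul))$cluster_class,
               "PUL")
  pl <- genes_with_markers(15, c(3, 5), marker_labels = c("SUSD", "GH"))
  expect_equal(S4Vectors::mcols(detectGeneClusters(pl))$cluster_class,
               "PUL_LIKE")
  cgc <- genes_with_markers(15, c(2, 4), marker_labels = c("GH", "SULFATASE"))
  expect_equal(S4Vectors::mcols(detectGeneClusters(cgc))$cluster_class,
               "CGC")
})

test_that("planted clusters are recovered exactly over 50 random tables", {
  classes <- c("PUL", "PUL_LIKE", "CGC")
  for (seed in 1:50) {
    k <- 1 + seed %% 3
    spec <- lapply(classes[seq_len(k)], plantedCluster)
    st <- simulateGeneTable(nGenes = 150, clusters = spec,
                            backgroundMarkers = 0, seed = seed)
    cl <- detectGeneClusters(st$genes)
    got <- vapply(as.list(S4Vectors::mcols(cl)$member_ordinals),
                  paste, character(1), collapse = ",")
    expect_setequal(got, st$truth$ordinals)
    expect_equal(sort(S4Vectors::mcols(cl)$cluster_class),
                 sort(st$truth$class))
    # every retained cluster honors the gap bound
    for (o in as.list(S4Vectors::mcols(cl)$member_ordinals))
      expect_true(all(diff(o) <= 10))
  }
})

test_that("chaining partitions retained markers and is gap-monotone", {
  st <- simulateGeneTable(nGenes = 200,
                          clusters = list(plantedCluster("PUL"),
                                          plantedCluster("CGC"),
                                          plantedCluster("PUL_LIKE")),
                          seed = 77)
  for (gap in c(3, 5, 10, 20, 50)) {
    cl <- chainClusters(st$genes, pulParams(maxGapGenes = gap))
    ords <- unlist(as.list(S4Vectors::mcols(cl)$member_ordinals))
    expect_false(anyDuplicated(ords) > 0)
  }
  # once every planted cluster's internal gaps fit the bound, raising the
  # bound can only merge clusters, never split them
  n_by_gap <- vapply(c(3, 5, 10, 25, 100), function(gap)
    length(chainClusters(st$genes, pulParams(maxGapGenes = gap))),
    integer(1))
  expect_true(all(diff(n_by_gap) <= 0))
})

test_that("genome summaries count annotations genome-wide", {
  empty <- summarizeGenome(genes_from_labels(character(0)),
                           detectGeneClusters(genes_from_labels(character(0))))
  expect_equal(nrow(empty), 0L)

  labels <- rep("OTHER", 60)
  labels[c(1, 3)] <- "GT"              # CAZymes but never markers
  labels[10:13] <- c("TBDT", "SUSD", "GH", "GH")
  labels[40:43] <- c("TBDT", "SUSD", "PL", "CE")
  labels[c(20, 25, 30)] <- "SULFATASE" # isolated singles + one pairable?
  labels[50:53] <- c("GH", "GH", "CBM", "AA")
  g <- genes_from_labels(labels)
  cl <- detectGeneClusters(g)
  s <- summarizeGenome(g, cl)
  expect_equal(s$n_cazymes,
               sum(labels %in% c("GH", "GT", "PL", "CE", "CBM", "AA")))
  expect_equal(s$n_sulfatases, 3L)
  expect_equal(s$n_puls + s$n_pul_like + s$n_cgcs, length(cl))
})

test_that("summaries are invariant to contig order permutation", {
  df <- rbind(
    as.data.frame(genes_with_markers(30, c(2, 4, 6),
                                     marker_labels = c("TBDT", "SUSD", "GH"),
                                     contig = "c1")),
    as.data.frame(genes_with_markers(30, c(10, 12),
                                     marker_labels = c("GH", "SULFATASE"),
                                     contig = "c2")))
  to_df <- function(d) data.frame(
    genome_id = "g1", contig_id = as.character(d$seqnames),
    ordinal = d$ordinal, start = d$start, end = d$end,
    strand = as.character(d$strand), label = d$label,
    stringsAsFactors = FALSE)
  g1 <- geneTable(to_df(df))
  g2 <- geneTable(to_df(df[rev(seq_len(nrow(df))), ]))
  s1 <- summarizeGenome(g1, detectGeneClusters(g1))
  s2 <- summarizeGenome(g2, detectGeneClusters(g2))
  expect_identical(s1, s2)
})

test_that("GT genes never seed or join clusters", {
  g <- genes_with_markers(20, c(5, 7), marker_labels = c("GH", "GT"))
  # GT is not a marker: only one marker remains -> below minMarkers
  expect_length(chainClusters(g), 0L)
})
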