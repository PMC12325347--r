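# Synthetic data with known ground truth for every pipeline stage:
# proteome pairs with a controlled ortholog fraction and per-ortholog
# identity, gene tables with planted marker clusters at controlled
# spacings, and nucleotide alignments evolved on known trees.
#
# Ortholog mutations are substitutions only (no indels), so the realized
# identity of each pair is exact by construction and serves as a clean
# oracle for the AAI/POCP filters. Background proteins are drawn i.i.d.
# from uniform residue frequencies; at the default lengths the chance of
# a spurious qualifying hit is negligible.

.randomProtein <- function(len) paste(sample(.AA20, len, TRUE), collapse = "")

.mutateProtein <- function(seq, targetIdentity) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  k <- round(L * (1 - targetIdentity / 100))
  if (k > 0) {
    pos <- sample.int(L, k)
    for (p in pos) {
      chars[p] <- sample(setdiff(.AA20, chars[p]), 1L)
    }
  }
  list(seq = paste(chars, collapse = ""),
       realized_identity = 100 * (L - k) / L)
}

#' Simulate a proteome pair with planted orthologs
#'
#' Generates two proteomes sharing `nOrth` ortholog pairs: each ortholog
#' in genome B is a point-mutated copy of its genome-A partner with
#' realized identity within half a percent of `targetIdentity` (exact by
#' construction, recorded per pair). Remaining proteins are unrelated
#' random sequences. The same seed reproduces the output exactly.
#'
#' @param nA,nB proteome sizes.
#' @param nOrth number of ortholog pairs (`<= min(nA, nB)`).
#' @param targetIdentity target percent identity of ortholog pairs.
#' @param lengthRange integer range of protein lengths (residues).
#' @param seed integer seed.
#' @param idA,idB genome ids.
#' @return list with elements `a`, `b` ([Proteome-class]) and `truth`, a
#'   `data.frame` of planted pairs (`id_a`, `id_b`, `realized_identity`).
#' @examples
#' sim <- simulateProteomePair(nA = 10, nB = 10, nOrth = 5,
#'                             targetIdentity = 80, seed = 1)
#' sim$truth
#' @export
simulateProteomePair <- function(nA = 100, nB = 100, nOrth = 60,
                                 targetIdentity = 80,
                                 lengthRange = c(100L, 400L), seed = 1L,
                                 idA = "genomeA", idB = "genomeB") {
  if (nOrth > min(nA, nB))
    stop("nOrth cannot exceed the smaller proteome size")
  stopifnot(targetIdentity > 0, targetIdentity <= 100)
  .withSeed(seed, {
    lensA <- sample(seq(lengthRange[1], lengthRange[2]), nA, TRUE)
    seqsA <- vapply(lensA, .randomProtein, character(1))
    idsA <- sprintf("%s_p%04d", idA, seq_len(nA))
    seqsB <- character(nB)
    idsB <- sprintf("%s_p%04d", idB, seq_len(nB))
    realized <- numeric(nOrth)
    for (i in seq_len(nOrth)) {
      m <- .mutateProtein(seqsA[i], targetIdentity)
      seqsB[i] <- m$seq
      realized[i] <- m$realized_identity
    }
    if (nB > nOrth) {
      lensB <- sample(seq(lengthRange[1], lengthRange[2]), nB - nOrth, TRUE)
      seqsB[(nOrth + 1):nB] <- vapply(lensB, .randomProtein, character(1))
    }
    list(
      a = Proteome(idA, stats::setNames(seqsA, idsA)),
      b = Proteome(idB, stats::setNames(seqsB, idsB)),
      truth = data.frame(id_a = idsA[seq_len(nOrth)],
                         id_b = idsB[seq_len(nOrth)],
                         realized_identity = realized,
                         stringsAsFactors = FALSE))
  })
}

#' Canonical planted-cluster templates
#'
#' Marker label sequences and ordinal gaps that realize each cluster
#' class: a PUL (susC/susD tandem plus a degradative CAZyme), a PUL-like
#' cluster (susD without the tandem) and a CGC (CAZyme plus sulfatase).
#'
#' @param class one of `"PUL"`, `"PUL_LIKE"`, `"CGC"`.
#' @return list with `class`, `labels` and `gaps` (ordinal increments
#'   between consecutive markers).
#' @export
plantedCluster <- function(class = c("PUL", "PUL_LIKE", "CGC")) {
  class <- match.arg(class)
  switch(class,
    PUL = list(class = "PUL", labels = c("TBDT", "SUSD", "GH", "GH"),
               gaps = c(1L, 2L, 3L)),
    PUL_LIKE = list(class = "PUL_LIKE", labels = c("SUSD", "GH", "CE"),
                    gaps = c(2L, 1L)),
    CGC = list(class = "CGC", labels = c("GH", "SULFATASE", "PL"),
               gaps = c(2L, 2L)))
}

#' Simulate a gene table with planted clusters
#'
#' Plants the requested marker clusters along a single contig, separated
#' from each other (and from any background markers) by more than
#' `maxGap` non-marker genes, so the planted member sets are exactly the
#' clusters a correct detector must recover. Background markers, if
#' requested, are isolated singletons.
#'
#' @param nGenes total genes on the contig.
#' @param clusters list of planted-cluster specs ([plantedCluster()] or
#'   lists with `class`, `labels`, `gaps`).
#' @param backgroundMarkers number of isolated background marker genes
#'   (placed `> maxGap` from every other marker).
#' @param maxGap separation guarantee, matching [pulParams()]
#'   `maxGapGenes`.
#' @param seed integer seed.
#' @param genomeID,contig identifiers for the emitted features.
#' @return list with `genes` (a gene-feature `GRanges`) and `truth`
#'   (`data.frame` of planted clusters: `class`,
#'   comma-separated `ordinals`).
#' @export
simulateGeneTable <- function(nGenes = 300, clusters = list(),
                              backgroundMarkers = 0, maxGap = 10,
                              seed = 1L, genomeID = "g1", contig = "ctg1") {
  sep <- maxGap + 1L
  need <- sum(vapply(clusters, function(cl) sum(cl$gaps) + 1L, numeric(1)))
  need <- need + (length(clusters) + backgroundMarkers) * sep +
    backgroundMarkers
  if (nGenes < need + sep)
    stop("nGenes too small to honor cluster separations")
  .withSeed(seed, {
    labels <- rep("OTHER", nGenes)
    truth <- list()
    cursor <- sample.int(sep, 1L)          # leading OTHER padding
    for (cl in clusters) {
      ords <- cursor + cumsum(c(0L, cl$gaps))
      if (max(ords) + 1L > nGenes)
        stop("nGenes too small to honor cluster separations")
      labels[ords + 1L] <- cl$labels
      truth[[length(truth) + 1L]] <- data.frame(
        class = cl$class, ordinals = paste(ords, collapse = ","),
        stringsAsFactors = FALSE)
      cursor <- max(ords) + sep + sample.int(3L, 1L)
    }
    for (b in seq_len(backgroundMarkers)) {
      if (cursor + 1L > nGenes)
        stop("nGenes too small to honor cluster separations")
      labels[cursor + 1L] <- sample(.MARKER_LABELS, 1L)
      cursor <- cursor + sep + sample.int(3L, 1L)
    }
    starts <- seq_len(nGenes) * 1000L - 999L
    genes <- geneTable(data.frame(
      genome_id = genomeID, contig_id = contig,
      ordinal = seq_len(nGenes) - 1L,
      start = starts, end = starts + 899L,
      strand = rep(c("+", "-"), length.out = nGenes),
      label = labels, stringsAsFactors = FALSE))
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(class = character(), ordinals = character())
    list(genes = genes, truth = truth_df)
  })
}

.K80_PROBS <- function(d, kappa) {
  # branch length d in expected substitutions/site; kappa = ts/tv rate ratio
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.25 - 0.25 * exp(-4 * bt)       # each of the two transversions
  c(ts = p_ts, tv = p_tv, same = 1 - p_ts - 2 * p_tv)
}

.BASES <- c("A", "C", "G", "T")
.TV1 <- c(A = "C", C = "A", G = "C", T = "A")
.TV2 <- c(A = "T", C = "G", G = "T", T = "G")

.evolveSeq <- function(parent, d, kappa) {
  if (d < 0) stop("negative branch length")
  pr <- .K80_PROBS(d, kappa)
  n <- length(parent)
  u <- stats::runif(n)
  child <- parent
  ts_idx <- u < pr["ts"]
  tv1_idx <- !ts_idx & u < pr["ts"] + pr["tv"]
  tv2_idx <- !ts_idx & !tv1_idx & u < pr["ts"] + 2 * pr["tv"]
  child[ts_idx] <- .TRANSITIONS[parent[ts_idx]]
  child[tv1_idx] <- .TV1[parent[tv1_idx]]
  child[tv2_idx] <- .TV2[parent[tv2_idx]]
  child
}

#' Evolve an alignment on a known tree
#'
#' Simulates nucleotide sequences down a tree under JC69 (`kappa = 1`) or
#' K2P substitution: the root sequence is uniform over A/C/G/T and each
#' branch applies the model's exact transition probabilities for its
#' length (expected substitutions/site). No indels are introduced, so the
#' leaf sequences form an alignment of exactly `nCols` columns.
#'
#' @param tree an [ape::phylo] with non-negative branch lengths.
#' @param nCols alignment columns.
#' @param model `"JC69"` or `"K2P"`.
#' @param kappa transition/transversion rate ratio for K2P.
#' @param seed integer seed.
#' @return aligned `DNAStringSet` named by tip label.
#' @export
evolveAlignment <- function(tree, nCols, model = c("JC69", "K2P"),
                            kappa = 2, seed = 1L) {
  model <- match.arg(model)
  if (model == "JC69") kappa <- 1
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  .withSeed(seed, {
    nTip <- length(tree$tip.label)
    root <- nTip + 1L
    seqs <- vector("list", nTip + tree$Nnode)
    seqs[[root]] <- sample(.BASES, nCols, TRUE)
    # parents precede children in cladewise edge order
    edge <- ape::reorder.phylo(tree, "cladewise")$edge
    lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edge))) {
      seqs[[edge[e, 2L]]] <- .evolveSeq(seqs[[edge[e, 1L]]], lens[e], kappa)
    }
    out <- Biostrings::DNAStringSet(vapply(seqs[seq_len(nTip)], paste,
                                           character(1), collapse = ""))
    names(out) <- tree$tip.label
    out
  })
}
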