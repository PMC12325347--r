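# 16S rRNA machinery: pairwise identity, distance matrices under
# p-distance / JC69 / K2P models, neighbor-joining (Saitou-Nei, with the
# standard Q-criterion, deterministic tie-breaks and zero-clamped branch
# lengths), and nonparametric bootstrap supports from column resampling.
#
# The multiple sequence alignment itself is an input (produced upstream by
# any standard aligner); only pairs are aligned here.

.GAP_OR_MISSING <- c("-", "N", ".", "?")
.TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Pairwise 16S identity
#'
#' Percent identity between two nucleotide sequences. Unaligned input is
#' globally aligned first ([needlemanWunschNucleotide()]); pre-aligned
#' input (equal length, may contain `-`) is used as-is. By default every
#' gap column (internal and terminal) is excluded from the denominator,
#' i.e. identity = matches over columns where both sequences carry a base;
#' `includeGaps = TRUE` switches to the variant that counts internal gap
#' columns in the denominator.
#'
#' @param a,b nucleotide sequences (character or `DNAString`).
#' @param aligned logical: treat inputs as already aligned.
#' @param includeGaps logical: include internal gap columns in the
#'   denominator.
#' @return percent identity in `[0, 100]`.
#' @examples
#' pairwiseIdentity16S("ACGT", "ACGA")  # 75
#' @export
pairwiseIdentity16S <- function(a, b, aligned = FALSE, includeGaps = FALSE) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!aligned) {
    al <- needlemanWunschNucleotide(a, b)
    a <- al$aligned_a; b <- al$aligned_b
  } else if (nchar(a) != nchar(b)) {
    stop("aligned sequences must have equal length")
  }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  both <- !(av %in% .GAP_OR_MISSING) & !(bv %in% .GAP_OR_MISSING)
  matches <- sum(av == bv & both)
  if (includeGaps) {
    either <- !(av %in% .GAP_OR_MISSING) | !(bv %in% .GAP_OR_MISSING)
    span <- range(which(both))
    denom <- sum(either[span[1]:span[2]])
  } else {
    denom <- sum(both)
  }
  if (!is.finite(denom) || denom == 0)
    stop("undefined identity: no overlapping bases after gap exclusion")
  100 * matches / denom
}

#' Distance matrix from an aligned nucleotide set
#'
#' Distances are computed over pairwise-complete columns (both sequences
#' carry an unambiguous base). Models: `"p"` (mismatch proportion),
#' `"JC69"` (`d = -(3/4) ln(1 - 4p/3)`), `"K2P"` (from transition and
#' transversion proportions `P`, `Q`:
#' `d = -(1/2) ln((1 - 2P - Q) sqrt(1 - 2Q))`). Pairs whose logarithm
#' argument is non-positive are mutationally saturated: their distance is
#' `NA` and flagged.
#'
#' @param alignment `DNAStringSet` (equal widths, gaps allowed) or named
#'   character vector; at least 3 taxa.
#' @param model `"K2P"` (default), `"JC69"` or `"p"`.
#' @return a [SeqDistanceMatrix-class].
#' @export
distanceMatrix16S <- function(alignment, model = c("K2P", "JC69", "p")) {
  model <- match.arg(model)
  if (is(alignment, "XStringSet")) {
    ids <- names(alignment)
    seqs <- as.character(alignment)
  } else {
    ids <- names(alignment)
    seqs <- toupper(as.character(alignment))
  }
  if (length(seqs) < 3L) stop("at least 3 taxa required")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must have equal length")
  if (is.null(ids) || anyDuplicated(ids))
    stop("taxa must carry unique names")
  M <- do.call(rbind, strsplit(toupper(seqs), ""))
  ok <- M %in% c("A", "C", "G", "T")
  dim(ok) <- dim(M)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    use <- ok[i, ] & ok[j, ]
    L <- sum(use)
    if (L == 0L) stop("no pairwise-complete columns for ", ids[i],
                      " vs ", ids[j])
    x <- M[i, use]; y <- M[j, use]
    diffs <- x != y
    p <- sum(diffs) / L
    val <- switch(model,
      p = p,
      JC69 = {
        arg <- 1 - 4 * p / 3
        if (arg <= 0) NA_real_ else -0.75 * log(arg)
      },
      K2P = {
        ts <- sum(diffs & .TRANSITIONS[x] == y) / L
        tv <- p - ts
        a1 <- 1 - 2 * ts - tv
        a2 <- 1 - 2 * tv
        if (a1 <= 0 || a2 <= 0) NA_real_
        else -0.5 * log(a1 * sqrt(a2))
      })
    d[i, j] <- d[j, i] <- val
    sat[i, j] <- sat[j, i] <- is.na(val)
  }
  new("SeqDistanceMatrix", ids = ids, d = d, saturated = sat, model = model)
}

# ---- neighbor joining core -------------------------------------------------
# Operates on a plain matrix; returns the tree as a nested node structure
# plus the leaf set ("clade") created by each agglomeration, which is what
# bootstrap bipartition counting needs. Tie-breaks on the Q criterion pick
# the smallest (i, j) pair in the current node ordering, so results are
# deterministic.

.njLeaf <- function(label) list(leaf = label, leaves = label)

.njJoin <- function(a, b, la, lb) {
  list(children = list(a, b), lengths = c(la, lb),
       leaves = c(a$leaves, b$leaves))
}

.njCore <- function(d, labels) {
  n <- nrow(d)
  stopifnot(n >= 3L)
  nodes <- lapply(labels, .njLeaf)
  D <- d
  clades <- list()
  while (length(nodes) > 3L) {
    r <- length(nodes)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    hit <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    # negative intermediate lengths: clamp to zero, deficit moves to the
    # sister edge so the path length through the new node is preserved
    if (li < 0) { li <- 0; lj <- D[i, j] }
    if (lj < 0) { lj <- 0; li <- D[i, j] }
    newNode <- .njJoin(nodes[[i]], nodes[[j]], li, lj)
    clades[[length(clades) + 1L]] <- newNode$leaves
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], list(newNode))
    D <- D2
  }
  # final three nodes joined at an unrooted trifurcation
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  lens <- pmax(c(la, lb, lc), 0)
  root <- list(children = nodes, lengths = lens,
               leaves = unlist(lapply(nodes, `[[`, "leaves")))
  list(root = root, clades = clades)
}

.cladeKey <- function(leaves, allLeaves) {
  if (allLeaves[1] %in% leaves) leaves <- setdiff(allLeaves, leaves)
  paste(sort(leaves), collapse = "\r")
}

.njNewick <- function(node, supports = NULL, allLeaves = NULL) {
  if (!is.null(node$leaf)) return(node$leaf)
  parts <- vapply(seq_along(node$children), function(i) {
    sprintf("%s:%.12g", .njNewick(node$children[[i]], supports, allLeaves),
            node$lengths[i])
  }, character(1))
  label <- ""
  if (!is.null(supports)) {
    key <- .cladeKey(node$leaves, allLeaves)
    if (!is.null(supports[[key]])) label <- as.character(supports[[key]])
  }
  sprintf("(%s)%s", paste(parts, collapse = ","), label)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Negative
#' intermediate branch lengths are clamped to zero with the deficit
#' transferred to the sister edge; Q ties are broken deterministically by
#' the smallest index pair. On an additive matrix the generating tree's
#' topology and path lengths are recovered exactly.
#'
#' @param dm a [SeqDistanceMatrix-class] or a symmetric numeric matrix
#'   with taxon dimnames (at least 3 taxa, finite entries).
#' @return an unrooted [ape::phylo] tree.
#' @export
neighborJoining <- function(dm) {
  if (is(dm, "SeqDistanceMatrix")) {
    if (any(dm@saturated))
      stop("distance matrix contains saturated pairs; ",
           "recompute with a different model (e.g. p-distance)")
    d <- dm@d
  } else d <- dm
  if (any(!is.finite(d)))
    stop("distance matrix contains non-finite entries")
  labels <- rownames(d)
  res <- .njCore(d, labels)
  readNewickTree(text = paste0(.njNewick(res$root), ";"))
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data tree, then resamples alignment columns with
#' replacement `nBootstrap` times (seeded); the support of each internal
#' edge is the percentage of replicate trees containing the same leaf
#' bipartition, rounded to the nearest integer and stored as the node
#' label. Supports below `minShowSupport` are retained but flagged hidden
#' for display in the `supportDisplay` attribute (and can be blanked on
#' export via [writeNewickTree()]).
#'
#' Replicates whose resampled distance matrix is saturated under the model
#' are counted as not containing any bipartition.
#'
#' @param alignment aligned `DNAStringSet` (or named character vector).
#' @param params a [phyloParams()] list.
#' @return an [ape::phylo] with `node.label` supports (absent when
#'   `nBootstrap = 0`) and attributes `supports` (numeric, named by node)
#'   and `supportDisplay` (logical).
#' @export
bootstrapSupports <- function(alignment, params = phyloParams()) {
  dm <- distanceMatrix16S(alignment, params$model)
  if (any(dm@saturated))
    stop("distance matrix contains saturated pairs; ",
         "recompute with a different model (e.g. p-distance)")
  main <- .njCore(dm@d, dm@ids)
  if (params$nBootstrap == 0L)
    return(readNewickTree(text = paste0(.njNewick(main$root), ";")))
  seqs <- if (is(alignment, "XStringSet")) as.character(alignment)
          else toupper(as.character(alignment))
  ids <- names(seqs)
  M <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(M) <- ids
  keys <- vapply(main$clades, .cladeKey, character(1), allLeaves = dm@ids)
  counts <- stats::setNames(numeric(length(keys)), keys)
  .withSeed(params$seed, {
    for (b in seq_len(params$nBootstrap)) {
      cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
      rep_aln <- apply(M[, cols, drop = FALSE], 1L, paste, collapse = "")
      rep_keys <- tryCatch({
        rdm <- distanceMatrix16S(rep_aln, params$model)
        if (any(rdm@saturated)) character() else
          vapply(.njCore(rdm@d, rdm@ids)$clades, .cladeKey,
                 character(1), allLeaves = dm@ids)
      }, error = function(e) character())
      hitk <- intersect(keys, rep_keys)
      counts[hitk] <- counts[hitk] + 1
    }
  })
  supports <- round(100 * counts / params$nBootstrap)
  tree <- readNewickTree(text = paste0(
    .njNewick(main$root, supports = as.list(supports), allLeaves = dm@ids),
    ";"))
  num <- suppressWarnings(as.numeric(tree$node.label))
  attr(tree, "supports") <- num
  attr(tree, "supportDisplay") <- !is.na(num) & num >= params$minShowSupport
  tree
}
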