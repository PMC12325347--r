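# Small fixture builders used across test files.

write_temp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  tf
}

# gene-feature GRanges from ordinal/label pairs on one contig
genes_from_labels <- function(labels, genome = "g1", contig = "c1") {
  n <- length(labels)
  starts <- seq_len(n) * 100L - 99L
  geneTable(data.frame(
    genome_id = rep(genome, n), contig_id = rep(contig, n),
    ordinal = seq_len(n) - 1L,
    start = starts, end = starts + 89L, strand = rep("+", n),
    label = labels, stringsAsFactors = FALSE))
}

# genes with markers at the given 0-based ordinals (label "GH" unless
# overridden), OTHER elsewhere
genes_with_markers <- function(n, marker_ordinals,
                               marker_labels = NULL, ...) {
  labels <- rep("OTHER", n)
  if (is.null(marker_labels)) marker_labels <- rep("GH",
                                                   length(marker_ordinals))
  labels[marker_ordinals + 1L] <- marker_labels
  genes_from_labels(labels, ...)
}

# symmetric block matrix: intra-block entries ~ N(intra, sd), inter-block
# ~ N(inter, sd), diagonal diag_val
block_matrix <- function(blocks, intra, inter, sd = 2, diag_val = 100) {
  ids <- unlist(lapply(names(blocks), function(b)
    paste0(b, "_g", seq_len(blocks[[b]]))))
  lab <- rep(names(blocks), unlist(blocks))
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      mu <- if (lab[i] == lab[j]) intra else inter
      m[i, j] <- m[j, i] <- min(100, max(0, stats::rnorm(1, mu, sd)))
    }
  }
  diag(m) <- diag_val
  list(m = m, labels = stats::setNames(lab, ids))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# alignment of two 5-taxon clades separated by n_diag fixed diagnostic
# columns plus per-taxon private noise columns
two_clade_alignment <- function(n_diag = 200, n_noise = 200, seed = 1) {
  set.seed(seed)
  taxa <- paste0("t", 1:10)
  clade1 <- taxa[1:5]
  base <- sample(c("A", "C", "G", "T"), n_noise, TRUE)
  seqs <- vapply(taxa, function(tx) {
    diag_block <- rep(if (tx %in% clade1) "A" else "G", n_diag)
    noise <- base
    flip <- sample.int(n_noise, max(1, round(n_noise * 0.03)))
    noise[flip] <- vapply(noise[flip], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(c(diag_block, noise), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

# random unrooted binary tree with given tip count and branch lengths
random_additive_matrix <- function(ntaxa, min_len = 0.1, max_len = 1) {
  tr <- ape::rtree(ntaxa, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  list(tree = tr, d = stats::cophenetic(tr))
}
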