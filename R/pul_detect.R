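# Detection of PULs, PUL-like clusters and CAZyme-rich gene clusters
# (CGCs) from annotated gene tables. Marker genes -- any degradative
# CAZyme (GH/PL/CE/CBM/AA, glycosyl transferases excluded), sulfatase,
# TonB-dependent transporter or susD-like gene -- are chained into one
# cluster by single linkage whenever two markers lie within ten gene
# ordinals of each other on the same contig. The seven-gene scan window of
# the sliding-window formulation is an implementation detail of scanning
# and cannot alter membership. Strand is ignored.

#' Flag marker genes for cluster chaining
#'
#' Markers are degradative CAZymes (GH, PL, CE, CBM, AA), sulfatases,
#' TBDTs and susD-like genes. Glycosyl transferases (GT) and unannotated
#' genes (OTHER) are never markers.
#'
#' @param genes gene-feature `GRanges` ([readGeneTable()]).
#' @return logical vector along `genes`.
#' @export
flagMarkers <- function(genes) {
  S4Vectors::mcols(genes)$label %in% .MARKER_LABELS
}

.clusterLabelCounts <- function(labels) {
  cnt <- table(factor(labels, levels = .GENE_LABELS))
  stats::setNames(as.integer(cnt), paste0("n_", names(cnt)))
}

#' Chain marker genes into candidate clusters
#'
#' Single-linkage chaining per (genome, contig): two markers join the same
#' cluster iff their ordinal distance is `<= maxGapGenes` (a distance of
#' 10 allows up to 9 intervening genes). Clusters with fewer than
#' `minMarkers` markers, or without a degradative CAZyme when
#' `requireCazyme`, are discarded. Clusters never span contigs.
#'
#' @param genes gene-feature `GRanges`, sorted as produced by
#'   [readGeneTable()].
#' @param params a [pulParams()] list.
#' @return `GRanges` of cluster spans with metadata columns `genome_id`,
#'   `member_ordinals` (`IntegerList`), `n_markers`, per-label counts
#'   (`n_GH`, ...), and `cluster_class` (`NA`; see [classifyClusters()]).
#' @export
chainClusters <- function(genes, params = pulParams()) {
  mc <- S4Vectors::mcols(genes)
  key <- paste(mc$genome_id, as.character(GenomicRanges::seqnames(genes)),
               sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sel <- which(key == k)
    sel <- sel[order(mc$ordinal[sel])]
    mk <- sel[flagMarkers(genes[sel])]
    if (!length(mk)) next
    ords <- mc$ordinal[mk]
    grp <- cumsum(c(1L, diff(ords) > params$maxGapGenes))
    for (g in unique(grp)) {
      members <- mk[grp == g]
      labs <- mc$label[members]
      if (length(members) < params$minMarkers) next
      if (params$requireCazyme && !any(labs %in% .DEGRADATIVE_CAZYMES))
        next
      counts <- .clusterLabelCounts(labs)
      out[[length(out) + 1L]] <- c(list(
        contig = as.character(GenomicRanges::seqnames(genes[members[1L]])),
        start = min(BiocGenerics::start(genes[members])),
        end = max(BiocGenerics::end(genes[members])),
        genome_id = mc$genome_id[members[1L]],
        member_ordinals = list(mc$ordinal[members]),
        n_markers = length(members)), as.list(counts))
    }
  }
  if (!length(out)) return(.emptyClusters())
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(out, `[[`, character(1), "contig"),
    ranges = IRanges::IRanges(
      start = vapply(out, `[[`, numeric(1), "start"),
      end = vapply(out, `[[`, numeric(1), "end")),
    strand = "*")
  df <- S4Vectors::DataFrame(
    genome_id = vapply(out, `[[`, character(1), "genome_id"),
    member_ordinals = IRanges::IntegerList(
      lapply(out, function(o) o$member_ordinals[[1L]])),
    n_markers = vapply(out, `[[`, integer(1), "n_markers"),
    cluster_class = NA_character_)
  for (nm in paste0("n_", .GENE_LABELS))
    df[[nm]] <- vapply(out, `[[`, integer(1), nm)
  S4Vectors::mcols(gr) <- df
  gr
}

.emptyClusters <- function() {
  gr <- GenomicRanges::GRanges()
  df <- S4Vectors::DataFrame(
    genome_id = character(), member_ordinals = IRanges::IntegerList(),
    n_markers = integer(), cluster_class = character())
  for (nm in paste0("n_", .GENE_LABELS)) df[[nm]] <- integer()
  S4Vectors::mcols(gr) <- df
  gr
}

#' Classify candidate clusters as PUL, PUL-like or CGC
#'
#' A cluster is a PUL when it carries a susC/susD tandem -- a TBDT and a
#' susD-like gene at adjacent ordinals -- plus at least one degradative
#' CAZyme; PUL-like when it carries a TBDT or susD-like gene without such
#' a tandem; CGC otherwise.
#'
#' @param clusters output of [chainClusters()].
#' @param genes the gene-feature `GRanges` the clusters came from.
#' @return `clusters` with `cluster_class` filled in.
#' @export
classifyClusters <- function(clusters, genes) {
  if (!length(clusters)) return(clusters)
  mc <- S4Vectors::mcols(genes)
  gkey <- paste(mc$genome_id, as.character(GenomicRanges::seqnames(genes)),
                mc$ordinal, sep = "\r")
  lab_by_key <- stats::setNames(mc$label, gkey)
  cl_mc <- S4Vectors::mcols(clusters)
  classes <- character(length(clusters))
  for (i in seq_along(clusters)) {
    ords <- cl_mc$member_ordinals[[i]]
    keys <- paste(cl_mc$genome_id[i],
                  as.character(GenomicRanges::seqnames(clusters[i])),
                  ords, sep = "\r")
    labs <- lab_by_key[keys]
    tbdt <- ords[labs == "TBDT"]
    susd <- ords[labs == "SUSD"]
    tandem <- length(tbdt) && length(susd) &&
      any(outer(tbdt, susd, function(a, b) abs(a - b) == 1L))
    has_caz <- any(labs %in% .DEGRADATIVE_CAZYMES)
    classes[i] <- if (tandem && has_caz) "PUL"
      else if (length(tbdt) || length(susd)) "PUL_LIKE"
      else "CGC"
  }
  S4Vectors::mcols(clusters)$cluster_class <- classes
  clusters
}

#' Detect and classify gene clusters in one call
#'
#' @inheritParams chainClusters
#' @return classified cluster `GRanges` ([chainClusters()] then
#'   [classifyClusters()]).
#' @export
detectGeneClusters <- function(genes, params = pulParams()) {
  classifyClusters(chainClusters(genes, params), genes)
}

#' Per-genome CAZyme / sulfatase / cluster summary
#'
#' `n_cazymes` counts every CAZyme-labeled gene genome-wide, including
#' glycosyl transferases (the annotation total), not only genes inside
#' clusters; `n_sulfatases` likewise. Cluster counts are split by class.
#'
#' @param genes gene-feature `GRanges` (may cover several genomes).
#' @param clusters classified clusters produced from `genes`.
#' @return `data.frame`, one row per genome: `genome_id`, `n_cazymes`,
#'   `n_sulfatases`, `n_puls`, `n_pul_like`, `n_cgcs`.
#' @export
summarizeGenome <- function(genes, clusters) {
  mc <- S4Vectors::mcols(genes)
  genomes <- unique(mc$genome_id)
  cl_mc <- S4Vectors::mcols(clusters)
  out <- lapply(genomes, function(g) {
    labs <- mc$label[mc$genome_id == g]
    cls <- cl_mc$cluster_class[cl_mc$genome_id == g]
    data.frame(
      genome_id = g,
      n_cazymes = sum(labs %in% .CAZYME_LABELS),
      n_sulfatases = sum(labs == "SULFATASE"),
      n_puls = sum(cls == "PUL"),
      n_pul_like = sum(cls == "PUL_LIKE"),
      n_cgcs = sum(cls == "CGC"),
      stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(genome_id = character(), n_cazymes = integer(),
                      n_sulfatases = integer(), n_puls = integer(),
                      n_pul_like = integer(), n_cgcs = integer()))
  do.call(rbind, out)
}

#' Write cluster and genome-summary tables
#'
#' One row per cluster (genome, contig, class, member ordinals, label
#' counts, nucleotide span) and one row per genome.
#'
#' @param clusters classified cluster `GRanges`.
#' @param genes the source gene-feature `GRanges`.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
writeClusterTables <- function(clusters, genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "clusters.tsv")
  p2 <- file.path(dir, "genome_summaries.tsv")
  mc <- S4Vectors::mcols(clusters)
  df <- data.frame(
    genome_id = mc$genome_id,
    contig_id = as.character(GenomicRanges::seqnames(clusters)),
    cluster_class = mc$cluster_class,
    member_ordinals = vapply(as.list(mc$member_ordinals), paste,
                             character(1), collapse = ","),
    span_start = BiocGenerics::start(clusters),
    span_end = BiocGenerics::end(clusters),
    stringsAsFactors = FALSE)
  for (nm in paste0("n_", .GENE_LABELS)) df[[nm]] <- mc[[nm]]
  utils::write.table(df, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summarizeGenome(genes, clusters), p2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
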