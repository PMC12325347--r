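# AAI and POCP for genome pairs and all-pairs matrices.
#
# AAI: mean percent identity over reciprocal best hits passing quality
# filters (identity >= 30%, coverage >= 70% of the shorter sequence,
# E < 1e-5 by default). POCP: 100*(C1+C2)/(T1+T2) where C counts proteins
# with any hit at E < 1e-5, identity > 40% and alignable region > 50% of
# the query length (strict inequalities, per the metric's definition),
# and T are the proteome sizes.

# both directional hit tables for a pair, computed once and reused
.pairHits <- function(pa, pb, params) {
  list(ab = .allPairsHits(pa, pb, params),
       ba = .allPairsHits(pb, pa, params))
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (x, y) is reciprocal iff y is x's best hit in `pb` and x is y's
#' best hit in `pa` (e-value cutoff applied in both directions); each
#' protein appears in at most one pair. The returned identity is the mean
#' of the two directional alignment identities, which makes every metric
#' built on it exactly symmetric in the two genomes.
#'
#' @param pa,pb [Proteome-class] objects.
#' @param params an [alignParams()] list.
#' @param maxEvalue best-hit e-value cutoff (strict `<`).
#' @param hits optional precomputed result of the internal pair search
#'   (used by [allPairsMetrics()] to avoid re-alignment).
#' @return `data.frame` with columns `id_a`, `id_b`, `identity_pct`,
#'   `cover_shorter_pct`, `evalue` (worse of the two directions),
#'   `len_a`, `len_b`.
#' @export
reciprocalBestHits <- function(pa, pb, params = alignParams(),
                               maxEvalue = 1e-5, hits = NULL) {
  if (is.null(hits)) hits <- .pairHits(pa, pb, params)
  best_ab <- .bestFromHits(hits$ab, maxEvalue)
  best_ba <- .bestFromHits(hits$ba, maxEvalue)
  if (!nrow(best_ab) || !nrow(best_ba)) return(.emptyRbh())
  back <- stats::setNames(best_ba$subject_id, best_ba$query_id)
  recip <- !is.na(back[best_ab$subject_id]) &
    back[best_ab$subject_id] == best_ab$query_id
  ab <- best_ab[recip, , drop = FALSE]
  if (!nrow(ab)) return(.emptyRbh())
  ba <- best_ba[match(ab$subject_id, best_ba$query_id), , drop = FALSE]
  shorter <- pmin(ab$query_len, ab$subject_len)
  # alignable span on the shorter sequence, from the direction where it is
  # the query in ab (query_len) or subject (subject_cover)
  cov_short <- ifelse(ab$query_len <= ab$subject_len,
                      ab$query_cover_pct, ab$subject_cover_pct)
  data.frame(
    id_a = ab$query_id, id_b = ab$subject_id,
    identity_pct = (ab$identity_pct + ba$identity_pct) / 2,
    cover_shorter_pct = cov_short,
    evalue = pmax(ab$evalue, ba$evalue),
    len_a = ab$query_len, len_b = ab$subject_len,
    stringsAsFactors = FALSE)
}

.emptyRbh <- function() {
  data.frame(id_a = character(), id_b = character(),
             identity_pct = numeric(), cover_shorter_pct = numeric(),
             evalue = numeric(), len_a = integer(), len_b = integer(),
             stringsAsFactors = FALSE)
}

.newPairMetrics <- function(pa, pb, aai = NA_real_, nPairs = 0L,
                            defined = FALSE, pocp = NA_real_,
                            c1 = NA_integer_, c2 = NA_integer_) {
  new("PairwiseGenomeMetrics",
      genomeA = pa@genomeID, genomeB = pb@genomeID,
      aaiMean = aai, aaiNPairs = as.integer(nPairs), aaiDefined = defined,
      pocp = pocp, c1 = as.integer(c1), c2 = as.integer(c2),
      t1 = length(pa@proteins), t2 = length(pb@proteins))
}

#' Average amino acid identity between two genomes
#'
#' Unweighted mean identity over reciprocal best-hit pairs passing the
#' [aaiParams()] filters. When no pair passes, AAI is explicitly undefined
#' (`aaiDefined()` is `FALSE`), never reported as 0.
#'
#' @param pa,pb [Proteome-class] objects.
#' @param params an [alignParams()] list.
#' @param aai an [aaiParams()] filter set.
#' @param hits optional precomputed internal hit tables.
#' @return a [PairwiseGenomeMetrics-class] with the AAI fields set.
#' @export
computeAAI <- function(pa, pb, params = alignParams(), aai = aaiParams(),
                       hits = NULL) {
  rbh <- reciprocalBestHits(pa, pb, params, maxEvalue = aai$maxEvalue,
                            hits = hits)
  keep <- rbh$identity_pct >= aai$minIdentity &
    rbh$cover_shorter_pct >= aai$minCover &
    rbh$evalue < aai$maxEvalue
  rbh <- rbh[keep, , drop = FALSE]
  if (!nrow(rbh)) return(.newPairMetrics(pa, pb))
  .newPairMetrics(pa, pb, aai = mean(rbh$identity_pct),
                  nPairs = nrow(rbh), defined = TRUE)
}

# proteins of the querying proteome with >= 1 qualifying conserved hit
.conservedCount <- function(hits) {
  q <- hits[hits$evalue < 1e-5 & hits$identity_pct > 40 &
              hits$query_cover_pct > 50, "query_id"]
  length(unique(q))
}

#' Percentage of conserved proteins between two genomes
#'
#' A protein is conserved when it has at least one hit in the other
#' proteome with e-value < 1e-5, identity > 40% and an alignable region
#' covering > 50% of its own (query) length.
#' `POCP = 100 * (C1 + C2) / (T1 + T2)`.
#'
#' @inheritParams computeAAI
#' @return a [PairwiseGenomeMetrics-class] with the POCP fields set.
#' @export
computePOCP <- function(pa, pb, params = alignParams(), hits = NULL) {
  if (is.null(hits)) hits <- .pairHits(pa, pb, params)
  c1 <- .conservedCount(hits$ab)
  c2 <- .conservedCount(hits$ba)
  t1 <- length(pa@proteins); t2 <- length(pb@proteins)
  .newPairMetrics(pa, pb, pocp = 100 * (c1 + c2) / (t1 + t2),
                  c1 = c1, c2 = c2)
}

#' Both metrics for one genome pair from a single search
#'
#' @inheritParams computeAAI
#' @return a [PairwiseGenomeMetrics-class] with AAI and POCP fields set.
#' @export
computePairMetrics <- function(pa, pb, params = alignParams(),
                               aai = aaiParams()) {
  hits <- .pairHits(pa, pb, params)
  ma <- computeAAI(pa, pb, params, aai, hits = hits)
  mp <- computePOCP(pa, pb, params, hits = hits)
  .newPairMetrics(pa, pb, aai = ma@aaiMean, nPairs = ma@aaiNPairs,
                  defined = ma@aaiDefined, pocp = mp@pocp,
                  c1 = mp@c1, c2 = mp@c2)
}

#' All-pairs AAI/POCP matrices
#'
#' Computes both metrics for every unordered genome pair. Matrices are
#' symmetric with diagonal 100; undefined AAI values are `NA` in the
#' matrix and flagged in the long-form table.
#'
#' @param proteomes list of [Proteome-class] objects with unique ids.
#' @param params an [alignParams()] list.
#' @param aai an [aaiParams()] filter set.
#' @return a [GenomeMetricsSet-class].
#' @export
allPairsMetrics <- function(proteomes, params = alignParams(),
                            aai = aaiParams()) {
  if (length(proteomes) < 2L)
    stop("allPairsMetrics requires at least 2 proteomes")
  ids <- vapply(proteomes, genomeID, character(1))
  if (anyDuplicated(ids))
    stop("duplicate genome id: ", ids[duplicated(ids)][1L])
  n <- length(proteomes)
  aaiM <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  pocpM <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(aaiM) <- 100; diag(pocpM) <- 100
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    m <- computePairMetrics(proteomes[[i]], proteomes[[j]], params, aai)
    aaiM[i, j] <- aaiM[j, i] <- if (m@aaiDefined) m@aaiMean else NA_real_
    pocpM[i, j] <- pocpM[j, i] <- m@pocp
    rows[[length(rows) + 1L]] <- data.frame(
      genome_a = ids[i], genome_b = ids[j],
      aai_mean_pct = if (m@aaiDefined) m@aaiMean else NA_real_,
      aai_n_pairs = m@aaiNPairs, pocp_pct = m@pocp,
      c1 = m@c1, c2 = m@c2, t1 = m@t1, t2 = m@t2,
      stringsAsFactors = FALSE)
  }
  new("GenomeMetricsSet", aai = aaiM, pocp = pocpM,
      table = do.call(rbind, rows))
}

#' Write a GenomeMetricsSet to TSV files
#'
#' Writes `aai_matrix.tsv`, `pocp_matrix.tsv` and `metrics_long.tsv`.
#'
#' @param x a [GenomeMetricsSet-class].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writeMetricsSet <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "aai_matrix.tsv"),
             file.path(dir, "pocp_matrix.tsv"),
             file.path(dir, "metrics_long.tsv"))
  writeMatrixTSV(x@aai, paths[1])
  writeMatrixTSV(x@pocp, paths[2])
  utils::write.table(x@table, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
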