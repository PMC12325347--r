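# Alignment engine behind AAI/POCP: local protein alignment with affine
# gaps (Biostrings dynamic programming), BLAST-style bit scores / e-values
# from fixed Karlin-Altschul constants, global nucleotide alignment, and
# one-way best-hit search between proteomes.
#
# Identity follows the BLAST convention: identical columns divided by
# alignment length, gap columns included in the denominator.

# residues with no column in the common matrices are scored as 'X'
.sanitizeAA <- function(s, matname) {
  mat <- .getSubMatrix(matname)
  known <- paste(rownames(mat), collapse = "")
  gsub(sprintf("[^%s]", gsub("\\*", "\\\\*", known)), "X",
       toupper(as.character(s)))
}

.subMatrixCache <- new.env(parent = emptyenv())

.getSubMatrix <- function(name) {
  if (is.matrix(name)) return(name)
  if (!exists(name, envir = .subMatrixCache)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = .subMatrixCache)
  }
  get(name, envir = .subMatrixCache)
}

.asAA <- function(x) {
  if (is(x, "AAString")) return(x)
  if (is(x, "AAStringSet")) {
    stopifnot(length(x) == 1L)
    return(x[[1L]])
  }
  Biostrings::AAString(as.character(x))
}

#' E-value from a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with the Karlin-Altschul constants in
#' `params`; `n` is the residue count of the searched subject set, so E
#' scales linearly with database size and decreases strictly with score.
#'
#' @param rawScore integer raw alignment score.
#' @param m query length in residues.
#' @param n total residues in the subject set.
#' @param params an [alignParams()] list.
#' @return the expected number of chance hits at this score or better.
#' @examples
#' evalueFromScore(0, 100, 1000)   # = K * m * n
#' @export
evalueFromScore <- function(rawScore, m, n, params = alignParams()) {
  stopifnot(m >= 1, n >= 1)
  params$k * m * n * exp(-params$lambda * rawScore)
}

#' Bit score from a raw score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @inheritParams evalueFromScore
#' @return bit score.
#' @export
bitScore <- function(rawScore, params = alignParams()) {
  (params$lambda * rawScore - log(params$k)) / log(2)
}

#' Optimal local protein alignment of two sequences
#'
#' Smith-Waterman alignment under affine gap scoring (a gap of length L
#' costs `gapOpen + L * gapExtend`). Residues without a substitution-matrix
#' column are scored through the matrix's `X` column. Returns `NULL` when
#' the optimal raw score is not positive (no local similarity).
#'
#' @param a,b amino-acid sequences (`AAString`, single `AAStringSet`
#'   element, or character), used as query and subject respectively.
#' @param params an [alignParams()] list.
#' @param n subject-set residue count for the e-value; defaults to the
#'   subject length (single-sequence search space).
#' @return one-row `data.frame` with columns `query_id`, `subject_id`,
#'   `raw_score`, `bit_score`, `evalue`, `identity_pct`, `aln_len`,
#'   `query_cover_pct`, `subject_cover_pct`, `query_len`, `subject_len`;
#'   or `NULL`.
#' @examples
#' smithWatermanProtein("MKTAYIAKQR", "MKTAYIAKQR")$identity_pct
#' @export
smithWatermanProtein <- function(a, b, params = alignParams(), n = NULL) {
  qa <- .sanitizeAA(a, params$substitutionMatrix)
  sb <- .sanitizeAA(b, params$substitutionMatrix)
  if (!nzchar(qa) || !nzchar(sb))
    stop("empty sequence passed to smithWatermanProtein")
  qid <- if (!is.null(names(a))) names(a)[1] else "query"
  sid <- if (!is.null(names(b))) names(b)[1] else "subject"
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(qa), subject = Biostrings::AAString(sb),
    type = "local",
    substitutionMatrix = .getSubMatrix(params$substitutionMatrix),
    gapOpening = params$gapOpen, gapExtension = params$gapExtend)
  s <- round(BiocGenerics::score(al))
  if (s <= 0) return(NULL)
  m <- nchar(qa)
  if (is.null(n)) n <- nchar(sb)
  qal <- BiocGenerics::end(Biostrings::pattern(al)) -
    BiocGenerics::start(Biostrings::pattern(al)) + 1L
  sal <- BiocGenerics::end(Biostrings::subject(al)) -
    BiocGenerics::start(Biostrings::subject(al)) + 1L
  data.frame(
    query_id = qid, subject_id = sid,
    raw_score = s,
    bit_score = bitScore(s, params),
    evalue = evalueFromScore(s, m, n, params),
    identity_pct = 100 * Biostrings::nmatch(al) / nchar(al),
    aln_len = nchar(al),
    query_cover_pct = 100 * qal / m,
    subject_cover_pct = 100 * sal / nchar(sb),
    query_len = m, subject_len = nchar(sb),
    stringsAsFactors = FALSE)
}

#' Optimal global nucleotide alignment
#'
#' Needleman-Wunsch alignment with match/mismatch scoring and a linear gap
#' penalty. Traceback is deterministic (single optimal alignment returned
#' by the dynamic program), so repeated calls are bit-identical.
#'
#' @param a,b nucleotide sequences (character or `DNAString`).
#' @param match,mismatch,gap scores (gap is the per-column gap score,
#'   negative).
#' @return list with elements `aligned_a`, `aligned_b` (gapped strings of
#'   equal length) and `score`.
#' @examples
#' needlemanWunschNucleotide("ACGT", "AGT")$aligned_b
#' @export
needlemanWunschNucleotide <- function(a, b, match = 1, mismatch = -1,
                                      gap = -2) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b))
    stop("empty sequence passed to needlemanWunschNucleotide")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = abs(gap))
  list(aligned_a = as.character(Biostrings::alignedPattern(al)),
       aligned_b = as.character(Biostrings::alignedSubject(al)),
       score = BiocGenerics::score(al))
}

# All positive-scoring hits of every query protein against every subject
# protein, one vectorized DP call per query. Columns as smithWatermanProtein.
.allPairsHits <- function(query, subject, params = alignParams()) {
  stopifnot(is(query, "Proteome"), is(subject, "Proteome"))
  qseq <- Biostrings::AAStringSet(
    .sanitizeAA(query@proteins, params$substitutionMatrix))
  names(qseq) <- names(query@proteins)
  sseq <- Biostrings::AAStringSet(
    .sanitizeAA(subject@proteins, params$substitutionMatrix))
  names(sseq) <- names(subject@proteins)
  n_db <- sum(Biostrings::width(sseq))
  mat <- .getSubMatrix(params$substitutionMatrix)
  out <- vector("list", length(qseq))
  slen <- Biostrings::width(sseq)
  for (i in seq_along(qseq)) {
    # pattern = subject set against the single query: scores, identities and
    # alignment lengths are orientation-free; per-side ranges are read from
    # the matching component below.
    al <- Biostrings::pairwiseAlignment(
      pattern = sseq, subject = qseq[[i]], type = "local",
      substitutionMatrix = mat,
      gapOpening = params$gapOpen, gapExtension = params$gapExtend)
    sc <- round(BiocGenerics::score(al))
    keep <- sc > 0
    if (!any(keep)) next
    qlen <- Biostrings::width(qseq)[i]
    q_aln <- BiocGenerics::end(Biostrings::subject(al)) -
      BiocGenerics::start(Biostrings::subject(al)) + 1L
    s_aln <- BiocGenerics::end(Biostrings::pattern(al)) -
      BiocGenerics::start(Biostrings::pattern(al)) + 1L
    out[[i]] <- data.frame(
      query_id = names(qseq)[i],
      subject_id = names(sseq)[keep],
      raw_score = sc[keep],
      bit_score = bitScore(sc[keep], params),
      evalue = evalueFromScore(sc[keep], qlen, n_db, params),
      identity_pct = 100 * Biostrings::nmatch(al)[keep] / nchar(al)[keep],
      aln_len = nchar(al)[keep],
      query_cover_pct = 100 * q_aln[keep] / qlen,
      subject_cover_pct = 100 * s_aln[keep] / slen[keep],
      query_len = qlen, subject_len = slen[keep],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- .emptyHits()
  res
}

.emptyHits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             raw_score = integer(), bit_score = numeric(),
             evalue = numeric(), identity_pct = numeric(),
             aln_len = integer(), query_cover_pct = numeric(),
             subject_cover_pct = numeric(), query_len = integer(),
             subject_len = integer(), stringsAsFactors = FALSE)
}

#' One-way best-hit search between two proteomes
#'
#' Aligns every query protein against every subject protein and keeps, for
#' each query with at least one hit below the e-value cutoff, the single
#' best hit: highest bit score, ties broken by lexicographically smaller
#' subject id. Queries without a qualifying hit are absent from the result.
#'
#' @param query,subject [Proteome-class] objects.
#' @param params an [alignParams()] list.
#' @param maxEvalue e-value cutoff (strict `<`, default 1e-5).
#' @return `data.frame` of best hits, one row per query with a hit.
#' @export
searchBestHits <- function(query, subject, params = alignParams(),
                           maxEvalue = 1e-5) {
  hits <- .allPairsHits(query, subject, params)
  .bestFromHits(hits, maxEvalue)
}

.bestFromHits <- function(hits, maxEvalue) {
  hits <- hits[hits$evalue < maxEvalue, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  o <- order(hits$query_id, -hits$bit_score, hits$subject_id)
  hits <- hits[o, , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}
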