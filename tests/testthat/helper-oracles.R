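# Independent oracles, written before and kept apart from the
# implementation paths they check.

.ORACLE_BLOSUM62 <- local({
  e <- new.env()
  utils::data(list = "BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Full O(mn) affine-gap Smith-Waterman score by three-matrix dynamic
# programming. A gap of length L costs open + L * ext.
oracle_sw_score <- function(a, b, open = 11, ext = 1,
                            mat = .ORACLE_BLOSUM62) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e9
  M <- matrix(0, m + 1, n + 1)
  Ix <- matrix(NEG, m + 1, n + 1)   # gap in b (vertical)
  Iy <- matrix(NEG, m + 1, n + 1)   # gap in a (horizontal)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0,
        M[i, j] + s, Ix[i, j] + s, Iy[i, j] + s)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              Iy[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Global Needleman-Wunsch score with a linear gap penalty.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  m <- length(av); n <- length(bv)
  F <- matrix(0, m + 1, n + 1)
  F[, 1] <- (0:m) * gap
  F[1, ] <- (0:n) * gap
  for (i in seq_len(m)) for (j in seq_len(n)) {
    s <- if (av[i] == bv[j]) match else mismatch
    F[i + 1, j + 1] <- max(F[i, j] + s, F[i, j + 1] + gap,
                           F[i + 1, j] + gap)
  }
  F[m + 1, n + 1]
}

# One pairwise hit computed directly through Biostrings plus literal
# formula application -- no package search/aggregation code involved.
oracle_pair_hit <- function(qid, qseq, sid, sseq, n_db,
                            open = 11, ext = 1, lambda = 0.267, K = 0.041) {
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(qseq),
    subject = Biostrings::AAString(sseq),
    type = "local", substitutionMatrix = .ORACLE_BLOSUM62,
    gapOpening = open, gapExtension = ext)
  s <- round(BiocGenerics::score(al))
  if (s <= 0) return(NULL)
  q_aln <- BiocGenerics::end(Biostrings::pattern(al)) -
    BiocGenerics::start(Biostrings::pattern(al)) + 1
  s_aln <- BiocGenerics::end(Biostrings::subject(al)) -
    BiocGenerics::start(Biostrings::subject(al)) + 1
  list(query_id = qid, subject_id = sid, raw_score = s,
       bit_score = (lambda * s - log(K)) / log(2),
       evalue = K * nchar(qseq) * n_db * exp(-lambda * s),
       identity_pct = 100 * Biostrings::nmatch(al) / nchar(al),
       query_cover_pct = 100 * q_aln / nchar(qseq),
       subject_cover_pct = 100 * s_aln / nchar(sseq),
       query_len = nchar(qseq), subject_len = nchar(sseq))
}

# Brute-force one-way best hits: all pairs, E < cutoff, argmax bit score,
# lexicographic subject tie-break.
oracle_best_hits <- function(pa, pb, maxEvalue = 1e-5) {
  qs <- as.character(proteins(pa)); ss <- as.character(proteins(pb))
  n_db <- sum(nchar(ss))
  out <- list()
  for (qid in names(qs)) {
    best <- NULL
    for (sid in sort(names(ss))) {
      h <- oracle_pair_hit(qid, qs[[qid]], sid, ss[[sid]], n_db)
      if (is.null(h) || h$evalue >= maxEvalue) next
      if (is.null(best) || h$bit_score > best$bit_score) best <- h
    }
    if (!is.null(best)) out[[qid]] <- best
  }
  out
}

# Brute-force reciprocal best hits as a set of "qid|sid" keys.
oracle_rbh_pairs <- function(pa, pb, maxEvalue = 1e-5) {
  ab <- oracle_best_hits(pa, pb, maxEvalue)
  ba <- oracle_best_hits(pb, pa, maxEvalue)
  keys <- character()
  for (qid in names(ab)) {
    sid <- ab[[qid]]$subject_id
    if (!is.null(ba[[sid]]) && ba[[sid]]$subject_id == qid)
      keys <- c(keys, paste(qid, sid, sep = "|"))
  }
  sort(keys)
}

# Literal POCP: any hit with E < 1e-5, identity > 40, query cover > 50.
oracle_pocp <- function(pa, pb) {
  count_dir <- function(px, py) {
    qs <- as.character(proteins(px)); ss <- as.character(proteins(py))
    n_db <- sum(nchar(ss))
    conserved <- 0L
    for (qid in names(qs)) {
      for (sid in names(ss)) {
        h <- oracle_pair_hit(qid, qs[[qid]], sid, ss[[sid]], n_db)
        if (!is.null(h) && h$evalue < 1e-5 && h$identity_pct > 40 &&
            h$query_cover_pct > 50) {
          conserved <- conserved + 1L
          break
        }
      }
    }
    conserved
  }
  c1 <- count_dir(pa, pb); c2 <- count_dir(pb, pa)
  t1 <- nProteins(pa); t2 <- nProteins(pb)
  list(c1 = c1, c2 = c2, pocp = 100 * (c1 + c2) / (t1 + t2))
}

# Literal AAI over oracle RBH pairs with inclusive filters; identity per
# pair is the mean of the two directional alignments, as documented.
oracle_aai <- function(pa, pb, minIdentity = 30, minCover = 70,
                       maxEvalue = 1e-5) {
  ab <- oracle_best_hits(pa, pb, maxEvalue)
  ba <- oracle_best_hits(pb, pa, maxEvalue)
  ids <- numeric()
  for (qid in names(ab)) {
    h <- ab[[qid]]
    sid <- h$subject_id
    if (is.null(ba[[sid]]) || ba[[sid]]$subject_id != qid) next
    idy <- (h$identity_pct + ba[[sid]]$identity_pct) / 2
    cov <- if (h$query_len <= h$subject_len) h$query_cover_pct
           else h$subject_cover_pct
    if (idy >= minIdentity && cov >= minCover &&
        max(h$evalue, ba[[sid]]$evalue) < maxEvalue)
      ids <- c(ids, idy)
  }
  if (!length(ids)) NULL else mean(ids)
}

topo_equal <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# Single-pass oracle for one genome pair: every pairwise hit computed once
# through oracle_pair_hit, then best hits, RBH, AAI and POCP derived by
# literal filter application on the flat table.
oracle_metrics <- function(pa, pb, maxEvalue = 1e-5) {
  dir_hits <- function(px, py) {
    qs <- as.character(proteins(px)); ss <- as.character(proteins(py))
    n_db <- sum(nchar(ss))
    hits <- list()
    for (qid in names(qs)) for (sid in names(ss)) {
      h <- oracle_pair_hit(qid, qs[[qid]], sid, ss[[sid]], n_db)
      if (!is.null(h)) hits[[length(hits) + 1L]] <- h
    }
    hits
  }
  best_of <- function(hits) {
    best <- list()
    for (h in hits) {
      if (h$evalue >= maxEvalue) next
      cur <- best[[h$query_id]]
      if (is.null(cur) || h$bit_score > cur$bit_score ||
          (h$bit_score == cur$bit_score && h$subject_id < cur$subject_id))
        best[[h$query_id]] <- h
    }
    best
  }
  ab <- dir_hits(pa, pb); ba <- dir_hits(pb, pa)
  best_ab <- best_of(ab); best_ba <- best_of(ba)
  rbh <- list()
  for (qid in names(best_ab)) {
    sid <- best_ab[[qid]]$subject_id
    if (!is.null(best_ba[[sid]]) && best_ba[[sid]]$subject_id == qid)
      rbh[[length(rbh) + 1L]] <- list(a = qid, b = sid,
                                      ha = best_ab[[qid]],
                                      hb = best_ba[[sid]])
  }
  aai_vals <- numeric()
  for (p in rbh) {
    idy <- (p$ha$identity_pct + p$hb$identity_pct) / 2
    cov <- if (p$ha$query_len <= p$ha$subject_len) p$ha$query_cover_pct
           else p$ha$subject_cover_pct
    if (idy >= 30 && cov >= 70 && max(p$ha$evalue, p$hb$evalue) < maxEvalue)
      aai_vals <- c(aai_vals, idy)
  }
  conserved <- function(hits) {
    q <- unique(vapply(Filter(function(h)
      h$evalue < 1e-5 && h$identity_pct > 40 && h$query_cover_pct > 50,
      hits), `[[`, character(1), "query_id"))
    length(q)
  }
  c1 <- conserved(ab); c2 <- conserved(ba)
  list(best_ab = best_ab, best_ba = best_ba,
       rbh_keys = sort(vapply(rbh, function(p)
         paste(p$a, p$b, sep = "|"), character(1))),
       aai = if (length(aai_vals)) mean(aai_vals) else NA_real_,
       c1 = c1, c2 = c2,
       pocp = 100 * (c1 + c2) / (nProteins(pa) + nProteins(pb)))
}
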