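utils::globalVariables(c("aai", "type"))

# Threshold-based genus delineation from pairwise AAI/POCP matrices:
# distribution summaries within and between genera, pair classification
# against the 65% AAI / 50% POCP genus thresholds, and merge proposals as
# connected components of the congeneric-genus graph (single linkage,
# mirroring the joint merge of two genera into a third).

.checkLabels <- function(m, labels) {
  ids <- rownames(m)
  miss <- setdiff(ids, names(labels))
  if (length(miss))
    stop("unlabeled genome(s): ", paste(miss, collapse = ", "))
  labels[ids]
}

.pairValues <- function(m, ids_x, ids_y, intra) {
  if (intra) {
    if (length(ids_x) < 2L) return(numeric())
    sub <- m[ids_x, ids_x, drop = FALSE]
    sub[upper.tri(sub)]
  } else {
    as.vector(m[ids_x, ids_y, drop = FALSE])
  }
}

#' Summarize AAI/POCP distributions within and between genera
#'
#' One summary row per metric per unordered genus pair with at least one
#' genome pair; intra-genus summaries exclude the matrix diagonal.
#'
#' @param aaiM,pocpM symmetric matrices with genome-id dimnames (e.g. from
#'   [allPairsMetrics()]), or a [GenomeMetricsSet-class] as first argument.
#' @param labels named character vector mapping genome id to genus.
#' @return `data.frame` with columns `genus_x`, `genus_y`, `metric`,
#'   `mean`, `min`, `max`, `n_pairs`.
#' @export
summarizeGroups <- function(aaiM, pocpM = NULL, labels) {
  if (is(aaiM, "GenomeMetricsSet")) {
    pocpM <- aaiM@pocp
    aaiM <- aaiM@aai
  }
  lab <- .checkLabels(aaiM, labels)
  .checkLabels(pocpM, labels)
  genera <- sort(unique(lab))
  by_genus <- split(rownames(aaiM), lab)
  rows <- list()
  mats <- list(AAI = aaiM, POCP = pocpM)
  for (gi in seq_along(genera)) for (gj in seq(gi, length(genera))) {
    gx <- genera[gi]; gy <- genera[gj]
    for (metric in names(mats)) {
      v <- .pairValues(mats[[metric]], by_genus[[gx]], by_genus[[gy]],
                       intra = gi == gj)
      v <- v[!is.na(v)]
      if (!length(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        genus_x = gx, genus_y = gy, metric = metric,
        mean = mean(v), min = min(v), max = max(v),
        n_pairs = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify a genome or genus pair against genus thresholds
#'
#' Congeneric iff AAI >= the AAI threshold AND POCP >= the POCP threshold
#' (inclusive boundaries); distinct iff both fall below; otherwise
#' ambiguous (the two metrics disagree).
#'
#' @param aai,pocpVal percent values in `[0, 100]` (vectorized).
#' @param thresholds a [genusThresholds()] list.
#' @return character vector: `"congeneric"`, `"distinct"` or `"ambiguous"`.
#' @examples
#' classifyPair(72.0, 62.2)  # congeneric
#' classifyPair(60.2, 38.1)  # distinct
#' @export
classifyPair <- function(aai, pocpVal, thresholds = genusThresholds()) {
  stopifnot(all(aai >= 0 & aai <= 100), all(pocpVal >= 0 & pocpVal <= 100))
  a <- aai >= thresholds$aaiGenus
  p <- pocpVal >= thresholds$pocpGenus
  ifelse(a & p, "congeneric", ifelse(!a & !p, "distinct", "ambiguous"))
}

# connected components of an undirected edge list over `nodes`
.components <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ci <- comp[edges[k, 1L]]; cj <- comp[edges[k, 2L]]
    if (ci != cj) comp[comp == cj] <- ci
  }
  split(names(comp), comp)
}

#' Propose genus merges from pairwise matrices
#'
#' Builds a graph on genera with an edge wherever the inter-genus mean AAI
#' and mean POCP jointly clear the genus thresholds
#' ([classifyPair()] returns `"congeneric"`); connected components of size
#' two or more are proposed as single genera. Ambiguous pairs (one metric
#' passing) never create edges but are retained in the evidence table.
#'
#' @inheritParams summarizeGroups
#' @param thresholds a [genusThresholds()] list.
#' @param namePriority ordered character vector of genus names with
#'   nomenclatural priority; the first member present in a component is its
#'   proposed name, else the lexicographically smallest member.
#' @return a [ReclassificationReport-class].
#' @export
proposeMerges <- function(aaiM, pocpM = NULL, labels,
                          thresholds = genusThresholds(),
                          namePriority = character()) {
  if (is(aaiM, "GenomeMetricsSet")) {
    pocpM <- aaiM@pocp
    aaiM <- aaiM@aai
  }
  summaries <- summarizeGroups(aaiM, pocpM, labels)
  genera <- sort(unique(.checkLabels(aaiM, labels)))
  inter <- summaries[summaries$genus_x != summaries$genus_y, , drop = FALSE]
  ev_rows <- list()
  edges <- matrix(character(), ncol = 2)
  if (nrow(inter)) {
    key <- paste(inter$genus_x, inter$genus_y, sep = "\r")
    for (k in unique(key)) {
      sub <- inter[key == k, , drop = FALSE]
      ma <- sub$mean[sub$metric == "AAI"]
      mp <- sub$mean[sub$metric == "POCP"]
      if (!length(ma) || !length(mp)) next
      dec <- classifyPair(ma, mp, thresholds)
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        genus_x = sub$genus_x[1L], genus_y = sub$genus_y[1L],
        mean_aai = ma, mean_pocp = mp, decision = dec,
        stringsAsFactors = FALSE)
      if (dec == "congeneric")
        edges <- rbind(edges, c(sub$genus_x[1L], sub$genus_y[1L]))
    }
  }
  evidence <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(genus_x = character(), genus_y = character(),
               mean_aai = numeric(), mean_pocp = numeric(),
               decision = character(), stringsAsFactors = FALSE)
  comps <- .components(genera, edges)
  comps <- lapply(comps, sort)
  comps <- comps[vapply(comps, length, integer(1)) >= 2L]
  comps <- unname(comps[order(vapply(comps, `[`, character(1), 1L))])
  target <- vapply(comps, function(members) {
    pri <- namePriority[namePriority %in% members]
    if (length(pri)) pri[1L] else min(members)
  }, character(1))
  new("ReclassificationReport", summaries = summaries,
      mergeComponents = comps, evidence = evidence,
      targetNames = target, thresholds = thresholds)
}

#' Write a reclassification report to disk
#'
#' Emits `group_summaries.tsv`, `merge_evidence.tsv` and a human-readable
#' `reclassification.txt`.
#'
#' @param report a [ReclassificationReport-class].
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
writeReclassificationReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "group_summaries.tsv")
  p2 <- file.path(dir, "merge_evidence.tsv")
  p3 <- file.path(dir, "reclassification.txt")
  utils::write.table(report@summaries, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report@evidence, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  th <- report@thresholds
  txt <- c("Genus reclassification report",
           sprintf("Thresholds: AAI >= %.1f%%, POCP >= %.1f%% (gray zone up to %.1f%%)",
                   th$aaiGenus, th$pocpGenus, th$pocpUpper), "")
  if (!length(report@mergeComponents)) {
    txt <- c(txt, "No genus merges proposed.")
  } else {
    for (i in seq_along(report@mergeComponents)) {
      members <- report@mergeComponents[[i]]
      txt <- c(txt, sprintf("Proposed merge %d: %s -> %s", i,
                            paste(members, collapse = " + "),
                            report@targetNames[i]))
      ev <- report@evidence
      sel <- ev$genus_x %in% members & ev$genus_y %in% members
      for (r in which(sel))
        txt <- c(txt, sprintf(
          "  %s vs %s: mean AAI %.2f%%, mean POCP %.2f%% [%s]",
          ev$genus_x[r], ev$genus_y[r], ev$mean_aai[r], ev$mean_pocp[r],
          ev$decision[r]))
    }
  }
  writeLines(txt, p3)
  invisible(c(p1, p2, p3))
}

#' Scatter plot of pairwise AAI vs POCP with genus thresholds
#'
#' Mirrors the within/between-genus distribution view: every genome pair
#' as a point, colored by intra- vs inter-genus, with threshold lines.
#' Requires ggplot2.
#'
#' @inheritParams summarizeGroups
#' @param thresholds a [genusThresholds()] list.
#' @return a ggplot object.
#' @export
plotDelineation <- function(aaiM, pocpM = NULL, labels,
                            thresholds = genusThresholds()) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotDelineation requires the ggplot2 package")
  if (is(aaiM, "GenomeMetricsSet")) {
    pocpM <- aaiM@pocp
    aaiM <- aaiM@aai
  }
  lab <- .checkLabels(aaiM, labels)
  ids <- rownames(aaiM)
  idx <- which(upper.tri(aaiM), arr.ind = TRUE)
  df <- data.frame(
    aai = aaiM[idx], pocp = pocpM[idx],
    type = ifelse(lab[ids[idx[, 1]]] == lab[ids[idx[, 2]]],
                  "intra-genus", "inter-genus"))
  ggplot2::ggplot(df, ggplot2::aes(x = pocp, y = aai, color = type)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = thresholds$aaiGenus,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(thresholds$pocpGenus,
                                       thresholds$pocpUpper),
                        linetype = "dashed") +
    ggplot2::labs(x = "POCP (%)", y = "AAI (%)", color = NULL)
}
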