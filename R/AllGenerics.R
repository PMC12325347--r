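#' @rdname Proteome-class
#' @param x,object a `Proteome`.
#' @export
setGeneric("genomeID", function(x) standardGeneric("genomeID"))

#' @rdname Proteome-class
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname Proteome-class
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @rdname PairwiseGenomeMetrics-class
#' @param x,object a `PairwiseGenomeMetrics`.
#' @export
setGeneric("aaiMean", function(x) standardGeneric("aaiMean"))

#' @rdname PairwiseGenomeMetrics-class
#' @export
setGeneric("aaiNPairs", function(x) standardGeneric("aaiNPairs"))

#' @rdname PairwiseGenomeMetrics-class
#' @export
setGeneric("aaiDefined", function(x) standardGeneric("aaiDefined"))

#' @rdname PairwiseGenomeMetrics-class
#' @export
setGeneric("pocp", function(x) standardGeneric("pocp"))

#' @rdname PairwiseGenomeMetrics-class
#' @export
setGeneric("conservedCounts", function(x) standardGeneric("conservedCounts"))

#' @rdname GenomeMetricsSet-class
#' @param x,object a `GenomeMetricsSet`.
#' @export
setGeneric("aaiMatrix", function(x) standardGeneric("aaiMatrix"))

#' @rdname GenomeMetricsSet-class
#' @export
setGeneric("pocpMatrix", function(x) standardGeneric("pocpMatrix"))

#' @rdname GenomeMetricsSet-class
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' @rdname SeqDistanceMatrix-class
#' @param x,object a `SeqDistanceMatrix`.
#' @export
setGeneric("isSaturated", function(x) standardGeneric("isSaturated"))

#' @rdname SeqDistanceMatrix-class
#' @export
setGeneric("distModel", function(x) standardGeneric("distModel"))

#' @rdname ReclassificationReport-class
#' @param x,object a `ReclassificationReport`.
#' @export
setGeneric("mergeComponents", function(x) standardGeneric("mergeComponents"))

#' @rdname ReclassificationReport-class
#' @export
setGeneric("mergeEvidence", function(x) standardGeneric("mergeEvidence"))

#' @rdname ReclassificationReport-class
#' @export
setGeneric("groupSummaries", function(x) standardGeneric("groupSummaries"))

#' @rdname ReclassificationReport-class
#' @export
setGeneric("targetNames", function(x) standardGeneric("targetNames"))

# ---- methods ----

#' @rdname Proteome-class
#' @export
setMethod("genomeID", "Proteome", function(x) x@genomeID)

#' @rdname Proteome-class
#' @export
setMethod("proteins", "Proteome", function(x) x@proteins)

#' @rdname Proteome-class
#' @export
setMethod("nProteins", "Proteome", function(x) length(x@proteins))

setMethod("show", "Proteome", function(object) {
  cat(sprintf("Proteome '%s': %d proteins, %d residues total\n",
              object@genomeID, length(object@proteins),
              sum(Biostrings::width(object@proteins))))
})

#' @rdname PairwiseGenomeMetrics-class
#' @export
setMethod("aaiMean", "PairwiseGenomeMetrics", function(x)
  if (x@aaiDefined) x@aaiMean else NA_real_)

#' @rdname PairwiseGenomeMetrics-class
#' @export
setMethod("aaiNPairs", "PairwiseGenomeMetrics", function(x) x@aaiNPairs)

#' @rdname PairwiseGenomeMetrics-class
#' @export
setMethod("aaiDefined", "PairwiseGenomeMetrics", function(x) x@aaiDefined)

#' @rdname PairwiseGenomeMetrics-class
#' @export
setMethod("pocp", "PairwiseGenomeMetrics", function(x) x@pocp)

#' @rdname PairwiseGenomeMetrics-class
#' @export
setMethod("conservedCounts", "PairwiseGenomeMetrics", function(x)
  c(c1 = x@c1, c2 = x@c2, t1 = x@t1, t2 = x@t2))

setMethod("show", "PairwiseGenomeMetrics", function(object) {
  aai <- if (object@aaiDefined)
    sprintf("%.2f%% over %d RBH pairs", object@aaiMean, object@aaiNPairs)
  else "undefined (no RBH pair passed filters)"
  cat(sprintf("Genome pair %s vs %s\n", object@genomeA, object@genomeB))
  cat(sprintf("  AAI : %s\n", aai))
  if (!is.na(object@pocp))
    cat(sprintf("  POCP: %.2f%% (C1=%d/T1=%d, C2=%d/T2=%d)\n",
                object@pocp, object@c1, object@t1, object@c2, object@t2))
})

#' @rdname GenomeMetricsSet-class
#' @export
setMethod("aaiMatrix", "GenomeMetricsSet", function(x) x@aai)

#' @rdname GenomeMetricsSet-class
#' @export
setMethod("pocpMatrix", "GenomeMetricsSet", function(x) x@pocp)

#' @rdname GenomeMetricsSet-class
#' @export
setMethod("metricsTable", "GenomeMetricsSet", function(x) x@table)

setMethod("show", "GenomeMetricsSet", function(object) {
  cat(sprintf("GenomeMetricsSet: %d genomes, %d pairs\n",
              nrow(object@aai), nrow(object@table)))
})

#' @rdname SeqDistanceMatrix-class
#' @param ... unused.
#' @export
setMethod("as.matrix", "SeqDistanceMatrix", function(x, ...) x@d)

#' @rdname SeqDistanceMatrix-class
#' @export
setMethod("isSaturated", "SeqDistanceMatrix", function(x) x@saturated)

#' @rdname SeqDistanceMatrix-class
#' @export
setMethod("distModel", "SeqDistanceMatrix", function(x) x@model)

setMethod("show", "SeqDistanceMatrix", function(object) {
  cat(sprintf("SeqDistanceMatrix (%s): %d taxa%s\n", object@model,
              length(object@ids),
              if (any(object@saturated)) ", contains saturated pairs" else ""))
})

#' @rdname ReclassificationReport-class
#' @export
setMethod("mergeComponents", "ReclassificationReport", function(x)
  x@mergeComponents)

#' @rdname ReclassificationReport-class
#' @export
setMethod("mergeEvidence", "ReclassificationReport", function(x) x@evidence)

#' @rdname ReclassificationReport-class
#' @export
setMethod("groupSummaries", "ReclassificationReport", function(x) x@summaries)

#' @rdname ReclassificationReport-class
#' @export
setMethod("targetNames", "ReclassificationReport", function(x) x@targetNames)

setMethod("show", "ReclassificationReport", function(object) {
  cat("Genus reclassification report\n")
  if (!length(object@mergeComponents)) {
    cat("  No merges proposed.\n")
  } else {
    for (i in seq_along(object@mergeComponents)) {
      cat(sprintf("  Merge %d: {%s} -> %s\n", i,
                  paste(object@mergeComponents[[i]], collapse = ", "),
                  object@targetNames[i]))
    }
  }
  cat(sprintf("  %d group summaries, %d genus-pair decisions\n",
              nrow(object@summaries), nrow(object@evidence)))
})

setMethod("show", "ModuleDefinition", function(object) {
  cat(sprintf("ModuleDefinition %s: %d blocks\n  %s\n",
              object@moduleID, object@nBlocks, object@definition))
})
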