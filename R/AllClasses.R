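#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Proteome: one genome's set of protein sequences
#'
#' A `Proteome` wraps an [Biostrings::AAStringSet] together with a genome
#' identifier. It is the unit of comparison for AAI and POCP; the number of
#' proteins is the `T` denominator of POCP.
#'
#' @slot genomeID single genome identifier.
#' @slot proteins an `AAStringSet`; names are protein ids (unique, non-empty).
#'
#' @seealso [readProteome()], [computeAAI()], [computePOCP()]
#' @exportClass Proteome
setClass("Proteome", representation(
  genomeID = "character",
  proteins = "AAStringSet"
))

setValidity("Proteome", function(object) {
  msg <- character()
  if (length(object@genomeID) != 1L || !nzchar(object@genomeID))
    msg <- c(msg, "genomeID must be a single non-empty string")
  ids <- names(object@proteins)
  if (length(object@proteins) < 1L)
    msg <- c(msg, "a Proteome must contain at least one protein")
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "all proteins must have non-empty ids")
  if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate protein id: %s",
                          ids[duplicated(ids)][1L]))
  if (length(object@proteins) && any(Biostrings::width(object@proteins) == 0L))
    msg <- c(msg, "empty protein sequence")
  if (length(msg)) msg else TRUE
})

#' Proteome constructor
#'
#' @param genomeID single genome identifier.
#' @param proteins an `AAStringSet` (or named character vector of amino-acid
#'   sequences) whose names are unique protein ids.
#' @return a [Proteome-class] object.
#' @examples
#' p <- Proteome("g1", c(p1 = "MKTAYIAKQR", p2 = "MSVLTPLLLR"))
#' nProteins(p)
#' @export
Proteome <- function(genomeID, proteins) {
  if (!is(proteins, "AAStringSet"))
    proteins <- Biostrings::AAStringSet(proteins)
  new("Proteome", genomeID = as.character(genomeID), proteins = proteins)
}

#' Pairwise AAI/POCP metrics for a genome pair
#'
#' Container for the quantitative comparison of two proteomes: the mean
#' amino-acid identity over filtered reciprocal best hits (AAI), the number
#' of retained RBH pairs, the conserved-protein counts `C1`/`C2` per search
#' direction, the proteome sizes `T1`/`T2`, and
#' `POCP = 100 * (C1 + C2) / (T1 + T2)`.
#'
#' AAI can be undefined when no RBH pair passes the quality filters; this is
#' recorded explicitly (`aaiDefined(x)` is `FALSE`, `aaiMean(x)` is `NA`),
#' never as 0.
#'
#' @slot genomeA,genomeB genome ids.
#' @slot aaiMean mean percent identity over retained RBH pairs (`NA` when
#'   undefined).
#' @slot aaiNPairs number of RBH pairs retained by the AAI filters.
#' @slot aaiDefined `TRUE` when at least one RBH pair passed the filters.
#' @slot pocp percentage of conserved proteins.
#' @slot c1,c2 conserved-protein counts for the A->B and B->A directions.
#' @slot t1,t2 proteome sizes of A and B.
#' @exportClass PairwiseGenomeMetrics
setClass("PairwiseGenomeMetrics", representation(
  genomeA = "character",
  genomeB = "character",
  aaiMean = "numeric",
  aaiNPairs = "integer",
  aaiDefined = "logical",
  pocp = "numeric",
  c1 = "integer",
  c2 = "integer",
  t1 = "integer",
  t2 = "integer"
))

setValidity("PairwiseGenomeMetrics", function(object) {
  msg <- character()
  if (object@aaiDefined &&
      (is.na(object@aaiMean) || object@aaiMean < 0 || object@aaiMean > 100))
    msg <- c(msg, "aaiMean must lie in [0, 100] when defined")
  if (!is.na(object@pocp)) {
    if (object@pocp < 0 || object@pocp > 100)
      msg <- c(msg, "pocp must lie in [0, 100]")
    lhs <- object@pocp * (object@t1 + object@t2)
    rhs <- 100 * (object@c1 + object@c2)
    if (abs(lhs - rhs) > 1e-9 * max(1, abs(rhs)))
      msg <- c(msg, "pocp must equal 100*(c1+c2)/(t1+t2)")
    if (object@c1 > object@t1 || object@c2 > object@t2)
      msg <- c(msg, "conserved counts cannot exceed proteome sizes")
  }
  if (length(msg)) msg else TRUE
})

#' All-pairs genome metrics
#'
#' Result of [allPairsMetrics()]: symmetric AAI and POCP matrices (diagonal
#' 100) plus a long-form table with one row per unordered genome pair.
#'
#' @slot aai,pocp symmetric numeric matrices with genome ids as dimnames.
#'   AAI entries are `NA` where AAI is undefined for a pair.
#' @slot table `data.frame` with columns `genome_a`, `genome_b`,
#'   `aai_mean_pct`, `aai_n_pairs`, `pocp_pct`, `c1`, `c2`, `t1`, `t2`.
#' @exportClass GenomeMetricsSet
setClass("GenomeMetricsSet", representation(
  aai = "matrix",
  pocp = "matrix",
  table = "data.frame"
))

setValidity("GenomeMetricsSet", function(object) {
  msg <- character()
  for (nm in c("aai", "pocp")) {
    m <- slot(object, nm)
    if (!identical(rownames(m), colnames(m)))
      msg <- c(msg, sprintf("%s matrix dimnames must match", nm))
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-9, check.attributes = FALSE)))
      msg <- c(msg, sprintf("%s matrix must be symmetric", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Distance matrix over aligned 16S sequences
#'
#' Symmetric non-negative distances with zero diagonal, computed under a
#' p-distance, JC69 or K2P model. Pairs whose model transform is undefined
#' (logarithm argument <= 0, i.e. mutationally saturated) carry `NA` in the
#' matrix and `TRUE` in the `saturated` flag matrix.
#'
#' @slot ids taxon ids, in matrix order.
#' @slot d symmetric distance matrix (substitutions/site).
#' @slot saturated logical matrix flagging saturated pairs.
#' @slot model one of `"p"`, `"JC69"`, `"K2P"`.
#' @exportClass SeqDistanceMatrix
setClass("SeqDistanceMatrix", representation(
  ids = "character",
  d = "matrix",
  saturated = "matrix",
  model = "character"
))

setValidity("SeqDistanceMatrix", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (!all(dim(object@d) == c(n, n)))
    msg <- c(msg, "distance matrix dimensions must match ids")
  fin <- object@d[!is.na(object@d)]
  if (any(fin < 0))
    msg <- c(msg, "distances must be non-negative")
  if (n && any(diag(object@d) != 0))
    msg <- c(msg, "diagonal must be zero")
  ok <- is.na(object@d) | is.na(t(object@d)) |
    abs(object@d - t(object@d)) < 1e-12
  if (!all(ok))
    msg <- c(msg, "distance matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Genus-level reclassification report
#'
#' Result of [proposeMerges()]: per-group distribution summaries of AAI and
#' POCP, the genus sets proposed for merging (connected components of the
#' "congeneric" graph), the pairwise evidence behind each decision, and the
#' nomenclatural target name chosen for each merged component.
#'
#' @slot summaries `data.frame` from [summarizeGroups()].
#' @slot mergeComponents list of character vectors, each a set of genera
#'   proposed as one genus (disjoint).
#' @slot evidence `data.frame` with one row per genus pair: inter-genus mean
#'   AAI and POCP, and the threshold decision.
#' @slot targetNames character, one proposed genus name per component.
#' @slot thresholds the [GenusThresholds-class] used.
#' @exportClass ReclassificationReport
setClass("ReclassificationReport", representation(
  summaries = "data.frame",
  mergeComponents = "list",
  evidence = "data.frame",
  targetNames = "character",
  thresholds = "ANY"
))

setValidity("ReclassificationReport", function(object) {
  msg <- character()
  all_members <- unlist(object@mergeComponents)
  if (anyDuplicated(all_members))
    msg <- c(msg, "merge components must be disjoint")
  if (length(object@targetNames) != length(object@mergeComponents))
    msg <- c(msg, "one target name per merge component required")
  if (length(msg)) msg else TRUE
})

#' Parsed KEGG-style module definition
#'
#' A boolean expression over KO identifiers, parsed from the KEGG definition
#' syntax: space = serial steps (AND), comma = alternatives (OR), plus =
#' complex (all subunits required), minus prefix = optional component
#' (ignored in scoring). Completeness is the fraction of satisfied
#' top-level steps ("blocks").
#'
#' @slot moduleID module identifier (e.g. `"M00003"`).
#' @slot expr parsed expression tree (nested lists; internal format).
#' @slot nBlocks number of scorable top-level blocks.
#' @slot definition the source definition string.
#' @exportClass ModuleDefinition
setClass("ModuleDefinition", representation(
  moduleID = "character",
  expr = "list",
  nBlocks = "integer",
  definition = "character"
))

setValidity("ModuleDefinition", function(object) {
  if (object@nBlocks < 1L)
    "a module must contain at least one non-optional block"
  else TRUE
})
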