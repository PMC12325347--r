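# Parameter containers. Plain validated lists with a class attribute: they
# are passed around a lot and users override single fields, which list
# semantics make painless.

#' Protein alignment parameters
#'
#' Scoring parameters for the local protein alignments underlying AAI and
#' POCP: substitution matrix, affine gap penalties, and the Karlin-Altschul
#' constants used to convert raw scores into bit scores and e-values
#' (`E = K * m * n * exp(-lambda * S)`). Defaults follow the gapped
#' BLOSUM62 regime (gap open 11, extend 1, lambda = 0.267, K = 0.041);
#' `n` is taken as the total residue count of the subject proteome.
#'
#' @param substitutionMatrix name of a built-in amino-acid matrix
#'   (passed to [Biostrings::pairwiseAlignment()]).
#' @param gapOpen,gapExtend positive gap penalties (a gap of length L costs
#'   `gapOpen + L * gapExtend`).
#' @param lambda,k Karlin-Altschul scale and K constants.
#' @return an `AlignParams` list.
#' @examples
#' alignParams(gapOpen = 10)
#' @export
alignParams <- function(substitutionMatrix = "BLOSUM62",
                        gapOpen = 11, gapExtend = 1,
                        lambda = 0.267, k = 0.041) {
  stopifnot(gapOpen >= gapExtend, gapExtend > 0, lambda > 0, k > 0)
  structure(list(substitutionMatrix = substitutionMatrix,
                 gapOpen = gapOpen, gapExtend = gapExtend,
                 lambda = lambda, k = k),
            class = c("AlignParams", "list"))
}

#' AAI quality filters
#'
#' Filters applied to reciprocal best hits before averaging identities:
#' minimum percent identity, minimum coverage of the shorter sequence, and
#' maximum e-value. Identity and coverage filters are inclusive (`>=`).
#'
#' @param minIdentity minimum percent identity (default 30).
#' @param minCover minimum percent coverage of the shorter sequence
#'   (default 70).
#' @param maxEvalue maximum e-value (default 1e-5, strict `<`).
#' @return an `AaiParams` list.
#' @export
aaiParams <- function(minIdentity = 30, minCover = 70, maxEvalue = 1e-5) {
  stopifnot(minIdentity >= 0, minIdentity <= 100,
            minCover > 0, minCover <= 100, maxEvalue > 0)
  structure(list(minIdentity = minIdentity, minCover = minCover,
                 maxEvalue = maxEvalue),
            class = c("AaiParams", "list"))
}

#' Genus delineation thresholds
#'
#' Organisms sharing at least `aaiGenus` percent AAI and at least
#' `pocpGenus` percent POCP are treated as congeneric; `pocpUpper` is the
#' upper bound of the commonly cited POCP gray zone (50-60%) and is used
#' only in report text.
#'
#' @param aaiGenus genus-level AAI threshold in percent (default 65).
#' @param pocpGenus genus-level POCP threshold in percent (default 50).
#' @param pocpUpper upper bound of the POCP gray zone (default 60).
#' @return a `GenusThresholds` list.
#' @export
genusThresholds <- function(aaiGenus = 65, pocpGenus = 50, pocpUpper = 60) {
  stopifnot(aaiGenus > 0, aaiGenus < 100, pocpGenus <= pocpUpper)
  structure(list(aaiGenus = aaiGenus, pocpGenus = pocpGenus,
                 pocpUpper = pocpUpper),
            class = c("GenusThresholds", "list"))
}

#' PUL / gene-cluster detection parameters
#'
#' Marker genes (degradative CAZymes, sulfatases, TonB-dependent
#' transporters, susD-like genes) are chained into one cluster when their
#' gene-ordinal distance is at most `maxGapGenes` (single linkage, per
#' contig). `windowGenes` is the scan window width of the sliding-window
#' formulation; it affects scanning only and can never change cluster
#' membership, which is governed solely by the linkage rule.
#'
#' @param maxGapGenes maximum ordinal distance joining two markers
#'   (default 10, inclusive).
#' @param windowGenes scan window in genes (default 7).
#' @param minMarkers minimum markers per reported cluster (default 2).
#' @param requireCazyme require at least one degradative CAZyme per cluster
#'   (default TRUE).
#' @return a `PulParams` list.
#' @export
pulParams <- function(maxGapGenes = 10, windowGenes = 7, minMarkers = 2,
                      requireCazyme = TRUE) {
  stopifnot(maxGapGenes >= 1, windowGenes >= 1, minMarkers >= 2)
  structure(list(maxGapGenes = as.integer(maxGapGenes),
                 windowGenes = as.integer(windowGenes),
                 minMarkers = as.integer(minMarkers),
                 requireCazyme = isTRUE(requireCazyme)),
            class = c("PulParams", "list"))
}

#' 16S phylogeny parameters
#'
#' @param model distance model: `"K2P"` (default), `"JC69"` or `"p"`.
#' @param nBootstrap bootstrap replicates (default 1000).
#' @param seed integer seed for column resampling.
#' @param minShowSupport supports below this are kept but flagged hidden
#'   for display (default 50).
#' @return a `PhyloParams` list.
#' @export
phyloParams <- function(model = c("K2P", "JC69", "p"), nBootstrap = 1000,
                        seed = 1L, minShowSupport = 50) {
  model <- match.arg(model)
  stopifnot(nBootstrap >= 0)
  structure(list(model = model, nBootstrap = as.integer(nBootstrap),
                 seed = as.integer(seed),
                 minShowSupport = minShowSupport),
            class = c("PhyloParams", "list"))
}
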