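# KEGG-style metabolic module completeness. A module definition is a
# boolean expression over KO identifiers with operator precedence
# minus > plus > comma > space (parentheses override):
#   space  serial steps, all required        -> AND blocks
#   comma  alternatives                      -> OR
#   plus   protein complex, all subunits     -> COMPLEX
#   minus  optional component, not scored    -> OPTIONAL
# Completeness is the fraction of satisfied top-level AND blocks, matching
# step-fraction semantics of KEGG Mapper style reports.

.tokenizeDefinition <- function(text) {
  chars <- strsplit(text, "")[[1]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("[A-Za-z0-9_.]", ch)) {
      j <- i
      while (j < n && grepl("[A-Za-z0-9_.]", chars[j + 1L])) j <- j + 1L
      toks[[length(toks) + 1L]] <- list(
        type = "ID", value = paste(chars[i:j], collapse = ""), pos = i)
      i <- j + 1L
    } else if (ch %in% c("(", ")", ",", "+", "-")) {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L
    } else if (grepl("\\s", ch)) {
      # collapse runs of whitespace into one AND separator
      if (length(toks) && toks[[length(toks)]]$type != "SPACE")
        toks[[length(toks) + 1L]] <- list(type = "SPACE", value = " ",
                                          pos = i)
      i <- i + 1L
    } else {
      stop(sprintf("module definition parse error at offset %d: '%s'",
                   i, ch))
    }
  }
  # trim leading/trailing space tokens
  while (length(toks) && toks[[1L]]$type == "SPACE") toks[[1L]] <- NULL
  while (length(toks) && toks[[length(toks)]]$type == "SPACE")
    toks[[length(toks)]] <- NULL
  toks
}

# recursive-descent parser over the token stream held in an environment
.parseAnd <- function(st) {
  children <- list(.parseOr(st))
  while (!is.null(.peek(st)) && .peek(st)$type == "SPACE") {
    .advance(st)
    children[[length(children) + 1L]] <- .parseOr(st)
  }
  if (length(children) == 1L) children[[1L]]
  else list(kind = "AND", children = children)
}

.parseOr <- function(st) {
  children <- list(.parseComplex(st))
  while (!is.null(.peek(st)) && .peek(st)$type == ",") {
    .advance(st)
    children[[length(children) + 1L]] <- .parseComplex(st)
  }
  if (length(children) == 1L) children[[1L]]
  else list(kind = "OR", children = children)
}

.parseComplex <- function(st) {
  first <- .parsePrimary(st)
  children <- list(first)
  optional <- FALSE
  while (!is.null(.peek(st)) && .peek(st)$type %in% c("+", "-")) {
    op <- .advance(st)
    nxt <- .parsePrimary(st)
    if (op$type == "-") nxt <- list(kind = "OPTIONAL", child = nxt)
    children[[length(children) + 1L]] <- nxt
    optional <- TRUE
  }
  if (length(children) == 1L) first
  else list(kind = "COMPLEX", children = children)
}

.parsePrimary <- function(st) {
  tok <- .peek(st)
  if (is.null(tok))
    stop(sprintf("module definition parse error at offset %d: %s",
                 st$lastPos, "dangling operator"))
  if (tok$type == "ID") {
    .advance(st)
    return(list(kind = "STEP", ko = tok$value))
  }
  if (tok$type == "-") {       # leading minus: optional component
    .advance(st)
    return(list(kind = "OPTIONAL", child = .parsePrimary(st)))
  }
  if (tok$type == "(") {
    .advance(st)
    inner <- .parseAnd(st)
    close <- .peek(st)
    if (is.null(close) || close$type != ")")
      stop(sprintf("module definition parse error at offset %d: %s",
                   tok$pos, "unbalanced parenthesis"))
    .advance(st)
    return(inner)
  }
  stop(sprintf("module definition parse error at offset %d: unexpected '%s'",
               tok$pos, tok$value))
}

.peek <- function(st) {
  if (st$i > length(st$toks)) NULL else st$toks[[st$i]]
}

.advance <- function(st) {
  tok <- st$toks[[st$i]]
  st$lastPos <- tok$pos
  st$i <- st$i + 1L
  tok
}

.hasRequiredStep <- function(node) {
  switch(node$kind,
    STEP = TRUE,
    OPTIONAL = FALSE,
    any(vapply(node$children, .hasRequiredStep, logical(1))))
}

#' Parse a KEGG-style module definition string
#'
#' @param text definition string over KO ids, spaces, commas, parentheses,
#'   `+` and `-`.
#' @param moduleID module identifier carried into the result.
#' @return a [ModuleDefinition-class].
#' @examples
#' parseModuleDefinition("(K00001,K00002) K00003", "M_demo")
#' @export
parseModuleDefinition <- function(text, moduleID = "module") {
  if (!nzchar(trimws(text))) stop("empty module definition")
  st <- new.env(parent = emptyenv())
  st$toks <- .tokenizeDefinition(text)
  st$i <- 1L
  st$lastPos <- nchar(text)
  expr <- .parseAnd(st)
  left <- .peek(st)
  if (!is.null(left))
    stop(sprintf("module definition parse error at offset %d: unexpected '%s'",
                 left$pos, left$value))
  blocks <- .topBlocks(expr)
  nb <- sum(vapply(blocks, .hasRequiredStep, logical(1)))
  if (nb < 1L) stop("module definition has no non-optional step")
  new("ModuleDefinition", moduleID = moduleID, expr = expr,
      nBlocks = as.integer(nb), definition = text)
}

.topBlocks <- function(expr) {
  if (identical(expr$kind, "AND")) expr$children else list(expr)
}

.evalNode <- function(node, koSet) {
  switch(node$kind,
    STEP = node$ko %in% koSet,
    OPTIONAL = TRUE,
    AND = all(vapply(node$children, .evalNode, logical(1), koSet = koSet)),
    OR = any(vapply(node$children, .evalNode, logical(1), koSet = koSet)),
    COMPLEX = all(vapply(node$children, .evalNode, logical(1),
                         koSet = koSet)))
}

#' Module completeness for a KO set
#'
#' The percentage of satisfied top-level blocks: a block is satisfied when
#' its boolean subtree evaluates true given the KO set (complexes require
#' all non-optional subunits; optional components are ignored and
#' entirely-optional blocks are excluded from both numerator and
#' denominator).
#'
#' @param module a [ModuleDefinition-class] (or definition string).
#' @param koSet character vector of KO ids present in the genome.
#' @return completeness percentage in `[0, 100]`.
#' @examples
#' moduleCompleteness("K00001 K00002", c("K00001"))  # 50
#' @export
moduleCompleteness <- function(module, koSet) {
  if (is.character(module)) module <- parseModuleDefinition(module)
  blocks <- .topBlocks(module@expr)
  blocks <- blocks[vapply(blocks, .hasRequiredStep, logical(1))]
  sat <- vapply(blocks, .evalNode, logical(1), koSet = koSet)
  100 * sum(sat) / length(sat)
}

#' Read module definitions / KO sets from TSV
#'
#' Definitions: two columns `module_id`, `definition`. KO sets: two
#' columns `genome_id`, `ko`.
#'
#' @param path TSV path.
#' @return `readModuleDefinitions`: named list of
#'   [ModuleDefinition-class]; `readKoSets`: named list of character
#'   vectors per genome.
#' @export
readModuleDefinitions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("module_id", "definition") %in% names(df)))
    stop("module definition table must have columns module_id, definition")
  stats::setNames(
    lapply(seq_len(nrow(df)), function(i)
      parseModuleDefinition(df$definition[i], df$module_id[i])),
    df$module_id)
}

#' @rdname readModuleDefinitions
#' @export
readKoSets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "ko") %in% names(df)))
    stop("KO set table must have columns genome_id, ko")
  lapply(split(df$ko, df$genome_id), unique)
}

#' Long-form completeness table across genomes and modules
#'
#' @param modules named list of [ModuleDefinition-class] (or definition
#'   strings).
#' @param koSets named list of KO-id character vectors, one per genome.
#' @return `data.frame` with columns `genome_id`, `module_id`,
#'   `completeness_pct`, suitable for heatmapping.
#' @export
completenessTable <- function(modules, koSets) {
  modules <- lapply(modules, function(m)
    if (is.character(m)) parseModuleDefinition(m) else m)
  rows <- list()
  for (g in names(koSets)) for (m in names(modules)) {
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = g, module_id = m,
      completeness_pct = moduleCompleteness(modules[[m]], koSets[[g]]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
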