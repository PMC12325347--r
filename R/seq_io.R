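# Readers and writers for the formats every stage touches: FASTA, gene
# annotation TSV, Newick, square metric matrices. Parsing itself is
# delegated to Biostrings / ape; this layer adds the validation contracts
# (unique ids, alphabet checks with line numbers, consecutive ordinals).

.GENE_LABELS <- c("GH", "GT", "PL", "CE", "AA", "CBM",
                  "SULFATASE", "TBDT", "SUSD", "OTHER")
.CAZYME_LABELS <- c("GH", "GT", "PL", "CE", "AA", "CBM")
.DEGRADATIVE_CAZYMES <- c("GH", "PL", "CE", "CBM", "AA")
.MARKER_LABELS <- c(.DEGRADATIVE_CAZYMES, "SULFATASE", "TBDT", "SUSD")

.PROTEIN_CHARS <- "ACDEFGHIKLMNPQRSTVWYBJOUXZ*"
.NUC_CHARS <- "ACGTUNRYSWKMBDHV"

# locate the first file line whose sequence block contains `ch` for record id
.badCharLine <- function(path, id, ch) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  rec_start <- hdr[vapply(lines[hdr], function(h)
    sub("^>(\\S+).*$", "\\1", h) == id, logical(1))][1]
  if (is.na(rec_start)) return(NA_integer_)
  nxt <- hdr[hdr > rec_start][1]
  stop_at <- if (is.na(nxt)) length(lines) else nxt - 1L
  for (i in seq(rec_start + 1L, stop_at)) {
    if (grepl(ch, lines[i], fixed = TRUE)) return(i)
  }
  NA_integer_
}

#' Read a FASTA file of protein or nucleotide sequences
#'
#' Wraps [Biostrings::readBStringSet()] and enforces the contracts the
#' downstream pipeline relies on: record ids (the first whitespace-delimited
#' header token) are unique and non-empty, sequences are non-empty,
#' uppercased, and drawn from the declared alphabet. Gap characters `-` are
#' accepted only for nucleotide input declared as an alignment.
#'
#' The remainder of each header is kept as the record description in
#' `mcols(x)$description`.
#'
#' @param path path to a text FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param alignment logical; permit `-` gap characters (nucleotide only).
#' @return an `AAStringSet` or `DNAStringSet` named by record id.
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 a protein", "MKT", "AYI"), tf)
#' readFasta(tf, "protein")
#' @export
readFasta <- function(path, alphabet = c("protein", "nucleotide"),
                      alignment = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    out <- if (alphabet == "protein") Biostrings::AAStringSet()
           else Biostrings::DNAStringSet()
    return(out)
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids)))
    stop("FASTA format error in ", path, ": record with empty id")
  if (anyDuplicated(ids))
    stop("FASTA format error in ", path, ": duplicate record id '",
         ids[duplicated(ids)][1L], "'")
  seqs <- toupper(as.character(raw))
  if (any(!nzchar(seqs)))
    stop("FASTA format error in ", path, ": empty sequence for record '",
         ids[!nzchar(seqs)][1L], "'")
  allowed <- if (alphabet == "protein") .PROTEIN_CHARS else .NUC_CHARS
  if (alphabet == "nucleotide" && alignment) allowed <- paste0(allowed, "-")
  bad_re <- sprintf("[^%s]", gsub("([*-])", "\\\\\\1", allowed))
  pos <- regexpr(bad_re, seqs)
  if (any(pos > 0)) {
    i <- which(pos > 0)[1L]
    ch <- substring(seqs[i], pos[i], pos[i])
    line <- .badCharLine(path, ids[i], ch)
    stop(sprintf(
      "FASTA format error in %s: character '%s' not in %s alphabet (record '%s'%s)",
      path, ch, alphabet, ids[i],
      if (is.na(line)) "" else sprintf(", line %d", line)))
  }
  out <- if (alphabet == "protein") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write sequences to FASTA
#'
#' @param x a named `XStringSet` (descriptions in `mcols(x)$description`
#'   are appended to headers) .
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 70L) {
  hdr <- names(x)
  d <- S4Vectors::mcols(x)$description
  if (!is.null(d)) hdr <- ifelse(nzchar(d), paste(hdr, d), hdr)
  y <- x
  names(y) <- hdr
  Biostrings::writeXStringSet(y, filepath = path, width = width)
  invisible(path)
}

#' Read a proteome FASTA as a Proteome object
#'
#' @param path protein FASTA path.
#' @param genomeID genome id; defaults to the file base name without
#'   extension.
#' @return a [Proteome-class].
#' @export
readProteome <- function(path, genomeID = sub("\\.[^.]*$", "", basename(path))) {
  Proteome(genomeID, readFasta(path, "protein"))
}

#' Read an annotated gene table
#'
#' Reads the per-genome ordered gene annotation TSV consumed by the PUL
#' detector: columns `genome_id`, `contig_id`, `ordinal` (0-based position
#' along the contig in annotation order), `start`, `end` (1-based,
#' inclusive), `strand` (`+`/`-`), `label` (one of GH, GT, PL, CE, AA, CBM,
#' SULFATASE, TBDT, SUSD, OTHER; dbCAN2-style classes collapsed to class
#' level). Rows may appear in any order; output is sorted by
#' (genome, contig, ordinal) and ordinals are checked to be consecutive
#' from 0 within each contig.
#'
#' @param path TSV path.
#' @return a [GenomicRanges::GRanges] (seqnames = contig) with metadata
#'   columns `genome_id`, `ordinal`, `label`.
#' @export
readGeneTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("genome_id", "contig_id", "ordinal", "start", "end",
           "strand", "label")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("gene table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  geneTable(df)
}

#' Build a validated gene-feature GRanges from a data.frame
#'
#' @param df data.frame with the [readGeneTable()] columns.
#' @return a `GRanges`, sorted by (genome, contig, ordinal).
#' @export
geneTable <- function(df) {
  bad <- setdiff(unique(df$label), .GENE_LABELS)
  if (length(bad))
    stop("unknown gene label(s): ", paste(bad, collapse = ", "))
  if (any(df$start > df$end))
    stop("gene with start > end")
  df <- df[order(df$genome_id, df$contig_id, df$ordinal), , drop = FALSE]
  key <- paste(df$genome_id, df$contig_id, sep = "\r")
  for (k in unique(key)) {
    o <- df$ordinal[key == k]
    if (!identical(as.integer(o), seq_along(o) - 1L))
      stop("non-consecutive ordinals on contig '",
           df$contig_id[key == k][1L], "' of genome '",
           df$genome_id[key == k][1L], "'")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig_id,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    genome_id = df$genome_id,
    ordinal = as.integer(df$ordinal),
    label = df$label)
  gr
}

#' Write a gene-feature GRanges back to the gene-table TSV dialect
#'
#' @param genes a `GRanges` from [readGeneTable()]/[geneTable()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  df <- data.frame(
    genome_id = S4Vectors::mcols(genes)$genome_id,
    contig_id = as.character(GenomicRanges::seqnames(genes)),
    ordinal = S4Vectors::mcols(genes)$ordinal,
    start = BiocGenerics::start(genes),
    end = BiocGenerics::end(genes),
    strand = as.character(BiocGenerics::strand(genes)),
    label = S4Vectors::mcols(genes)$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]. Numeric
#' internal-node labels are bootstrap supports. `writeNewickTree()` can
#' blank supports below a display threshold (they remain in the in-memory
#' tree).
#'
#' @param text,path Newick string or file path (one of the two).
#' @return `readNewickTree`: an [ape::phylo]; `writeNewickTree`: the Newick
#'   string, invisibly if written to a file.
#' @export
readNewickTree <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE),
                                   collapse = "")
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr))
    stop(sprintf("Newick parse error near character %d",
                 .newickErrorOffset(text)))
  tr
}

# crude but useful: offset of the first structural imbalance
.newickErrorOffset <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
    if (chars[i] == ";" && depth > 0L) return(i)
  }
  length(chars)
}

#' @rdname readNewickTree
#' @param tree an `ape::phylo`.
#' @param minSupport if not `NULL`, node labels that parse as numbers below
#'   this value are blanked in the output string.
#' @export
writeNewickTree <- function(tree, path = NULL, minSupport = NULL) {
  if (!is.null(minSupport) && !is.null(tree$node.label)) {
    lab <- tree$node.label
    num <- suppressWarnings(as.numeric(lab))
    lab[!is.na(num) & num < minSupport] <- ""
    tree$node.label <- lab
  }
  s <- ape::write.tree(tree, digits = 12)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Read / write square metric matrices as TSV
#'
#' Genome ids form the header row and first column.
#'
#' @param m numeric matrix with identical row/column names.
#' @param path TSV path.
#' @return `writeMatrixTSV`: `path` invisibly; `readMatrixTSV`: the matrix.
#' @export
writeMatrixTSV <- function(m, path) {
  df <- data.frame(genome_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a genome-to-genus label mapping
#'
#' Two-column TSV (`genome_id`, `genus`).
#'
#' @param path TSV path.
#' @return named character vector, genome id -> genus.
#' @export
readGenusLabels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "genus") %in% names(df)))
    stop("genus label table must have columns genome_id, genus")
  stats::setNames(df$genus, df$genome_id)
}
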