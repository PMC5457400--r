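## Readers and writers for the standard formats the pipeline touches.
## Coordinates on disk (GTF/GFF3) are 1-based closed, which is also the
## internal IRanges convention, so no shifting happens at the boundary.

#' Read gene models from a GTF or GFF3 file
#'
#' Exon features are grouped into transcripts and transcripts into genes.
#' Both the GTF attribute dialect (\code{gene_id "x"; transcript_id "y"}) and
#' the GFF3 \code{ID=}/\code{Parent=} chains are accepted.
#'
#' @param path path to a .gtf/.gff/.gff3 file
#' @return named list of [GeneModel-class]
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  checkAnnotationLines(path)
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  ex <- gr[mc$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  mce <- S4Vectors::mcols(ex)
  if (!is.null(mce$transcript_id) && any(!is.na(mce$transcript_id))) {
    txid <- as.character(mce$transcript_id)
    gid <- as.character(mce$gene_id)
  } else if (!is.null(mce$Parent)) {
    txid <- as.character(unlist(mce$Parent))
    # map transcript -> gene via the Parent of transcript-level features
    tx <- gr[as.character(S4Vectors::mcols(gr)$type) %in%
               c("mRNA", "transcript", "lnc_RNA", "ncRNA")]
    mtx <- S4Vectors::mcols(tx)
    t2g <- stats::setNames(as.character(unlist(mtx$Parent)),
                           as.character(mtx$ID))
    gid <- unname(t2g[txid])
    gid[is.na(gid)] <- txid[is.na(gid)]
  } else {
    stop("cannot identify transcripts: need transcript_id or Parent attributes")
  }
  genes <- list()
  for (tid in unique(txid)) {
    sel <- txid == tid
    chroms <- unique(as.character(GenomicRanges::seqnames(ex[sel])))
    if (length(chroms) != 1L)
      stop("transcript ", tid, " spans multiple chromosomes: ",
           paste(chroms, collapse = ", "))
    strands <- unique(as.character(GenomicRanges::strand(ex[sel])))
    if (length(strands) != 1L || !strands %in% c("+", "-"))
      stop("transcript ", tid, " needs a single explicit strand")
    g <- unique(gid[sel])[1L]
    r <- GenomicRanges::ranges(ex[sel])
    tm <- TranscriptModel(tid, g, chroms, strands, r)
    genes[[g]] <- c(genes[[g]], list(tm))
  }
  out <- lapply(names(genes), function(g) GeneModel(g, genes[[g]]))
  names(out) <- names(genes)
  out
}

## cheap structural validation so malformed records fail with a line number
checkAnnotationLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^(#|\\s*$)", lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L)
      stop("malformed record at line ", i, " of ", path,
           ": expected >= 8 tab-separated fields, found ", length(f))
    if (is.na(suppressWarnings(as.integer(f[4L]))) ||
        is.na(suppressWarnings(as.integer(f[5L]))))
      stop("malformed record at line ", i, " of ", path,
           ": non-numeric start/end")
  }
  invisible(TRUE)
}

#' Write gene models as GTF
#'
#' Emits one \code{transcript} and per-exon \code{exon} features per isoform,
#' 1-based closed coordinates, GTF attribute dialect.
#'
#' @param genes list of [GeneModel-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeGeneModels <- function(genes, path) {
  rows <- character(0)
  for (g in genes) {
    for (tx in g@transcripts) {
      attr <- sprintf('gene_id "%s"; transcript_id "%s";',
                      g@geneId, tx@transcriptId)
      sp <- txSpan(tx)
      rows <- c(rows, sprintf("%s\tspliceomics\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              tx@chrom, start(sp), end(sp), tx@strand, attr))
      rows <- c(rows, sprintf("%s\tspliceomics\texon\t%d\t%d\t.\t%s\t.\t%s",
                              tx@chrom, start(tx@exons), end(tx@exons),
                              tx@strand, attr))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a transcript x sample FPKM table
#'
#' @param path TSV with header; first column = transcript_id, remaining
#'   columns = samples
#' @param conditions optional character vector mapping samples to conditions
#'   (named by sample, or in column order); defaults to one condition per
#'   sample
#' @param knownTranscripts optional character vector of catalogue transcript
#'   ids; table rows absent from it trigger a warning (they are kept)
#' @return an [ExpressionMatrix-class]
#' @export
readExpression <- function(path, conditions = NULL, knownTranscripts = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs >= 2 columns")
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("empty or non-numeric FPKM cell at transcript '", ids[bad[1L]],
         "', sample '", colnames(m)[bad[2L]], "'")
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative FPKM at transcript '", ids[bad[1L]], "', sample '",
         colnames(m)[bad[2L]], "'")
  }
  rownames(m) <- ids
  if (is.null(conditions))
    conditions <- stats::setNames(colnames(m), colnames(m))
  if (!is.null(knownTranscripts)) {
    unknown <- setdiff(ids, knownTranscripts)
    if (length(unknown))
      warning(length(unknown), " transcript(s) not in the gene catalogue: ",
              paste(utils::head(unknown, 5L), collapse = ", "),
              if (length(unknown) > 5L) ", ..." else "")
  }
  ExpressionMatrix(m, conditions)
}

#' Write an ExpressionMatrix as TSV
#' @param expr an [ExpressionMatrix-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeExpression <- function(expr, path) {
  m <- fpkm(expr)
  tab <- data.frame(transcript_id = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach spliced sequences to gene models from a genome
#'
#' The spliced sequence is the concatenation of exon sequences in
#' transcription order; minus-strand transcripts are reverse-complemented so
#' every stored sequence reads 5'->3' in transcript orientation.
#'
#' @param genes list of [GeneModel-class]
#' @param genome a [Biostrings::DNAStringSet] named by chromosome, or a FASTA
#'   path
#' @return the gene list with every transcript's \code{sequence} slot set
#' @export
extractSequences <- function(genes, genome) {
  genome <- asGenome(genome)
  lapply(genes, function(g) {
    g@transcripts <- lapply(g@transcripts, function(tx) {
      tx@sequence <- splicedSequence(tx, genome)
      tx
    })
    g
  })
}

asGenome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!is.null(names(genome)))
    names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Spliced (mature) sequence of one transcript
#' @param tx a [TranscriptModel-class]
#' @param genome DNAStringSet named by chromosome
#' @return character(1), 5'->3' in transcript orientation
#' @export
splicedSequence <- function(tx, genome) {
  chromSeq <- chromOf(genome, tx@chrom)
  checkBounds(tx@exons, chromSeq, tx@transcriptId)
  pieces <- Biostrings::extractAt(chromSeq, tx@exons)
  s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (tx@strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Pre-mRNA (unspliced span) sequence of a gene
#' @param gene a [GeneModel-class]
#' @param genome DNAStringSet named by chromosome
#' @return character(1), 5'->3' in transcript orientation
#' @export
preMrnaSequence <- function(gene, genome) {
  chromSeq <- chromOf(genome, geneChrom(gene))
  sp <- geneSpan(gene)
  checkBounds(sp, chromSeq, gene@geneId)
  s <- Biostrings::subseq(chromSeq, start(sp), end(sp))
  if (geneStrand(gene) == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

chromOf <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stop("chromosome ", chrom, " not found in genome FASTA")
  genome[[chrom]]
}

checkBounds <- function(ranges, chromSeq, what) {
  if (any(start(ranges) < 1L) || any(end(ranges) > length(chromSeq)))
    stop("feature of ", what, " outside chromosome bounds (length ",
         length(chromSeq), ")")
  invisible(TRUE)
}

## flatten a gene-model list to a transcript-level lookup
transcriptIndex <- function(genes) {
  txs <- unlist(lapply(genes, function(g) g@transcripts), recursive = FALSE)
  names(txs) <- vapply(txs, function(t) t@transcriptId, character(1))
  txs
}

## transcript_id -> gene_id map
txGeneMap <- function(genes) {
  txs <- transcriptIndex(genes)
  stats::setNames(vapply(txs, function(t) t@geneId, character(1)), names(txs))
}
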