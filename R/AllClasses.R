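#' @import methods
#' @importFrom IRanges IRanges start end width reduce gaps findOverlaps
#' @importFrom S4Vectors metadata metadata<- queryHits subjectHits
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' TranscriptModel: one isoform as an ordered set of genomic exons
#'
#' Exons are stored as 1-based closed [IRanges::IRanges] in genomic
#' coordinates, sorted ascending, strictly disjoint with at least 1 nt
#' between consecutive exons. The optional \code{sequence} slot holds the
#' spliced nucleotide sequence 5'->3' in transcript orientation (i.e. already
#' reverse-complemented for minus-strand models).
#'
#' @slot transcriptId character(1)
#' @slot geneId character(1)
#' @slot chrom character(1)
#' @slot strand character(1), "+" or "-"
#' @slot exons IRanges of exon intervals, genomic order
#' @slot sequence character(1), spliced sequence or NA
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneId = "character",
    chrom = "character",
    strand = "character",
    exons = "IRanges",
    sequence = "character"
  ),
  prototype(sequence = NA_character_)
)

setValidity("TranscriptModel", function(object) {
  msg <- character(0)
  if (length(object@transcriptId) != 1L || is.na(object@transcriptId))
    msg <- c(msg, "transcriptId must be a single non-NA string")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L)
    msg <- c(msg, "transcript needs at least one exon")
  if (any(width(ex) < 1L))
    msg <- c(msg, "every exon must satisfy start <= end")
  if (length(ex) > 1L) {
    if (is.unsorted(start(ex)))
      msg <- c(msg, "exons must be sorted by genomic start")
    # non-overlapping, non-adjacent: gap >= 1 nt between consecutive exons
    if (any(start(ex)[-1L] - end(ex)[-length(ex)] < 2L))
      msg <- c(msg, "exons must be separated by introns of >= 1 nt")
  }
  if (length(msg)) msg else TRUE
})

#' GeneModel: a locus grouping one or more isoforms
#'
#' @slot geneId character(1)
#' @slot transcripts list of [TranscriptModel-class], names = transcript ids
#' @slot referenceTranscriptId character(1) or NA; the annotation-designated
#'   reference isoform, used to split "reference" vs "alternative" views
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    geneId = "character",
    transcripts = "list",
    referenceTranscriptId = "character"
  ),
  prototype(referenceTranscriptId = NA_character_)
)

setValidity("GeneModel", function(object) {
  msg <- character(0)
  txs <- object@transcripts
  if (length(txs) < 1L)
    msg <- c(msg, "gene needs at least one transcript")
  if (!all(vapply(txs, is, logical(1), "TranscriptModel")))
    return("transcripts must all be TranscriptModel objects")
  ids <- vapply(txs, function(t) t@transcriptId, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "transcript ids must be unique within a gene")
  if (!all(vapply(txs, function(t) t@geneId, character(1)) == object@geneId))
    msg <- c(msg, "all transcripts must carry the gene's geneId")
  if (length(unique(vapply(txs, function(t) t@chrom, character(1)))) != 1L)
    msg <- c(msg, "all transcripts must share one chromosome")
  if (length(unique(vapply(txs, function(t) t@strand, character(1)))) != 1L)
    msg <- c(msg, "all transcripts must share one strand")
  if (!is.na(object@referenceTranscriptId) &&
      !object@referenceTranscriptId %in% ids)
    msg <- c(msg, "referenceTranscriptId must name one of the transcripts")
  if (length(msg)) msg else TRUE
})

#' ExpressionMatrix: FPKM per transcript x sample with a condition map
#'
#' Thin subclass of [SummarizedExperiment::SummarizedExperiment] with one
#' assay \code{"fpkm"} (non-negative) and a mandatory \code{condition} column
#' in \code{colData}.
#'
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character(0)
  if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'fpkm' is required")
  else {
    v <- SummarizedExperiment::assay(object, "fpkm")
    if (any(is.na(v)))
      msg <- c(msg, "FPKM values must not be NA")
    else if (any(v < 0))
      msg <- c(msg, "FPKM values must be non-negative")
  }
  if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'condition' column")
  if (length(msg)) msg else TRUE
})

#' DetectabilityResult: outcome of the in-silico AS detection resampling
#'
#' @slot perReplicate integer, AS-distinguishable gene count per replicate
#'   (isoform-specific peptides drawn from >= 2 distinct isoforms)
#' @slot perReplicateAny integer, relaxed count (>= 1 isoform-specific peptide)
#' @slot nReps integer(1)
#' @slot seed integer(1)
#' @slot observed numeric(1), observed AS-confirmed gene count (NA if unset)
#' @exportClass DetectabilityResult
setClass("DetectabilityResult",
  representation(
    perReplicate = "integer",
    perReplicateAny = "integer",
    nReps = "integer",
    seed = "integer",
    observed = "numeric"
  ),
  prototype(observed = NA_real_)
)

setValidity("DetectabilityResult", function(object) {
  if (object@nReps < 1L) return("nReps must be >= 1")
  if (length(object@perReplicate) != object@nReps)
    return("perReplicate length must equal nReps")
  TRUE
})

## ---- constructors ----------------------------------------------------------

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneId,chrom,strand scalar identifiers
#' @param exons an IRanges, or a 2-column matrix/data.frame of (start, end)
#'   in 1-based closed genomic coordinates
#' @param sequence optional spliced sequence (5'->3', transcript orientation)
#' @return a [TranscriptModel-class]
#' @export
TranscriptModel <- function(transcriptId, geneId, chrom, strand, exons,
                            sequence = NA_character_) {
  if (!is(exons, "IRanges")) {
    exons <- as.matrix(exons)
    exons <- IRanges(start = as.integer(exons[, 1L]),
                     end = as.integer(exons[, 2L]))
  }
  exons <- exons[order(start(exons))]
  new("TranscriptModel", transcriptId = as.character(transcriptId),
      geneId = as.character(geneId), chrom = as.character(chrom),
      strand = strand, exons = exons, sequence = as.character(sequence))
}

#' Construct a GeneModel
#'
#' @param geneId scalar gene identifier
#' @param transcripts list of [TranscriptModel-class]
#' @param referenceTranscriptId optional reference isoform id
#' @return a [GeneModel-class]
#' @export
GeneModel <- function(geneId, transcripts,
                      referenceTranscriptId = NA_character_) {
  names(transcripts) <- vapply(transcripts, function(t) t@transcriptId,
                               character(1))
  new("GeneModel", geneId = as.character(geneId), transcripts = transcripts,
      referenceTranscriptId = as.character(referenceTranscriptId))
}

#' Construct an ExpressionMatrix
#'
#' @param fpkm numeric matrix, rows = transcripts, columns = samples
#' @param conditions character vector mapping samples to conditions; either
#'   named by sample or in column order
#' @return an [ExpressionMatrix-class]
#' @export
ExpressionMatrix <- function(fpkm, conditions) {
  fpkm <- as.matrix(fpkm)
  if (is.null(colnames(fpkm)))
    stop("fpkm matrix must have sample column names")
  if (!is.null(names(conditions))) {
    missing <- setdiff(colnames(fpkm), names(conditions))
    if (length(missing))
      stop("no condition given for sample(s): ",
           paste(missing, collapse = ", "))
    conditions <- conditions[colnames(fpkm)]
  } else if (length(conditions) != ncol(fpkm)) {
    stop("conditions must be named by sample or match the number of columns")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = fpkm),
    colData = S4Vectors::DataFrame(condition = as.character(conditions),
                                   row.names = colnames(fpkm)))
  new("ExpressionMatrix", se)
}

## ---- accessors -------------------------------------------------------------

#' @rdname TranscriptModel
#' @param object a TranscriptModel or GeneModel
#' @export
setGeneric("transcriptId", function(object) standardGeneric("transcriptId"))
#' @rdname TranscriptModel
#' @export
setMethod("transcriptId", "TranscriptModel", function(object) object@transcriptId)

#' @rdname GeneModel
#' @param object a GeneModel or TranscriptModel
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))
#' @rdname GeneModel
#' @export
setMethod("geneId", "TranscriptModel", function(object) object@geneId)
#' @rdname GeneModel
#' @export
setMethod("geneId", "GeneModel", function(object) object@geneId)

#' @rdname TranscriptModel
#' @export
setGeneric("exonRanges", function(object) standardGeneric("exonRanges"))
#' @rdname TranscriptModel
#' @export
setMethod("exonRanges", "TranscriptModel", function(object) object@exons)

#' @rdname TranscriptModel
#' @export
setGeneric("txSequence", function(object) standardGeneric("txSequence"))
#' @rdname TranscriptModel
#' @export
setMethod("txSequence", "TranscriptModel", function(object) object@sequence)

#' @rdname GeneModel
#' @export
setGeneric("transcripts", function(object) standardGeneric("transcripts"))
#' @rdname GeneModel
#' @export
setMethod("transcripts", "GeneModel", function(object) object@transcripts)

#' @rdname ExpressionMatrix
#' @param object an ExpressionMatrix
#' @export
setGeneric("fpkm", function(object) standardGeneric("fpkm"))
#' @rdname ExpressionMatrix
#' @export
setMethod("fpkm", "ExpressionMatrix",
          function(object) SummarizedExperiment::assay(object, "fpkm"))

#' @rdname ExpressionMatrix
#' @export
setGeneric("sampleConditions",
           function(object) standardGeneric("sampleConditions"))
#' @rdname ExpressionMatrix
#' @export
setMethod("sampleConditions", "ExpressionMatrix", function(object) {
  stats::setNames(SummarizedExperiment::colData(object)$condition,
                  colnames(object))
})

## convenience, internal
txStrand <- function(tx) tx@strand
txChrom <- function(tx) tx@chrom
geneStrand <- function(gene) gene@transcripts[[1L]]@strand
geneChrom <- function(gene) gene@transcripts[[1L]]@chrom
geneSpan <- function(gene) {
  s <- vapply(gene@transcripts, function(t) min(start(t@exons)), integer(1))
  e <- vapply(gene@transcripts, function(t) max(end(t@exons)), integer(1))
  IRanges(min(s), max(e))
}
txSpan <- function(tx) IRanges(min(start(tx@exons)), max(end(tx@exons)))
## transcription start / end in genomic coordinates (strand-aware)
txTss <- function(tx) if (tx@strand == "+") min(start(tx@exons)) else max(end(tx@exons))
txTts <- function(tx) if (tx@strand == "+") max(end(tx@exons)) else min(start(tx@exons))
## introns of one transcript, genomic order
txIntrons <- function(tx) {
  ex <- tx@exons
  if (length(ex) < 2L) return(IRanges())
  IRanges(start = end(ex)[-length(ex)] + 1L, end = start(ex)[-1L] - 1L)
}

## ---- show ------------------------------------------------------------------

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@transcriptId, "(gene", object@geneId, ")\n")
  cat("  ", object@chrom, object@strand, " ", length(object@exons), "exon(s),",
      sum(width(object@exons)), "nt spliced",
      if (!is.na(object@sequence)) "[sequence set]" else "", "\n")
})

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId, "with", length(object@transcripts),
      "transcript(s) on", geneChrom(object), geneStrand(object), "\n")
})

setMethod("show", "DetectabilityResult", function(object) {
  cat("DetectabilityResult:", object@nReps, "replicates, seed",
      object@seed, "\n")
  cat("  mean AS-distinguishable genes:",
      round(mean(object@perReplicate), 3), "(sd",
      round(stats::sd(object@perReplicate), 3), ")\n")
  if (!is.na(object@observed))
    cat("  observed:", object@observed, " ratio:",
        round(mean(object@perReplicate) / object@observed, 2), "\n")
})
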