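## AS event classification against the hypothetical pre-mRNA, and the splice
## junction catalogue. Event vocabulary follows the spliceR convention:
## intron_retention (IR), alt_donor (A5), alt_acceptor (A3), exon_skipping
## (ES), mutually_exclusive_exons (MEE), alt_tss (ATSS), alt_tts (ATTS).

AS_EVENT_TYPES <- c("intron_retention", "alt_donor", "alt_acceptor",
                    "exon_skipping", "mutually_exclusive_exons",
                    "alt_tss", "alt_tts")

#' Hypothetical pre-mRNA of a locus
#'
#' The exon set is the interval union over all isoforms; introns are the
#' complement within the gene span.
#'
#' @param gene a [GeneModel-class]
#' @return list with IRanges elements \code{exons}, \code{introns} and
#'   \code{span}
#' @export
buildPreMrna <- function(gene) {
  allEx <- do.call(c, unname(lapply(gene@transcripts, function(t) t@exons)))
  ex <- reduce(allEx)
  sp <- geneSpan(gene)
  list(exons = ex, introns = gaps(ex, start = start(sp), end = end(sp)),
       span = sp)
}

emptyEventTable <- function() {
  data.frame(gene_id = character(0), event_type = character(0),
             start = integer(0), end = integer(0),
             transcripts = character(0), involves_reference = logical(0),
             stringsAsFactors = FALSE)
}

#' Classify alternative-splicing events of one locus
#'
#' Every pair of isoforms is compared; events are deduplicated by
#' (type, interval) and annotated with the union of involved transcripts.
#' alt_donor/alt_acceptor calls whose differing boundary region is explained
#' by a complete exon of the other isoform inside the intron (an
#' exon-skipping context) are suppressed, as are exon_skipping calls for
#' exons that participate in a mutually-exclusive pair.
#'
#' @param gene a [GeneModel-class]
#' @return data.frame with columns gene_id, event_type, start, end,
#'   transcripts (comma-separated ids), involves_reference
#' @export
classifyASEvents <- function(gene) {
  txs <- gene@transcripts
  if (length(txs) < 2L) return(emptyEventTable())
  strand <- geneStrand(gene)
  ev <- list()
  addEvent <- function(type, s, e, ids) {
    key <- paste(type, s, e, sep = ":")
    if (is.null(ev[[key]]))
      ev[[key]] <<- list(type = type, start = s, end = e, ids = ids)
    else
      ev[[key]]$ids <<- union(ev[[key]]$ids, ids)
  }
  idx <- utils::combn(length(txs), 2L)
  for (k in seq_len(ncol(idx))) {
    A <- txs[[idx[1L, k]]]; B <- txs[[idx[2L, k]]]
    comparePairEvents(A, B, strand, addEvent)
  }
  if (!length(ev)) return(emptyEventTable())
  out <- data.frame(
    gene_id = gene@geneId,
    event_type = vapply(ev, function(x) x$type, character(1)),
    start = vapply(ev, function(x) x$start, integer(1)),
    end = vapply(ev, function(x) x$end, integer(1)),
    transcripts = vapply(ev, function(x)
      paste(sort(x$ids), collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  ## drop exon-skipping events subsumed by a mutually-exclusive pair
  mee <- out[out$event_type == "mutually_exclusive_exons", , drop = FALSE]
  if (nrow(mee)) {
    es <- out$event_type == "exon_skipping"
    inMee <- es & vapply(seq_len(nrow(out)), function(i) {
      any(out$start[i] >= mee$start & out$end[i] <= mee$end)
    }, logical(1))
    out <- out[!inMee, , drop = FALSE]
  }
  ref <- gene@referenceTranscriptId
  out$involves_reference <- if (is.na(ref)) NA else
    vapply(strsplit(out$transcripts, ","), function(x) ref %in% x, logical(1))
  out <- out[order(out$start, out$end, out$event_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## pairwise comparison of two isoforms; reports via the addEvent callback
comparePairEvents <- function(A, B, strand, addEvent) {
  ids <- c(A@transcriptId, B@transcriptId)
  exA <- A@exons; exB <- B@exons
  inA <- txIntrons(A); inB <- txIntrons(B)
  contains <- function(outer_s, outer_e, s, e) outer_s <= s & outer_e >= e

  ## intron retention: an exon of one isoform fully covers an intron of the
  ## other
  for (dir in 1:2) {
    ex <- if (dir == 1L) exA else exB
    itr <- if (dir == 1L) inB else inA
    for (i in seq_along(itr)) {
      hit <- contains(start(ex), end(ex), start(itr)[i], end(itr)[i])
      if (any(hit))
        addEvent("intron_retention", start(itr)[i], end(itr)[i], ids)
    }
  }

  ## exon skipping and mutually exclusive exons (internal exons only)
  internal <- function(ex) if (length(ex) > 2L) ex[-c(1L, length(ex))] else IRanges()
  skA <- skippedExons(internal(exA), inB)
  skB <- skippedExons(internal(exB), inA)
  ## MEE: a skipped exon of A and a skipped exon of B, mutually disjoint
  meePairs <- list()
  if (length(skA) && length(skB)) {
    for (i in seq_along(skA)) for (j in seq_along(skB)) {
      if (end(skA)[i] < start(skB)[j] || end(skB)[j] < start(skA)[i]) {
        addEvent("mutually_exclusive_exons",
                 min(start(skA)[i], start(skB)[j]),
                 max(end(skA)[i], end(skB)[j]), ids)
      }
    }
  }
  for (e in list(skA, skB))
    for (i in seq_along(e))
      addEvent("exon_skipping", start(e)[i], end(e)[i], ids)

  ## alternative donor/acceptor: overlapping intron pairs differing at one or
  ## both boundaries, unless explained by a skipped exon
  if (length(inA) && length(inB)) {
    for (i in seq_along(inA)) for (j in seq_along(inB)) {
      su <- start(inA)[i]; eu <- end(inA)[i]
      sv <- start(inB)[j]; ev_ <- end(inB)[j]
      if (su > ev_ || sv > eu) next            # no overlap
      if (su == sv && eu == ev_) next          # identical intron
      skipCtx <- function(rs, re) {
        ## a complete exon of either isoform inside the other's intron,
        ## overlapping the differing region, explains the boundary shift
        over <- function(ex, os, oe) {
          any(start(ex) >= os & end(ex) <= oe &
              start(ex) <= re & end(ex) >= rs)
        }
        over(exA, sv, ev_) || over(exB, su, eu)
      }
      if (su != sv) {   # left boundaries differ
        rs <- min(su, sv); re <- max(su, sv) - 1L
        type <- if (strand == "+") "alt_donor" else "alt_acceptor"
        if (!skipCtx(rs, re)) addEvent(type, rs, re, ids)
      }
      if (eu != ev_) {  # right boundaries differ
        rs <- min(eu, ev_) + 1L; re <- max(eu, ev_)
        type <- if (strand == "+") "alt_acceptor" else "alt_donor"
        if (!skipCtx(rs, re)) addEvent(type, rs, re, ids)
      }
    }
  }

  ## alternative transcription start / termination
  tssA <- txTss(A); tssB <- txTss(B)
  if (tssA != tssB) {
    if (strand == "+")
      addEvent("alt_tss", min(tssA, tssB), max(tssA, tssB) - 1L, ids)
    else
      addEvent("alt_tss", min(tssA, tssB) + 1L, max(tssA, tssB), ids)
  }
  ttsA <- txTts(A); ttsB <- txTts(B)
  if (ttsA != ttsB) {
    if (strand == "+")
      addEvent("alt_tts", min(ttsA, ttsB) + 1L, max(ttsA, ttsB), ids)
    else
      addEvent("alt_tts", min(ttsA, ttsB), max(ttsA, ttsB) - 1L, ids)
  }
  invisible(NULL)
}

skippedExons <- function(internalExons, introns) {
  if (!length(internalExons) || !length(introns)) return(IRanges())
  keep <- vapply(seq_along(internalExons), function(i) {
    any(start(introns) <= start(internalExons)[i] &
        end(introns) >= end(internalExons)[i])
  }, logical(1))
  internalExons[keep]
}

#' Catalogue the splice junctions of a locus
#'
#' One row per distinct intron across isoforms. A junction is alternative iff
#' it is not used identically by all isoforms whose span covers it, or iff it
#' overlaps/borders an AS event interval. Donor and acceptor dinucleotides
#' are read from the intron ends in transcription orientation.
#'
#' @param gene a [GeneModel-class]
#' @param genome optional DNAStringSet for dinucleotide extraction
#' @param events optional precomputed event table from [classifyASEvents]
#' @return data.frame with columns gene_id, intron_start, intron_end, strand,
#'   donor_pos, acceptor_pos, donor_dinucleotide, acceptor_dinucleotide,
#'   subtype, is_alternative, transcripts
#' @export
catalogueJunctions <- function(gene, genome = NULL, events = NULL) {
  txs <- gene@transcripts
  strand <- geneStrand(gene)
  if (is.null(events)) events <- classifyASEvents(gene)
  keys <- list()
  for (tx in txs) {
    itr <- txIntrons(tx)
    for (i in seq_along(itr)) {
      key <- paste(start(itr)[i], end(itr)[i], sep = ":")
      keys[[key]] <- union(keys[[key]], tx@transcriptId)
    }
  }
  if (!length(keys))
    return(data.frame(gene_id = character(0), intron_start = integer(0),
                      intron_end = integer(0), strand = character(0),
                      donor_pos = integer(0), acceptor_pos = integer(0),
                      donor_dinucleotide = character(0),
                      acceptor_dinucleotide = character(0),
                      subtype = character(0), is_alternative = logical(0),
                      transcripts = character(0), stringsAsFactors = FALSE))
  coords <- do.call(rbind, lapply(strsplit(names(keys), ":"), as.integer))
  s <- coords[, 1L]; e <- coords[, 2L]
  ## alternative iff some isoform spanning the intron does not contain it
  isAlt <- vapply(seq_along(s), function(i) {
    for (tx in txs) {
      sp <- txSpan(tx)
      if (start(sp) <= s[i] && end(sp) >= e[i] &&
          !tx@transcriptId %in% keys[[i]]) return(TRUE)
    }
    FALSE
  }, logical(1))
  ## ... or iff it borders/overlaps an AS event interval
  if (nrow(events)) {
    isAlt <- isAlt | vapply(seq_along(s), function(i) {
      any(events$start <= e[i] + 1L & events$end >= s[i] - 1L)
    }, logical(1))
  }
  donorPos <- if (strand == "+") s else e
  acceptorPos <- if (strand == "+") e else s
  donorDi <- acceptorDi <- rep(NA_character_, length(s))
  if (!is.null(genome)) {
    genome <- asGenome(genome)
    chromSeq <- chromOf(genome, geneChrom(gene))
    for (i in seq_along(s)) {
      if (e[i] - s[i] + 1L < 4L) {
        warning("intron ", s[i], "-", e[i], " of ", gene@geneId,
                " shorter than 4 nt; dinucleotides left unclassified")
        next
      }
      left <- as.character(Biostrings::subseq(chromSeq, s[i], s[i] + 1L))
      right <- as.character(Biostrings::subseq(chromSeq, e[i] - 1L, e[i]))
      if (strand == "+") {
        donorDi[i] <- left; acceptorDi[i] <- right
      } else {
        donorDi[i] <- revcomp(right); acceptorDi[i] <- revcomp(left)
      }
    }
  }
  ord <- order(s, e)
  data.frame(gene_id = gene@geneId, intron_start = s, intron_end = e,
             strand = strand, donor_pos = donorPos,
             acceptor_pos = acceptorPos, donor_dinucleotide = donorDi,
             acceptor_dinucleotide = acceptorDi,
             subtype = "unclassified", is_alternative = isAlt,
             transcripts = vapply(keys, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)[ord, ]
}

#' Filter junctions for spliceosome typing
#'
#' Mirrors the exon-selection exclusions used when typing junctions: first
#' introns (those bordering a first exon of any isoform) and introns retained
#' in some isoform can be dropped.
#'
#' @param junctions output of [catalogueJunctions]
#' @param gene the [GeneModel-class] the junctions came from
#' @param events optional event table from [classifyASEvents]
#' @param dropFirstIntron drop each isoform's first intron in transcription
#'   order
#' @param dropRetained drop junctions of introns retained in another isoform
#' @return filtered junction data.frame
#' @export
filterJunctions <- function(junctions, gene, events = NULL,
                            dropFirstIntron = TRUE, dropRetained = TRUE) {
  keep <- rep(TRUE, nrow(junctions))
  if (dropFirstIntron) {
    strand <- geneStrand(gene)
    firsts <- vapply(gene@transcripts, function(tx) {
      itr <- txIntrons(tx)
      if (!length(itr)) return(NA_character_)
      i <- if (strand == "+") 1L else length(itr)
      paste(start(itr)[i], end(itr)[i], sep = ":")
    }, character(1))
    key <- paste(junctions$intron_start, junctions$intron_end, sep = ":")
    keep <- keep & !key %in% firsts
  }
  if (dropRetained) {
    if (is.null(events)) events <- classifyASEvents(gene)
    ir <- events[events$event_type == "intron_retention", , drop = FALSE]
    if (nrow(ir)) {
      hit <- junctions$intron_start %in% ir$start &
        junctions$intron_end %in% ir$end
      keep <- keep & !hit
    }
  }
  junctions[keep, , drop = FALSE]
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
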