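## ORF prediction, in-silico trypsinolysis, peptide specificity classes and
## mapping of observed peptides back to isoforms.

#' Predict open reading frames on a spliced transcript sequence
#'
#' Scans the three sense frames; within each stop-delimited segment the ORF
#' runs from the first ATG to the stop (or to the transcript end, flagged
#' partial). The longest qualifying ORF is the primary one.
#'
#' @param sequence character(1), transcript sequence 5'->3'
#' @param minLen minimum protein length in amino acids (default 100)
#' @param requireAtg require the ORF to start at ATG (default TRUE); when
#'   FALSE, segments without an ATG are translated from the segment start
#' @return data.frame start, end (1-based nt on the transcript, inclusive,
#'   excluding the stop codon), frame (0..2), protein, utr5_length, partial,
#'   primary; zero rows when nothing qualifies
#' @export
predictOrfs <- function(sequence, minLen = 100L, requireAtg = TRUE) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  out <- list()
  for (frame in 0:2) {
    if (n - frame < 3L) next
    aalen <- (n - frame) %/% 3L
    prot <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::subseq(Biostrings::DNAString(sequence), frame + 1L,
                         frame + aalen * 3L),
      if.fuzzy.codon = "solve")))
    stops <- gregexpr("*", prot, fixed = TRUE)[[1L]]
    bounds <- c(0L, if (stops[1L] != -1L) as.integer(stops), aalen + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      segStart <- bounds[b] + 1L           # aa index
      segEnd <- bounds[b + 1L] - 1L        # aa index of last residue
      if (segEnd < segStart) next
      seg <- substr(prot, segStart, segEnd)
      m <- regexpr("M", seg, fixed = TRUE)
      if (requireAtg) {
        if (m == -1L) next
        aaStart <- segStart + as.integer(m) - 1L
      } else {
        aaStart <- if (m == -1L) segStart else segStart  # translate from segment start
      }
      pep <- substr(prot, aaStart, segEnd)
      if (nchar(pep) < minLen) next
      ntStart <- frame + (aaStart - 1L) * 3L + 1L
      ntEnd <- frame + segEnd * 3L
      partial <- bounds[b + 1L] > aalen    # segment ran off the 3' end
      out[[length(out) + 1L]] <- data.frame(
        start = ntStart, end = ntEnd, frame = frame, protein = pep,
        utr5_length = ntStart - 1L, partial = partial,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), protein = character(0),
                      utr5_length = integer(0), partial = logical(0),
                      primary = logical(0), stringsAsFactors = FALSE))
  tab <- do.call(rbind, out)
  tab <- tab[order(-nchar(tab$protein), tab$start), , drop = FALSE]
  tab$primary <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  tab
}

#' Build the ORF database for a gene catalogue
#'
#' One primary ORF per transcript (transcripts without a qualifying ORF are
#' skipped). Requires sequences to be attached (see [extractSequences]).
#'
#' @param genes list of [GeneModel-class] with transcript sequences set
#' @param minLen,requireAtg passed to [predictOrfs]
#' @return data.frame orf_id, transcript_id, gene_id, protein, utr5_length,
#'   partial
#' @export
orfDatabase <- function(genes, minLen = 100L, requireAtg = TRUE) {
  rows <- list()
  for (g in genes) {
    for (tx in g@transcripts) {
      if (is.na(tx@sequence)) next
      orfs <- predictOrfs(tx@sequence, minLen = minLen,
                          requireAtg = requireAtg)
      if (!nrow(orfs)) next
      o <- orfs[orfs$primary, , drop = FALSE][1L, ]
      rows[[length(rows) + 1L]] <- data.frame(
        orf_id = paste0(tx@transcriptId, ".orf1"),
        transcript_id = tx@transcriptId, gene_id = g@geneId,
        protein = o$protein, utr5_length = o$utr5_length,
        partial = o$partial, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(orf_id = character(0), transcript_id = character(0),
                      gene_id = character(0), protein = character(0),
                      utr5_length = integer(0), partial = logical(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal of K or R except before P (Keil rule) and emits all
#' fully-cleaved fragments plus concatenations with up to \code{maxMissed}
#' missed cleavage sites.
#'
#' @param protein character(1) amino-acid sequence
#' @param maxMissed maximum missed cleavages (default 1)
#' @return data.frame peptide, missed, start (1-based residue position)
#' @export
digestTrypsin <- function(protein, maxMissed = 1L) {
  protein <- toupper(protein)
  n <- nchar(protein)
  if (n == 0L)
    return(data.frame(peptide = character(0), missed = integer(0),
                      start = integer(0), stringsAsFactors = FALSE))
  aa <- strsplit(protein, "")[[1L]]
  ## cut after position i when aa[i] is K/R and the next residue is not P
  cuts <- which(aa %in% c("K", "R"))
  cuts <- cuts[cuts < n & aa[pmin(cuts + 1L, n)] != "P"]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  frags <- substring(protein, starts, ends)
  nf <- length(frags)
  rows <- list()
  for (i in seq_len(nf)) {
    for (mc in 0:maxMissed) {
      j <- i + mc
      if (j > nf) break
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = paste(frags[i:j], collapse = ""), missed = mc,
        start = starts[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## peptide key used for uniqueness comparisons: optional I/L collapsing
## (mass spectrometry cannot distinguish them)
peptideKey <- function(pep, ilEquivalence = TRUE) {
  if (ilEquivalence) chartr("L", "I", pep) else pep
}

#' Classify tryptic peptides by specificity
#'
#' Every ORF is digested (with missed cleavages) and filtered to
#' \code{lengthBounds}; occurrence is exact set membership of the peptide in
#' an ORF's digest. A peptide is \code{isoform_specific} when, after optional
#' I/L collapsing, it occurs in exactly one isoform ORF of exactly one gene;
#' \code{gene_unique_shared} when confined to one gene but several isoforms;
#' \code{multi_gene} otherwise.
#'
#' @param orfDb data.frame from [orfDatabase]
#' @param lengthBounds integer(2), peptide length range kept (default 7..50)
#' @param ilEquivalence treat I and L as indistinguishable (default TRUE)
#' @param maxMissed missed cleavages allowed (default 1)
#' @return data.frame peptide, key, gene_ids, transcript_ids, n_genes,
#'   n_isoforms, specificity
#' @export
classifyPeptides <- function(orfDb, lengthBounds = c(7L, 50L),
                             ilEquivalence = TRUE, maxMissed = 1L) {
  pepGene <- new.env(parent = emptyenv())
  pepTx <- new.env(parent = emptyenv())
  pepSeq <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(orfDb))) {
    dg <- digestTrypsin(orfDb$protein[i], maxMissed = maxMissed)
    len <- nchar(dg$peptide)
    peps <- unique(dg$peptide[len >= lengthBounds[1L] &
                              len <= lengthBounds[2L]])
    keys <- peptideKey(peps, ilEquivalence)
    for (k in seq_along(keys)) {
      key <- keys[k]
      assign(key, c(get0(key, envir = pepGene), orfDb$gene_id[i]),
             envir = pepGene)
      assign(key, c(get0(key, envir = pepTx), orfDb$transcript_id[i]),
             envir = pepTx)
      if (is.null(get0(key, envir = pepSeq)))
        assign(key, peps[k], envir = pepSeq)
    }
  }
  keys <- ls(pepGene)
  if (!length(keys))
    return(data.frame(peptide = character(0), key = character(0),
                      gene_ids = character(0), transcript_ids = character(0),
                      n_genes = integer(0), n_isoforms = integer(0),
                      specificity = character(0), stringsAsFactors = FALSE))
  rows <- lapply(keys, function(key) {
    gs <- unique(get(key, envir = pepGene))
    ts <- unique(get(key, envir = pepTx))
    spec <- if (length(gs) > 1L) "multi_gene"
            else if (length(ts) == 1L) "isoform_specific"
            else "gene_unique_shared"
    data.frame(peptide = get(key, envir = pepSeq), key = key,
               gene_ids = paste(sort(gs), collapse = ","),
               transcript_ids = paste(sort(ts), collapse = ","),
               n_genes = length(gs), n_isoforms = length(ts),
               specificity = spec, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map observed peptides to the peptide database
#'
#' A gene is AS-confirmed at the proteome level iff observed
#' isoform-specific peptides (ISPs) cover at least two distinct isoforms.
#'
#' @param observations data.frame peptide_sequence, sample_id,
#'   spectral_count
#' @param peptideRecords data.frame from [classifyPeptides]
#' @param ilEquivalence must match the setting used for the records
#' @return list: \code{peptides} (per observation, with mapping),
#'   \code{genes} (gene_id, n_peptides, n_isp, isoforms_with_isp, confirmed,
#'   as_confirmed), \code{isoformSpectra} (transcript_id, gene_id,
#'   isp_spectra), \code{n_unmapped}
#' @export
mapObservedPeptides <- function(observations, peptideRecords,
                                ilEquivalence = TRUE) {
  obs <- observations
  obs$key <- peptideKey(toupper(obs$peptide_sequence), ilEquivalence)
  idx <- match(obs$key, peptideRecords$key)
  obs$mapped <- !is.na(idx)
  obs$specificity <- peptideRecords$specificity[idx]
  obs$gene_ids <- peptideRecords$gene_ids[idx]
  obs$transcript_ids <- peptideRecords$transcript_ids[idx]
  nUnmapped <- sum(!obs$mapped)
  if (nUnmapped)
    message(nUnmapped, " observed peptide record(s) not in the database")
  mapped <- obs[obs$mapped, , drop = FALSE]
  oneGene <- mapped[mapped$specificity != "multi_gene", , drop = FALSE]
  geneIds <- unique(oneGene$gene_ids)
  geneRows <- lapply(geneIds, function(g) {
    sub <- oneGene[oneGene$gene_ids == g, , drop = FALSE]
    isp <- sub[sub$specificity == "isoform_specific", , drop = FALSE]
    isoWithIsp <- unique(isp$transcript_ids)
    data.frame(gene_id = g, n_peptides = length(unique(sub$key)),
               n_isp = length(unique(isp$key)),
               isoforms_with_isp = length(isoWithIsp),
               confirmed = TRUE,
               as_confirmed = length(isoWithIsp) >= 2L,
               stringsAsFactors = FALSE)
  })
  genes <- if (length(geneRows)) do.call(rbind, geneRows) else
    data.frame(gene_id = character(0), n_peptides = integer(0),
               n_isp = integer(0), isoforms_with_isp = integer(0),
               confirmed = logical(0), as_confirmed = logical(0),
               stringsAsFactors = FALSE)
  isp <- oneGene[oneGene$specificity == "isoform_specific", , drop = FALSE]
  isoformSpectra <- if (nrow(isp)) {
    agg <- stats::aggregate(spectral_count ~ transcript_ids + gene_ids,
                            data = isp, FUN = sum)
    data.frame(transcript_id = agg$transcript_ids, gene_id = agg$gene_ids,
               isp_spectra = agg$spectral_count, stringsAsFactors = FALSE)
  } else {
    data.frame(transcript_id = character(0), gene_id = character(0),
               isp_spectra = numeric(0), stringsAsFactors = FALSE)
  }
  list(peptides = obs, genes = genes, isoformSpectra = isoformSpectra,
       n_unmapped = nUnmapped)
}

#' Rank correlation between isoform FPKM and ISP spectral counts
#'
#' @param isoformSpectra component of [mapObservedPeptides] output
#' @param expr an [ExpressionMatrix-class]
#' @param condition condition whose mean FPKM is used
#' @return list(rho, n)
#' @export
spectraFpkmCorrelation <- function(isoformSpectra, expr, condition) {
  m <- fpkm(expr)
  conds <- sampleConditions(expr)
  v <- rowMeans(m[, conds == condition, drop = FALSE])
  common <- intersect(isoformSpectra$transcript_id, names(v))
  if (length(common) < 3L) return(list(rho = NA_real_, n = length(common)))
  sp <- isoformSpectra$isp_spectra[match(common,
                                         isoformSpectra$transcript_id)]
  list(rho = suppressWarnings(stats::cor(v[common], sp,
                                         method = "spearman")),
       n = length(common))
}
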