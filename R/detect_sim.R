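## In-silico AS detection experiment: how many genes would show
## proteome-level evidence of >= 2 isoforms if all protein isoforms were
## expressed equally, given the per-gene numbers of peptides actually
## observed.

#' Build per-gene peptide sampling pools
#'
#' The pool of a gene is the multiset concatenation of each isoform's
#' digest (a peptide shared by k isoforms appears k times: equal molar
#' abundance semantics), canonically sorted for seeding. The alternative
#' \code{"distinct"} frame keeps one copy per distinct (peptide, isoform)
#' collapsed to distinct peptides.
#'
#' @param orfDb data.frame from [orfDatabase]
#' @param peptideRecords data.frame from [classifyPeptides] computed on the
#'   same database (provides the specificity classes)
#' @param lengthBounds,ilEquivalence,maxMissed digestion settings; must
#'   match those used for \code{peptideRecords}
#' @param frame \code{"multiset"} (default) or \code{"distinct"}
#' @return named list (by gene) of data.frames key, transcript_id, isp
#' @export
genePeptidePools <- function(orfDb, peptideRecords,
                             lengthBounds = c(7L, 50L),
                             ilEquivalence = TRUE, maxMissed = 1L,
                             frame = c("multiset", "distinct")) {
  frame <- match.arg(frame)
  ispKeys <- peptideRecords$key[peptideRecords$specificity ==
                                "isoform_specific"]
  pools <- list()
  for (g in unique(orfDb$gene_id)) {
    sub <- orfDb[orfDb$gene_id == g, , drop = FALSE]
    entries <- list()
    for (i in seq_len(nrow(sub))) {
      dg <- digestTrypsin(sub$protein[i], maxMissed = maxMissed)
      len <- nchar(dg$peptide)
      peps <- unique(dg$peptide[len >= lengthBounds[1L] &
                                len <= lengthBounds[2L]])
      if (!length(peps)) next
      keys <- peptideKey(peps, ilEquivalence)
      entries[[length(entries) + 1L]] <- data.frame(
        key = keys, transcript_id = sub$transcript_id[i],
        stringsAsFactors = FALSE)
    }
    if (!length(entries)) next
    pool <- do.call(rbind, entries)
    if (frame == "distinct")
      pool <- pool[!duplicated(pool$key), , drop = FALSE]
    pool$isp <- pool$key %in% ispKeys
    pool <- pool[order(pool$key, pool$transcript_id), , drop = FALSE]
    rownames(pool) <- NULL
    pools[[g]] <- pool
  }
  pools
}

#' Resample peptide draws to estimate proteome-level AS detectability
#'
#' Per replicate and per gene, \code{observedCounts[gene]} peptides are drawn
#' uniformly without replacement from the gene's pool; the gene counts as
#' AS-distinguishable when the draw contains isoform-specific peptides from
#' at least two distinct isoforms. Genes observed in MS but with an empty
#' pool are skipped with a message. Reproducible from the seed and invariant
#' to gene ordering (per-gene RNG substreams keyed by a stable hash of the
#' gene id).
#'
#' @param pools output of [genePeptidePools]
#' @param observedCounts named integer vector: observed peptides per gene
#' @param nReps number of replicates (default 100)
#' @param seed integer seed
#' @return a [DetectabilityResult-class]
#' @export
simulateDetection <- function(pools, observedCounts, nReps = 100L,
                              seed = 1L) {
  nReps <- as.integer(nReps)
  if (is.na(nReps) || nReps < 1L) stop("nReps must be >= 1")
  genes <- names(observedCounts)
  missing <- setdiff(genes, names(pools))
  if (length(missing)) {
    message(length(missing),
            " gene(s) with observed peptides but empty pool skipped: ",
            paste(utils::head(missing, 5L), collapse = ", "))
    genes <- setdiff(genes, missing)
  }
  perRep <- integer(nReps)
  perRepAny <- integer(nReps)
  for (r in seq_len(nReps)) {
    nDist <- 0L
    nAny <- 0L
    for (g in genes) {
      pool <- pools[[g]]
      k <- min(observedCounts[[g]], nrow(pool))
      if (k < 1L) next
      drawn <- withSeed(substreamSeed(seed, r, g), {
        sample.int(nrow(pool), k, replace = FALSE)
      })
      hit <- pool$isp[drawn]
      if (any(hit)) {
        nAny <- nAny + 1L
        if (length(unique(pool$transcript_id[drawn][hit])) >= 2L)
          nDist <- nDist + 1L
      }
    }
    perRep[r] <- nDist
    perRepAny[r] <- nAny
  }
  new("DetectabilityResult", perReplicate = perRep,
      perReplicateAny = perRepAny, nReps = nReps, seed = as.integer(seed))
}

## deterministic substream seed from (seed, replicate, gene id)
substreamSeed <- function(seed, rep, geneId) {
  (as.integer(seed) %% 100000L) * 7919L + rep * 104729L + geneHash(geneId)
}

#' Compare simulated detectability with the observed count
#'
#' @param result a [DetectabilityResult-class]
#' @param observed observed number of AS-confirmed genes (e.g. from
#'   [mapObservedPeptides])
#' @param factor fold difference beyond which the verdict reads
#'   "expected >> observed"
#' @return list(mean, sd, observed, ratio, verdict); ratio is NA when
#'   observed is 0
#' @export
compareToObserved <- function(result, observed, factor = 10) {
  m <- mean(result@perReplicate)
  s <- stats::sd(result@perReplicate)
  if (observed > 0) {
    ratio <- m / observed
    verdict <- if (ratio > factor) "expected >> observed"
      else if (ratio > 1) "expected > observed"
      else "expected <= observed"
  } else {
    ratio <- NA_real_
    verdict <- "observed count is zero; ratio undefined"
  }
  list(mean = m, sd = s, observed = observed, ratio = ratio,
       verdict = verdict)
}
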