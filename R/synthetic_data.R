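## Synthetic genomes, gene models, expression, MS observations and lncRNAs
## with planted ground truth. Every generator is a pure function of
## (parameters, seed); outputs are byte-identical across runs.

BASES <- c("A", "C", "G", "T")
SENSE_CODONS <- setdiff(apply(expand.grid(BASES, BASES, BASES), 1L,
                              paste, collapse = ""),
                        c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

randSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

## random sequence free of ATG (used for 5' UTRs so the planted ORF start
## is unambiguous)
randSeqNoAtg <- function(n) {
  s <- randSeq(n)
  while (grepl("ATG", s, fixed = TRUE))
    s <- sub("ATG", paste0("A", sample(c("C", "G"), 1L), "G"), s, fixed = TRUE)
  s
}

## intron with U2 (GT..AG) or U12 (AT-AC) consensus signals matching the
## shipped PPM config
makeIntron <- function(len, subtype = "U2") {
  if (subtype == "U2") {
    core <- len - 20L
    paste0("GTAAGT", randSeq(core), strrep("T", 11L), "CAG")
  } else {
    core <- len - 27L
    paste0("ATATCCTT", randSeq(core), "TTCCTTAAC", randSeq(8L), "AC")
  }
}

## map a local (transcription-orientation) interval to genomic coordinates
## for a gene occupying [off+1, off+L] on its chromosome
mapLocal <- function(off, L, strand, a, b) {
  if (strand == "+") c(off + a, off + b)
  else c(off + L - b + 1L, off + L - a + 1L)
}

#' Generate a synthetic genome and gene catalogue with planted AS events
#'
#' Each gene is built in transcription orientation (5' UTR, a planted ORF of
#' random sense codons, 3' UTR, split over exons with consensus-signal
#' introns) and written onto alternating strands. Genes assigned an AS event
#' type carry exactly one variant isoform differing by that event; event
#' intervals are recorded in the ground-truth registry in genomic
#' coordinates. A deterministic subset of genes is written with U12 (AT-AC)
#' introns.
#'
#' @param nGenes number of genes (default 40)
#' @param eventMix named proportions over event types plus \code{none}
#'   (single-isoform genes); intron retention dominates by default,
#'   mirroring its prevalence in plants
#' @param u12Fraction fraction of genes whose introns carry the U12
#'   consensus (default 0.05)
#' @param genesPerChrom genes per chromosome (default 10)
#' @param intergenic gap between gene loci in nt (default 1500)
#' @param seed integer seed
#' @return list: \code{genome} (DNAStringSet), \code{genes} (named list of
#'   [GeneModel-class] with sequences attached), \code{truth} (events table,
#'   u12 gene ids, per-transcript 5'-UTR lengths, parameters)
#' @export
generateGenomeAndGenes <- function(nGenes = 40L,
                                   eventMix = c(intron_retention = 0.30,
                                                alt_acceptor = 0.15,
                                                alt_donor = 0.15,
                                                exon_skipping = 0.10,
                                                mutually_exclusive_exons = 0.05,
                                                alt_tss = 0.05,
                                                alt_tts = 0.05,
                                                none = 0.15),
                                   u12Fraction = 0.05,
                                   genesPerChrom = 10L, intergenic = 1500L,
                                   seed = 1L) {
  stopifnot(nGenes >= 1L)
  withSeed(seed, {
    types <- apportionTypes(nGenes, eventMix)
    nU12 <- floor(nGenes * u12Fraction)
    u12Genes <- if (nU12 > 0L)
      sprintf("g%03d", unique(round(seq(1L, nGenes, length.out = nU12))))
    else character(0)
    chromSeqs <- list()
    genes <- list()
    events <- list()
    utr5 <- numeric(0)
    for (i in seq_len(nGenes)) {
      gid <- sprintf("g%03d", i)
      strand <- if (i %% 2L == 1L) "+" else "-"
      chromIdx <- (i - 1L) %/% genesPerChrom + 1L
      chrom <- paste0("chr", chromIdx)
      if (length(chromSeqs) < chromIdx) chromSeqs[[chromIdx]] <- randSeq(300L)
      off <- nchar(chromSeqs[[chromIdx]])
      intronType <- if (gid %in% u12Genes) "U12" else "U2"
      gd <- buildGeneLocus(gid, chrom, strand, off, types[i], intronType)
      gseq <- if (strand == "-") revcomp(gd$localSeq) else gd$localSeq
      chromSeqs[[chromIdx]] <- paste0(chromSeqs[[chromIdx]], gseq,
                                      randSeq(intergenic))
      genes[[gid]] <- gd$gene
      utr5 <- c(utr5, gd$utr5)
      if (!is.null(gd$event)) events[[length(events) + 1L]] <- gd$event
    }
    genome <- Biostrings::DNAStringSet(unlist(chromSeqs))
    names(genome) <- paste0("chr", seq_along(chromSeqs))
    eventsTab <- if (length(events)) do.call(rbind, events) else
      data.frame(gene_id = character(0), event_type = character(0),
                 start = integer(0), end = integer(0),
                 stringsAsFactors = FALSE)
    genes <- extractSequences(genes, genome)
    list(genome = genome, genes = genes,
         truth = list(events = eventsTab, u12_genes = u12Genes,
                      utr5 = utr5, types = stats::setNames(types, names(genes)),
                      params = list(nGenes = nGenes, eventMix = eventMix,
                                    u12Fraction = u12Fraction, seed = seed)))
  })
}

## deterministic apportioning of event types to genes
apportionTypes <- function(nGenes, mix) {
  mix <- mix / sum(mix)
  counts <- floor(nGenes * mix)
  rem <- nGenes - sum(counts)
  if (rem > 0L) {
    extra <- order(nGenes * mix - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  rep(names(mix), counts)
}

## build one gene locus in local transcription coordinates; returns the
## local genomic sequence, the GeneModel (genomic coordinates), the planted
## event (genomic) and per-transcript 5'-UTR lengths
buildGeneLocus <- function(gid, chrom, strand, off, type, intronType) {
  utr5len <- sample(40:60, 1L)
  aaLen <- sample(110:200, 1L)
  utr3len <- sample(30:80, 1L)
  orf <- paste0("ATG", paste(sample(SENSE_CODONS, aaLen, replace = TRUE),
                             collapse = ""), sample(STOP_CODONS, 1L))
  spliced <- paste0(randSeqNoAtg(utr5len), orf, randSeq(utr3len))
  S <- nchar(spliced)
  cuts <- round(S * c(0.25, 0.5, 0.75)) + sample(-12:12, 3L)
  ## middle exon (between cuts 1 and 2) kept frame-preserving so event
  ## variants that delete it or its edges make clean deletion proteins
  cuts[2L] <- cuts[1L] + 3L * ((cuts[2L] - cuts[1L]) %/% 3L)
  exLens <- diff(c(0L, cuts, S))
  stopifnot(all(exLens >= 60L))
  intronLens <- sample(80:120, 3L)
  introns <- vapply(intronLens, makeIntron, character(1), subtype = intronType)
  exSeq <- substring(spliced, c(1L, cuts + 1L), c(cuts, S))

  segs <- list()                   # (kind, seq) in transcription order
  for (k in 1:4) {
    segs[[length(segs) + 1L]] <- list(kind = "exon", seq = exSeq[k])
    if (k < 4L) segs[[length(segs) + 1L]] <- list(kind = "intron",
                                                  seq = introns[k])
  }
  extraY <- NULL
  if (type == "mutually_exclusive_exons") {
    ## split intron 2 and insert the alternative exon Y:
    ## e1 i1 e2 i2a Y i2b e3 i3 e4
    Y <- paste(sample(SENSE_CODONS, 30L, replace = TRUE), collapse = "")
    i2a <- makeIntron(80L, intronType)
    i2b <- makeIntron(80L, intronType)
    segs <- c(segs[1:3], list(list(kind = "intron", seq = i2a),
                              list(kind = "exonY", seq = Y),
                              list(kind = "intron", seq = i2b)),
              segs[5:7])
    extraY <- Y
  }
  ## local coordinates of each segment
  lens <- vapply(segs, function(s) nchar(s$seq), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  kinds <- vapply(segs, function(s) s$kind, character(1))
  localSeq <- paste(vapply(segs, function(s) s$seq, character(1)),
                    collapse = "")
  L <- nchar(localSeq)
  exIdx <- which(kinds == "exon")
  ex <- cbind(starts[exIdx], ends[exIdx])     # base isoform exons, local

  iso1 <- ex
  iso2 <- NULL
  eventLocal <- NULL
  if (type == "intron_retention") {
    ## retain intron 2 (between exons 2 and 3)
    iso2 <- rbind(ex[1L, ], c(ex[2L, 1L], ex[3L, 2L]), ex[4L, ])
    eventLocal <- c(ex[2L, 2L] + 1L, ex[3L, 1L] - 1L)
  } else if (type == "alt_donor") {
    d <- 9L
    iso2 <- ex; iso2[2L, 2L] <- iso2[2L, 2L] - d
    eventLocal <- c(ex[2L, 2L] - d + 1L, ex[2L, 2L])
  } else if (type == "alt_acceptor") {
    d <- 9L
    iso2 <- ex; iso2[3L, 1L] <- iso2[3L, 1L] + d
    eventLocal <- c(ex[3L, 1L], ex[3L, 1L] + d - 1L)
  } else if (type == "exon_skipping") {
    iso2 <- ex[-2L, ]
    eventLocal <- c(ex[2L, 1L], ex[2L, 2L])
  } else if (type == "mutually_exclusive_exons") {
    ## iso2 skips exon 2 and uses the alternative exon Y instead
    yIdx <- which(kinds == "exonY")
    yIv <- c(starts[yIdx], ends[yIdx])
    iso2 <- rbind(ex[1L, ], yIv, ex[3:4, ])
    eventLocal <- c(ex[2L, 1L], yIv[2L])
  } else if (type == "alt_tss") {
    t <- 15L
    iso2 <- ex; iso2[1L, 1L] <- iso2[1L, 1L] + t
    eventLocal <- c(ex[1L, 1L], ex[1L, 1L] + t - 1L)
  } else if (type == "alt_tts") {
    t <- 15L
    iso2 <- ex; iso2[nrow(iso2), 2L] <- iso2[nrow(iso2), 2L] - t
    eventLocal <- c(ex[4L, 2L] - t + 1L, ex[4L, 2L])
  }

  toGenomic <- function(m) {
    g <- t(apply(m, 1L, function(r) mapLocal(off, L, strand, r[1L], r[2L])))
    g[order(g[, 1L]), , drop = FALSE]
  }
  t1 <- TranscriptModel(paste0(gid, ".1"), gid, chrom, strand,
                        toGenomic(iso1))
  txs <- list(t1)
  u5 <- stats::setNames(utr5len, paste0(gid, ".1"))
  if (!is.null(iso2)) {
    t2 <- TranscriptModel(paste0(gid, ".2"), gid, chrom, strand,
                          toGenomic(iso2))
    txs <- c(txs, list(t2))
    u5 <- c(u5, stats::setNames(
      if (type == "alt_tss") utr5len - 15L else utr5len,
      paste0(gid, ".2")))
  }
  ev <- NULL
  if (!is.null(eventLocal)) {
    g <- mapLocal(off, L, strand, eventLocal[1L], eventLocal[2L])
    ev <- data.frame(gene_id = gid, event_type = type, start = g[1L],
                     end = g[2L], stringsAsFactors = FALSE)
  }
  list(localSeq = localSeq,
       gene = GeneModel(gid, txs, referenceTranscriptId = paste0(gid, ".1")),
       event = ev, utr5 = u5)
}

#' Generate replicate FPKM data with planted isoform switches and DE genes
#'
#' Condition means are constructed from planted isoform fractions (switch
#' genes swap fractions between conditions so the expected dIF equals
#' \code{targetDif}) and planted gene-level fold changes; replicate noise is
#' mean-preserving lognormal with coefficient of variation \code{noiseCv}
#' (0 = noiseless).
#'
#' @param genes named list of [GeneModel-class]
#' @param conditions character(2) condition names
#' @param replicates replicates per condition (default 5)
#' @param dasGenes gene ids to plant switches in; \code{NULL} picks every
#'   other multi-isoform gene
#' @param targetDif planted |dIF| in percentage points, recycled over
#'   \code{dasGenes} (default c(30, 50, 70))
#' @param deGenes gene ids to plant expression fold changes in; \code{NULL}
#'   picks every fifth gene
#' @param deLog2fc planted |log2 fold change| (default 3)
#' @param noiseCv lognormal coefficient of variation (default 0.2)
#' @param baseFpkm median gene expression level (default 20)
#' @param utr5Effect plant a negative 5'-UTR-length/expression association
#'   instead of switch/DE structure (requires \code{utr5Lengths})
#' @param utr5Lengths named per-transcript 5'-UTR lengths (from the genome
#'   generator truth)
#' @param seed integer seed
#' @return list: \code{expr} ([ExpressionMatrix-class]), \code{truth}
#'   (das/de registries with targets, true condition means)
#' @export
generateExpression <- function(genes, conditions = c("protonema",
                                                     "protoplast"),
                               replicates = 5L, dasGenes = NULL,
                               targetDif = c(30, 50, 70), deGenes = NULL,
                               deLog2fc = 3, noiseCv = 0.2, baseFpkm = 20,
                               utr5Effect = FALSE, utr5Lengths = NULL,
                               seed = 1L) {
  stopifnot(length(conditions) == 2L)
  withSeed(seed, {
    multi <- names(Filter(function(g) length(g@transcripts) > 1L, genes))
    if (is.null(dasGenes))
      dasGenes <- multi[seq_along(multi) %% 2L == 1L]
    dasGenes <- intersect(dasGenes, multi)
    if (is.null(deGenes))
      deGenes <- names(genes)[seq_along(genes) %% 5L == 0L]
    dasTarget <- stats::setNames(rep_len(targetDif, length(dasGenes)),
                                 dasGenes)
    txs <- transcriptIndex(genes)
    txIds <- names(txs)
    mu <- matrix(0, nrow = length(txIds), ncol = 2L,
                 dimnames = list(txIds, conditions))
    for (gi in seq_along(genes)) {
      g <- genes[[gi]]
      ids <- names(g@transcripts)
      ## a fixed total in UTR-effect mode keeps the planted within-gene
      ## monotone signal visible across the whole isoform set
      total <- if (utr5Effect) baseFpkm
        else baseFpkm * exp(stats::rnorm(1L, 0, 0.5))
      tot2 <- total
      if (g@geneId %in% deGenes)
        tot2 <- total * 2^(deLog2fc * if (gi %% 2L == 0L) 1 else -1)
      k <- length(ids)
      if (utr5Effect && !is.null(utr5Lengths)) {
        u <- utr5Lengths[ids]
        w <- exp(-(u - min(u)) / 20)
        f1 <- f2 <- w / sum(w)
      } else if (k == 1L) {
        f1 <- f2 <- 1
      } else if (g@geneId %in% names(dasTarget)) {
        d <- dasTarget[[g@geneId]] / 100
        p <- (1 + d) / 2
        f1 <- c(p, 1 - p, rep(0, k - 2L))
        f2 <- c(1 - p, p, rep(0, k - 2L))
      } else {
        f1 <- f2 <- c(0.6, 0.4, rep(0, k - 2L))[seq_len(k)]
        f1 <- f1 / sum(f1); f2 <- f2 / sum(f2)
      }
      mu[ids, 1L] <- total * f1
      mu[ids, 2L] <- tot2 * f2
    }
    sampleNames <- as.vector(t(outer(conditions, seq_len(replicates),
                                     function(cc, r) paste0(cc, "_r", r))))
    condOf <- rep(conditions, each = replicates)
    names(condOf) <- sampleNames
    m <- matrix(0, nrow = length(txIds), ncol = length(sampleNames),
                dimnames = list(txIds, sampleNames))
    sdlog <- sqrt(log(1 + noiseCv^2))
    for (j in seq_along(sampleNames)) {
      base <- mu[, condOf[j]]
      if (noiseCv > 0) {
        noise <- exp(stats::rnorm(length(base), -sdlog^2 / 2, sdlog))
        m[, j] <- base * noise
      } else m[, j] <- base
    }
    list(expr = ExpressionMatrix(m, condOf),
         truth = list(das = dasTarget, de = deGenes,
                      de_direction = stats::setNames(
                        ifelse(seq_along(genes) %% 2L == 0L, "up", "down"),
                        names(genes))[deGenes],
                      trueMeans = mu,
                      params = list(conditions = conditions,
                                    replicates = replicates,
                                    noiseCv = noiseCv, seed = seed)))
  })
}

#' Sample synthetic MS peptide observations from isoform ORFs
#'
#' Spectra are drawn with probability proportional to isoform abundance
#' times peptide detectability; isoform-specific peptides can be suppressed
#' (\code{ispWeight < 1}) and a dominant-isoform translation mode restricts
#' sampling to each gene's most abundant isoform.
#'
#' @param orfDb data.frame from [orfDatabase]
#' @param records data.frame from [classifyPeptides] on the same database
#' @param abundance named numeric, abundance per transcript (e.g. FPKM)
#' @param nSpectra total spectra to draw (default 3000)
#' @param sampleId sample label for the output table
#' @param ispWeight detectability multiplier for isoform-specific peptides
#'   (default 1; 0 reproduces a proteome blind to isoforms)
#' @param dominantIsoform only the most abundant isoform per gene is
#'   translated (default FALSE)
#' @param detectability function(peptide) -> weight (default constant 1)
#' @param lengthBounds,ilEquivalence,maxMissed digestion settings matching
#'   \code{records}
#' @param seed integer seed
#' @return list: \code{observations} (peptide_sequence, sample_id,
#'   spectral_count), \code{truth} (sampling parameters)
#' @export
generateMsObservations <- function(orfDb, records, abundance,
                                   nSpectra = 3000L, sampleId = "MS1",
                                   ispWeight = 1, dominantIsoform = FALSE,
                                   detectability = NULL,
                                   lengthBounds = c(7L, 50L),
                                   ilEquivalence = TRUE, maxMissed = 1L,
                                   seed = 1L) {
  withSeed(seed, {
    ispKeys <- records$key[records$specificity == "isoform_specific"]
    cand <- list()
    for (i in seq_len(nrow(orfDb))) {
      tx <- orfDb$transcript_id[i]
      ab <- if (tx %in% names(abundance)) abundance[[tx]] else 0
      if (dominantIsoform) {
        sub <- orfDb[orfDb$gene_id == orfDb$gene_id[i], "transcript_id"]
        abs_ <- vapply(sub, function(t)
          if (t %in% names(abundance)) abundance[[t]] else 0, numeric(1))
        if (tx != sub[which.max(abs_)]) ab <- 0
      }
      if (ab <= 0) next
      dg <- digestTrypsin(orfDb$protein[i], maxMissed = maxMissed)
      len <- nchar(dg$peptide)
      peps <- unique(dg$peptide[len >= lengthBounds[1L] &
                                len <= lengthBounds[2L]])
      if (!length(peps)) next
      keys <- peptideKey(peps, ilEquivalence)
      w <- rep(ab, length(peps))
      if (!is.null(detectability))
        w <- w * vapply(peps, detectability, numeric(1))
      w[keys %in% ispKeys] <- w[keys %in% ispKeys] * ispWeight
      cand[[length(cand) + 1L]] <- data.frame(peptide = peps, weight = w,
                                              stringsAsFactors = FALSE)
    }
    if (!length(cand))
      return(list(observations = data.frame(peptide_sequence = character(0),
                                            sample_id = character(0),
                                            spectral_count = integer(0)),
                  truth = list(seed = seed)))
    tab <- do.call(rbind, cand)
    tab <- stats::aggregate(weight ~ peptide, data = tab, FUN = sum)
    tab <- tab[order(tab$peptide), , drop = FALSE]
    obs <- if (sum(tab$weight) > 0) {
      draws <- sample(tab$peptide, nSpectra, replace = TRUE,
                      prob = tab$weight)
      cnt <- table(draws)
      data.frame(peptide_sequence = names(cnt), sample_id = sampleId,
                 spectral_count = as.integer(cnt),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(peptide_sequence = character(0), sample_id = character(0),
                 spectral_count = integer(0), stringsAsFactors = FALSE)
    }
    list(observations = obs,
         truth = list(nSpectra = nSpectra, ispWeight = ispWeight,
                      dominantIsoform = dominantIsoform, seed = seed))
  })
}

#' Generate lncRNAs with planted complementarity sites
#'
#' Intergenic lncRNAs are written into the intergenic gaps of the genome and
#' carry planted antiparallel complementary windows (reverse complement of
#' the target region, with an optional fraction of G:U wobble
#' substitutions) against chosen exonic, intronic or junction-spanning
#' positions of target pre-mRNAs. cis-NAT lncRNAs are antisense transcripts
#' overlapping a gene locus.
#'
#' @param sim output of [generateGenomeAndGenes]
#' @param nLnc number of lncRNAs (default 6)
#' @param siteSpecs data.frame gene_id, region ("exonic", "intronic",
#'   "junction"), length, wobble; \code{NULL} plants one junction site in
#'   each of the first three genes
#' @param nCisNat how many of the lncRNAs are cis-NATs (default 2)
#' @param lncLength lncRNA length in nt (default 500)
#' @param seed integer seed
#' @return list: \code{genome} (modified), \code{lncrnas} (list of
#'   [TranscriptModel-class] with sequences), \code{truth} (planted sites
#'   and classes)
#' @export
generateLncrnas <- function(sim, nLnc = 6L, siteSpecs = NULL, nCisNat = 2L,
                            lncLength = 500L, seed = 1L) {
  withSeed(seed, {
    seqs <- as.character(sim$genome)      # character space for appending
    genes <- sim$genes
    if (is.null(siteSpecs)) {
      tg <- utils::head(names(genes), 3L)
      siteSpecs <- data.frame(gene_id = tg, region = "junction",
                              length = 40L, wobble = 0,
                              stringsAsFactors = FALSE)
    }
    nPlanted <- nrow(siteSpecs)
    stopifnot(nLnc >= nPlanted + nCisNat)
    lncs <- list()
    sites <- list()
    classes <- character(0)
    appendChrL <- function(lseq) {
      ## intergenic lncRNA loci live on a dedicated chromosome
      if (!"chrL" %in% names(seqs)) seqs["chrL"] <<- randSeq(400L)
      offL <- nchar(seqs[["chrL"]])
      seqs[["chrL"]] <<- paste0(seqs[["chrL"]], lseq, randSeq(100L))
      offL
    }
    for (i in seq_len(nLnc)) {
      lid <- sprintf("lnc%02d", i)
      if (i <= nPlanted) {
        spec <- siteSpecs[i, ]
        gene <- genes[[spec$gene_id]]
        tw <- targetWindow(gene, spec$region, spec$length)
        preSeq <- preMrnaSequence(gene, sim$genome)
        twSeq <- substr(preSeq, tw$pre[1L], tw$pre[2L])
        seg <- plantWobbles(revcomp(twSeq), twSeq, spec$wobble)
        insertAt <- 200L
        lseq <- paste0(randSeq(insertAt), seg,
                       randSeq(lncLength - insertAt - nchar(seg)))
        offL <- appendChrL(lseq)
        tx <- TranscriptModel(lid, lid, "chrL", "+",
                              cbind(offL + 1L, offL + nchar(lseq)),
                              sequence = lseq)
        classes[lid] <- "intergenic"
        sites[[length(sites) + 1L]] <- data.frame(
          lncrna_id = lid, gene_id = spec$gene_id, region = spec$region,
          wobble = spec$wobble,
          lnc_start = insertAt + 1L, lnc_end = insertAt + nchar(seg),
          pre_start = tw$pre[1L], pre_end = tw$pre[2L],
          g_start = tw$genomic[1L], g_end = tw$genomic[2L],
          stringsAsFactors = FALSE)
      } else if (i <= nPlanted + nCisNat) {
        ## antisense overlap with a gene locus
        gene <- genes[[(i %% length(genes)) + 1L]]
        sp <- geneSpan(gene)
        a <- start(sp) + 20L
        b <- min(end(sp), a + lncLength - 1L)
        anti <- if (geneStrand(gene) == "+") "-" else "+"
        raw <- substr(seqs[[geneChrom(gene)]], a, b)
        lseq <- if (anti == "-") revcomp(raw) else raw
        tx <- TranscriptModel(lid, lid, geneChrom(gene), anti,
                              cbind(a, b), sequence = lseq)
        classes[lid] <- "cis_NAT"
      } else {
        ## plain intergenic lncRNA, no planted site
        lseq <- randSeq(lncLength)
        offL <- appendChrL(lseq)
        tx <- TranscriptModel(lid, lid, "chrL", "+",
                              cbind(offL + 1L, offL + nchar(lseq)),
                              sequence = lseq)
        classes[lid] <- "intergenic"
      }
      lncs[[lid]] <- tx
    }
    genome <- Biostrings::DNAStringSet(seqs)
    sitesTab <- if (length(sites)) do.call(rbind, sites) else
      data.frame(lncrna_id = character(0), gene_id = character(0),
                 region = character(0), wobble = numeric(0),
                 lnc_start = integer(0), lnc_end = integer(0),
                 pre_start = integer(0), pre_end = integer(0),
                 g_start = integer(0), g_end = integer(0),
                 stringsAsFactors = FALSE)
    list(genome = genome, lncrnas = lncs,
         truth = list(sites = sitesTab, classes = classes,
                      params = list(nLnc = nLnc, seed = seed)))
  })
}

## choose a target window (pre-mRNA and genomic coordinates) in the
## requested context of a gene
targetWindow <- function(gene, region, len) {
  ## windows are chosen on the union (pre-mRNA) structure so that planted
  ## "intronic" sites do not fall into introns retained by some isoform
  pre <- buildPreMrna(gene)
  stopifnot(length(pre$introns) >= 1L)
  pick <- function(rs) rs[min(2L, length(rs))]
  iv <- if (region == "exonic") {
    e <- pick(pre$exons[width(pre$exons) >= len + 10L])
    mid <- (start(e) + end(e)) %/% 2L
    c(mid - len %/% 2L, mid - len %/% 2L + len - 1L)
  } else if (region == "intronic") {
    i2 <- pick(pre$introns[width(pre$introns) >= len + 10L])
    mid <- (start(i2) + end(i2)) %/% 2L
    c(mid - len %/% 2L, mid - len %/% 2L + len - 1L)
  } else {                         # junction: centre on the donor boundary
    i2 <- pick(pre$introns)
    b <- if (geneStrand(gene) == "+") start(i2) else end(i2)
    c(b - len %/% 2L, b - len %/% 2L + len - 1L)
  }
  preIv <- sort(premrnaCoord(gene, iv))
  list(genomic = iv, pre = preIv)
}

## wobble substitutions: where the target (tw) base is G the paired base
## C -> T, where it is T the paired base A -> G; `seg` pairs antiparallel so
## seg position j faces tw position (n - j + 1)
plantWobbles <- function(seg, tw, frac) {
  if (frac <= 0) return(seg)
  n <- nchar(seg)
  segc <- strsplit(seg, "")[[1L]]
  twc <- strsplit(tw, "")[[1L]]
  eligible <- which(rev(twc) %in% c("G", "T"))
  k <- floor(frac * length(eligible))
  if (k < 1L) return(seg)
  pick <- sort(sample(eligible, k))
  for (j in pick) {
    t_ <- rev(twc)[j]
    segc[j] <- if (t_ == "G") "T" else "G"
  }
  paste(segc, collapse = "")
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper producing genome, gene models, replicate expression,
#' MS observations and lncRNAs (with expression rows appended for them) in
#' one call, together with the merged ground-truth registry.
#'
#' @param nGenes,seed,noiseCv,replicates main knobs; everything else uses
#'   the stage defaults
#' @param msMode \code{"equal"} (abundance-proportional),
#'   \code{"suppressed"} (isoform-specific peptides undetectable) or
#'   \code{"dominant"} (only the major isoform translated)
#' @param withLnc generate lncRNAs and planted interaction sites
#' @return list: genome, genes, expr, orfDb, peptideRecords, observations,
#'   lncrnas, truth
#' @export
generateDataset <- function(nGenes = 40L, seed = 1L, noiseCv = 0.2,
                            replicates = 5L,
                            msMode = c("equal", "suppressed", "dominant"),
                            withLnc = TRUE) {
  msMode <- match.arg(msMode)
  sim <- generateGenomeAndGenes(nGenes = nGenes, seed = seed)
  lnc <- NULL
  if (withLnc) {
    lnc <- generateLncrnas(sim, seed = seed + 1L)
    sim$genome <- lnc$genome
  }
  ex <- generateExpression(sim$genes, replicates = replicates,
                           noiseCv = noiseCv, seed = seed + 2L)
  expr <- ex$expr
  if (withLnc) {
    ## append lncRNA FPKM rows: planted-site lncRNAs track their target
    ## gene's expression (co-regulation), the rest are flat
    m <- fpkm(expr)
    conds <- sampleConditions(expr)
    lrows <- matrix(0, nrow = length(lnc$lncrnas), ncol = ncol(m),
                    dimnames = list(names(lnc$lncrnas), colnames(m)))
    st <- lnc$truth$sites
    withSeed(seed + 3L, {
      for (i in seq_len(nrow(lrows))) {
        lid <- rownames(lrows)[i]
        j <- match(lid, st$lncrna_id)
        if (!is.na(j)) {
          target <- names(sim$genes[[st$gene_id[j]]]@transcripts)[1L]
          lrows[i, ] <- 0.5 * m[target, ] + 0.01
        } else {
          lrows[i, ] <- exp(stats::rnorm(ncol(m), log(2), 0.3))
        }
      }
    })
    expr <- ExpressionMatrix(rbind(m, lrows), conds)
  }
  genes <- extractSequences(sim$genes, sim$genome)
  orfDb <- orfDatabase(genes)
  records <- classifyPeptides(orfDb)
  abundance <- rowMeans(fpkm(expr))[orfDb$transcript_id]
  names(abundance) <- orfDb$transcript_id
  ms <- switch(msMode,
    equal = generateMsObservations(orfDb, records, abundance,
                                   seed = seed + 4L),
    suppressed = generateMsObservations(orfDb, records, abundance,
                                        ispWeight = 0, seed = seed + 4L),
    dominant = generateMsObservations(orfDb, records, abundance,
                                      dominantIsoform = TRUE,
                                      seed = seed + 4L))
  list(genome = sim$genome, genes = genes, expr = expr, orfDb = orfDb,
       peptideRecords = records, observations = ms$observations,
       lncrnas = if (withLnc) lnc$lncrnas else NULL,
       truth = c(sim$truth, list(expression = ex$truth, ms = ms$truth,
                                 lnc = if (withLnc) lnc$truth else NULL)))
}

#' Write a synthetic dataset to disk
#'
#' Emits genome.fa, genes.gtf, expression.tsv, peptides.tsv, lncrnas.gtf
#' and ground_truth.yaml under \code{dir}.
#'
#' @param dataset output of [generateDataset]
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(dataset$genome, file.path(dir, "genome.fa"))
  writeGeneModels(dataset$genes, file.path(dir, "genes.gtf"))
  writeExpression(dataset$expr, file.path(dir, "expression.tsv"))
  utils::write.table(dataset$observations, file.path(dir, "peptides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$lncrnas)) {
    lncGenes <- lapply(dataset$lncrnas, function(tx)
      GeneModel(tx@geneId, list(tx)))
    writeGeneModels(lncGenes, file.path(dir, "lncrnas.gtf"))
  }
  yaml::write_yaml(truthToYaml(dataset$truth),
                   file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}

## YAML-friendly view of the registry: data.frames become column lists and
## named atomic vectors become maps (write_yaml drops vector names)
truthToYaml <- function(x) {
  if (is.data.frame(x) || is.list(x)) lapply(x, truthToYaml)
  else if (is.atomic(x) && !is.null(names(x))) as.list(x)
  else x
}
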