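## lncRNA candidate filtering, cis-NAT classification, antiparallel RNA-RNA
## complementarity search under the wobble-aware pairing matrix, site context
## classification, junction enrichment and expression correlation.

#' The RNA-RNA pairing score scheme
#'
#' G:C = +4, A:T = +2, G:T (wobble) = +1, all other pairs -6; a gap of
#' length k costs gapOpen + k * gapExtend.
#'
#' @param gapOpen gap opening cost (default 20)
#' @param gapExtend per-base gap extension cost (default 8)
#' @return list with \code{matrix} (5x5 over A,C,G,T,N), \code{gapOpen},
#'   \code{gapExtend}
#' @export
pairingScheme <- function(gapOpen = 20, gapExtend = 8) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(-6, 5L, 5L, dimnames = list(ab, ab))
  m["G", "C"] <- m["C", "G"] <- 4
  m["A", "T"] <- m["T", "A"] <- 2
  m["G", "T"] <- m["T", "G"] <- 1
  m[, "N"] <- m["N", ] <- -1000          # masked positions never align
  list(matrix = m, gapOpen = gapOpen, gapExtend = gapExtend)
}

#' Find complementarity sites between one lncRNA and one target RNA
#'
#' Models antiparallel hybridization: the lncRNA is reversed (not
#' complemented) and locally aligned to the target under the pairing matrix
#' with affine gaps; a perfect antiparallel duplex therefore scores through
#' the G:C/A:T/G:T entries directly. All non-overlapping locally optimal
#' sites with score >= \code{minScore} and alignment length >= \code{minLen}
#' are reported (iterative masking of the target), sorted by score.
#' Coordinates are 1-based inclusive on each molecule's native 5'->3'
#' orientation.
#'
#' @param lncSeq,targetSeq character(1) sequences, 5'->3'
#' @param scheme a [pairingScheme] result
#' @param minScore minimum alignment score (default 100, the score of a
#'   perfect 25-bp G:C duplex)
#' @param minLen minimum alignment length in columns (default 25)
#' @param convention \code{"antiparallel"} (default) or \code{"parallel"}
#'   (no reversal, for comparison)
#' @param maxSites safety cap on reported sites per pair
#' @return data.frame lnc_start, lnc_end, target_start, target_end, score,
#'   length
#' @export
alignDuplex <- function(lncSeq, targetSeq, scheme = pairingScheme(),
                        minScore = 100, minLen = 25,
                        convention = c("antiparallel", "parallel"),
                        maxSites = 50L) {
  convention <- match.arg(convention)
  empty <- data.frame(lnc_start = integer(0), lnc_end = integer(0),
                      target_start = integer(0), target_end = integer(0),
                      score = numeric(0), length = integer(0),
                      stringsAsFactors = FALSE)
  if (!nchar(lncSeq) || !nchar(targetSeq)) return(empty)
  L <- nchar(lncSeq)
  q <- if (convention == "antiparallel") reverseString(lncSeq) else lncSeq
  qd <- Biostrings::DNAString(q)
  target <- targetSeq
  rows <- list()
  for (iter in seq_len(maxSites)) {
    pa <- Biostrings::pairwiseAlignment(
      qd, Biostrings::DNAString(target), type = "local",
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gapOpen, gapExtension = scheme$gapExtend)
    sc <- Biostrings::score(pa)
    if (sc < minScore) break
    pat <- Biostrings::pattern(pa)
    sub <- Biostrings::subject(pa)
    ts <- Biostrings::start(sub); te <- Biostrings::end(sub)
    alnLen <- nchar(as.character(pat))     # alignment columns
    qs <- Biostrings::start(pat); qe <- Biostrings::end(pat)
    if (alnLen >= minLen) {
      if (convention == "antiparallel") {
        ls_ <- L - qe + 1L; le_ <- L - qs + 1L
      } else {
        ls_ <- qs; le_ <- qe
      }
      rows[[length(rows) + 1L]] <- data.frame(
        lnc_start = ls_, lnc_end = le_, target_start = ts,
        target_end = te, score = sc, length = alnLen,
        stringsAsFactors = FALSE)
    }
    ## mask the aligned target stretch and look for the next site
    substr(target, ts, te) <- strrep("N", te - ts + 1L)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$target_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

reverseString <- function(x)
  paste(rev(strsplit(x, "")[[1L]]), collapse = "")

#' Filter lncRNA candidates
#'
#' Keeps transcripts longer than 200 nt, expressed at FPKM >= \code{minFpkm}
#' in at least one condition, without a long ORF (the coding-potential
#' stand-in), and of an eligible assembly class (intergenic "u", antisense
#' "x", same-strand novel "s").
#'
#' @param candidates list of [TranscriptModel-class] with sequences set
#' @param expr an [ExpressionMatrix-class] covering the candidates
#' @param classCodes named character vector (by transcript id) of assembly
#'   class codes; missing ids are treated as "u"
#' @param minLength minimum length, exclusive (default 200 nt)
#' @param minFpkm FPKM threshold (default 0.5)
#' @param maxOrfCodons candidates with an ORF of at least this many codons
#'   are considered coding (default 100)
#' @return data.frame transcript_id, length, max_fpkm, longest_orf_codons,
#'   class_code, keep, reason
#' @export
filterLncrnaCandidates <- function(candidates, expr, classCodes = NULL,
                                   minLength = 200L, minFpkm = 0.5,
                                   maxOrfCodons = 100L) {
  m <- fpkm(expr)
  conds <- sampleConditions(expr)
  condMax <- vapply(rownames(m), function(t)
    max(vapply(unique(conds), function(cc)
      mean(m[t, conds == cc]), numeric(1))), numeric(1))
  rows <- lapply(candidates, function(tx) {
    id <- tx@transcriptId
    len <- sum(width(tx@exons))
    maxF <- if (id %in% names(condMax)) condMax[[id]] else 0
    orfs <- if (!is.na(tx@sequence))
      predictOrfs(tx@sequence, minLen = 1L) else NULL
    longestOrf <- if (!is.null(orfs) && nrow(orfs))
      max(nchar(orfs$protein)) else 0L
    cls <- if (!is.null(classCodes) && id %in% names(classCodes))
      classCodes[[id]] else "u"
    reason <- character(0)
    if (len <= minLength) reason <- c(reason, "short")
    if (maxF < minFpkm) reason <- c(reason, "low_fpkm")
    if (longestOrf >= maxOrfCodons) reason <- c(reason, "coding_potential")
    if (!cls %in% c("u", "x", "s")) reason <- c(reason, "annotated_class")
    data.frame(transcript_id = id, length = len, max_fpkm = maxF,
               longest_orf_codons = longestOrf, class_code = cls,
               keep = !length(reason),
               reason = paste(reason, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify lncRNAs as cis-NAT, same-strand novel, or intergenic
#'
#' cis-NAT: genomic overlap of >= 1 nt with a protein-coding locus on the
#' opposite strand.
#'
#' @param lncTranscripts list of [TranscriptModel-class]
#' @param genes list of [GeneModel-class] (the protein-coding catalogue)
#' @return data.frame transcript_id, class, overlapped_genes
#' @export
classifyCisNat <- function(lncTranscripts, genes) {
  gchrom <- vapply(genes, geneChrom, character(1))
  gstrand <- vapply(genes, geneStrand, character(1))
  gspan <- do.call(rbind, lapply(genes, function(g) {
    sp <- geneSpan(g); c(start(sp), end(sp))
  }))
  gids <- vapply(genes, geneId, character(1))
  rows <- lapply(lncTranscripts, function(tx) {
    sp <- txSpan(tx)
    hit <- gchrom == tx@chrom & gspan[, 1L] <= end(sp) &
      gspan[, 2L] >= start(sp)
    anti <- gids[hit & gstrand != tx@strand]
    same <- gids[hit & gstrand == tx@strand]
    cls <- if (length(anti)) "cis_NAT"
      else if (length(same)) "same_strand_novel"
      else "intergenic"
    data.frame(transcript_id = tx@transcriptId, class = cls,
               overlapped_genes = paste(sort(anti), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## transcription-oriented pre-mRNA coordinate of a genomic position
premrnaCoord <- function(gene, gpos) {
  sp <- geneSpan(gene)
  if (geneStrand(gene) == "+") gpos - start(sp) + 1L
  else end(sp) - gpos + 1L
}

#' Classify interaction sites by their pre-mRNA context
#'
#' A site is \code{junction_spanning} when its target interval covers at
#' least one exon-intron boundary of the locus, \code{exonic} when fully
#' inside the union-exon structure, \code{intronic} otherwise;
#' \code{spans_alternative_junction} is TRUE when a covered boundary belongs
#' to an alternative junction.
#'
#' @param sites data.frame with target_start, target_end in pre-mRNA
#'   coordinates (transcription orientation, as produced by [alignDuplex]
#'   against [preMrnaSequence])
#' @param gene the target [GeneModel-class]
#' @param junctions junction catalogue of the gene ([catalogueJunctions])
#' @return sites with site_class and spans_alternative_junction added
#' @export
classifySite <- function(sites, gene, junctions) {
  pre <- buildPreMrna(gene)
  sites$site_class <- NA_character_
  sites$spans_alternative_junction <- FALSE
  if (!nrow(sites)) return(sites)
  ## boundary b sits between pre-mRNA positions b and b+1 (transcription
  ## coords); a site covers it iff it contains both
  bounds <- junctionBoundaries(gene, junctions)
  for (i in seq_len(nrow(sites))) {
    a <- sites$target_start[i]; b <- sites$target_end[i]
    cov <- bounds$pos >= a & bounds$pos + 1L <= b
    if (any(cov)) {
      sites$site_class[i] <- "junction_spanning"
      sites$spans_alternative_junction[i] <- any(bounds$alt[cov])
    } else {
      g <- premrnaToGenomic(gene, a, b)
      inExon <- any(start(pre$exons) <= g[1L] & end(pre$exons) >= g[2L])
      sites$site_class[i] <- if (inExon) "exonic" else "intronic"
    }
  }
  sites
}

## exon|intron boundaries in pre-mRNA coordinates, with alternative flags
junctionBoundaries <- function(gene, junctions) {
  if (!nrow(junctions)) return(data.frame(pos = integer(0), alt = logical(0)))
  pos <- integer(0); alt <- logical(0)
  for (i in seq_len(nrow(junctions))) {
    s <- junctions$intron_start[i]; e <- junctions$intron_end[i]
    ## boundary between s-1|s and e|e+1 (genomic); convert each side pair
    p1 <- sort(premrnaCoord(gene, c(s - 1L, s)))[1L]
    p2 <- sort(premrnaCoord(gene, c(e, e + 1L)))[1L]
    pos <- c(pos, p1, p2)
    alt <- c(alt, rep(junctions$is_alternative[i], 2L))
  }
  data.frame(pos = pos, alt = alt)
}

premrnaToGenomic <- function(gene, a, b) {
  sp <- geneSpan(gene)
  if (geneStrand(gene) == "+")
    c(start(sp) + a - 1L, start(sp) + b - 1L)
  else
    sort(c(end(sp) - a + 1L, end(sp) - b + 1L))
}

#' Enrichment of interactions at alternative splice junctions
#'
#' Builds the 2x2 table {alternative, constitutive} x {interacted, not
#' interacted} over all junctions and returns the two-sided Fisher exact
#' p-value and the odds ratio (Haldane 0.5 correction when a cell is zero).
#'
#' @param junctions junction catalogue (possibly concatenated over genes)
#'   with is_alternative
#' @param interacted logical vector: was each junction covered by >= 1
#'   interaction site
#' @return list(table, odds_ratio, p)
#' @export
junctionEnrichment <- function(junctions, interacted) {
  stopifnot(nrow(junctions) == length(interacted))
  tab <- matrix(c(
    sum(junctions$is_alternative & interacted),
    sum(junctions$is_alternative & !interacted),
    sum(!junctions$is_alternative & interacted),
    sum(!junctions$is_alternative & !interacted)), 2L, 2L, byrow = TRUE,
    dimnames = list(c("alternative", "constitutive"),
                    c("interacted", "not_interacted")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    return(list(table = tab, odds_ratio = NA_real_, p = NA_real_))
  h <- if (any(tab == 0L)) tab + 0.5 else tab
  or <- (h[1L, 1L] * h[2L, 2L]) / (h[1L, 2L] * h[2L, 1L])
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p = p)
}

## which junctions are covered by >= 1 site (per gene)
junctionsInteracted <- function(junctions, sites, gene) {
  if (!nrow(junctions)) return(logical(0))
  out <- logical(nrow(junctions))
  if (!nrow(sites)) return(out)
  for (i in seq_len(nrow(junctions))) {
    s <- junctions$intron_start[i]; e <- junctions$intron_end[i]
    p1 <- sort(premrnaCoord(gene, c(s - 1L, s)))[1L]
    p2 <- sort(premrnaCoord(gene, c(e, e + 1L)))[1L]
    out[i] <- any((sites$target_start <= p1 & sites$target_end >= p1 + 1L) |
                  (sites$target_start <= p2 & sites$target_end >= p2 + 1L))
  }
  out
}

#' Spearman correlation of lncRNA and target expression across samples
#'
#' Average-rank ties; exact permutation p (all n! orderings) for n <= 8
#' samples, random permutations otherwise. Pairs passing rho >
#' \code{minRho} and p < \code{maxP} are flagged co-regulated. A warning is
#' raised when so few samples are available that the exact p cannot reach
#' \code{maxP}.
#'
#' @param pairs data.frame with columns lncrna_id, target_id (transcript
#'   ids present in \code{expr})
#' @param expr an [ExpressionMatrix-class]
#' @param minRho co-regulation threshold on rho (default 0.8)
#' @param maxP co-regulation threshold on p (default 0.05)
#' @param nPerm random permutations when n > 8
#' @param seed RNG seed for the random fallback
#' @return pairs with n, rho, p, co_regulated added
#' @export
correlatePairs <- function(pairs, expr, minRho = 0.8, maxP = 0.05,
                           nPerm = 1000L, seed = 1L) {
  m <- fpkm(expr)
  n <- ncol(m)
  pairs$n <- NA_integer_; pairs$rho <- NA_real_; pairs$p <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$lncrna_id[i]; b <- pairs$target_id[i]
    if (!a %in% rownames(m) || !b %in% rownames(m)) next
    x <- m[a, ]; y <- m[b, ]
    pairs$n[i] <- n
    if (n < 3L) next
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      message("constant expression vector for pair ", a, " / ", b,
              "; rho undefined")
      next
    }
    rho <- stats::cor(x, y, method = "spearman")
    pairs$rho[i] <- rho
    pairs$p[i] <- spearmanPermutationP(x, y, rho, nPerm = nPerm,
                                       seed = seed + i)
  }
  smallN <- stats::na.omit(unique(pairs$n))
  if (length(smallN) && any(factorial(smallN) < 1 / maxP))
    warning("with ", min(smallN), " samples the exact permutation p cannot ",
            "fall below ", signif(1 / factorial(min(smallN)), 3),
            "; co-regulation cannot reach p < ", maxP)
  pairs$co_regulated <- !is.na(pairs$rho) & !is.na(pairs$p) &
    pairs$rho > minRho & pairs$p < maxP
  pairs
}

## two-sided permutation p for Spearman rho; exact for n <= 8
spearmanPermutationP <- function(x, y, rho, nPerm = 1000L, seed = 1L) {
  n <- length(x)
  if (n <= 8L) {
    perms <- allPermutations(n)
    stats_ <- apply(perms, 1L, function(ix)
      stats::cor(x, y[ix], method = "spearman"))
    mean(abs(stats_) >= abs(rho) - 1e-12)
  } else {
    withSeed(seed, {
      stats_ <- replicate(nPerm, stats::cor(x, sample(y),
                                            method = "spearman"))
      mean(abs(stats_) >= abs(rho) - 1e-12)
    })
  }
}

allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[j, ]])
    }
  }
  out
}

#' Fraction of interaction sites shared between two site sets
#'
#' Site identity: same lncRNA, same target gene, and target-interval overlap
#' of >= 1 nt. Reports |shared| / |union| plus the per-group exclusives.
#'
#' @param sitesA,sitesB data.frames with lncrna_id, target_gene, g_start,
#'   g_end (genomic interval on the target locus)
#' @return list(shared_fraction, n_shared, n_only_a, n_only_b)
#' @export
commonSiteFraction <- function(sitesA, sitesB) {
  matchIn <- function(x, yset) {
    vapply(seq_len(nrow(x)), function(i) {
      any(yset$lncrna_id == x$lncrna_id[i] &
          yset$target_gene == x$target_gene[i] &
          yset$g_start <= x$g_end[i] & yset$g_end >= x$g_start[i])
    }, logical(1))
  }
  if (!nrow(sitesA) && !nrow(sitesB))
    return(list(shared_fraction = NA_real_, n_shared = 0L,
                n_only_a = 0L, n_only_b = 0L))
  ma <- if (nrow(sitesA)) matchIn(sitesA, sitesB) else logical(0)
  mb <- if (nrow(sitesB)) matchIn(sitesB, sitesA) else logical(0)
  nShared <- sum(ma)
  union <- nrow(sitesA) + nrow(sitesB) - nShared
  list(shared_fraction = if (union > 0) nShared / union else NA_real_,
       n_shared = nShared, n_only_a = sum(!ma), n_only_b = sum(!mb))
}
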