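## Isoform fractions, dIF, sqrt-Jensen-Shannon switch scores, differential
## alternative splicing (DAS) and differential expression (DE) calls, and the
## 5'-UTR-length vs expression association.

#' Per-condition isoform fractions (IF)
#'
#' IF of isoform t in condition c is 100 * FPKM_t,c / sum of its gene's
#' isoform FPKM in c, computed on condition-mean FPKM across replicate
#' samples. Genes with zero FPKM in a condition get NA (undefined), not 0.
#'
#' @param expr an [ExpressionMatrix-class]
#' @param genes list of [GeneModel-class] (defines the transcript -> gene
#'   grouping)
#' @return data.frame transcript_id, gene_id, condition, gene_fpkm,
#'   isoform_fpkm, IF (percent)
#' @export
isoformFractions <- function(expr, genes) {
  m <- fpkm(expr)
  conds <- sampleConditions(expr)
  map <- txGeneMap(genes)
  keep <- rownames(m) %in% names(map)
  m <- m[keep, , drop = FALSE]
  condMeans <- vapply(unique(conds), function(cc)
    rowMeans(m[, conds == cc, drop = FALSE]), numeric(nrow(m)))
  if (is.null(dim(condMeans)))
    condMeans <- matrix(condMeans, nrow = nrow(m),
                        dimnames = list(rownames(m), unique(conds)))
  gid <- unname(map[rownames(m)])
  out <- do.call(rbind, lapply(colnames(condMeans), function(cc) {
    v <- condMeans[, cc]
    tot <- tapply(v, gid, sum)[gid]
    data.frame(transcript_id = rownames(m), gene_id = gid, condition = cc,
               gene_fpkm = as.numeric(tot), isoform_fpkm = as.numeric(v),
               IF = ifelse(tot > 0, 100 * v / tot, NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Delta isoform fraction between two conditions
#'
#' dIF = IF(contrast) - IF(reference), in percentage points. Isoforms with an
#' undefined IF on either side are skipped (with a message).
#'
#' @param ifTable output of [isoformFractions]
#' @param conditionPair character(2): (reference, contrast)
#' @return data.frame transcript_id, gene_id, IF_ref, IF_contrast, dIF
#' @export
computeDif <- function(ifTable, conditionPair) {
  stopifnot(length(conditionPair) == 2L)
  a <- ifTable[ifTable$condition == conditionPair[1L], ]
  b <- ifTable[ifTable$condition == conditionPair[2L], ]
  if (!nrow(a) || !nrow(b))
    stop("condition(s) not present in the IF table: ",
         paste(setdiff(conditionPair, ifTable$condition), collapse = ", "))
  merged <- merge(a[, c("transcript_id", "gene_id", "IF")],
                  b[, c("transcript_id", "IF")],
                  by = "transcript_id", suffixes = c("_ref", "_contrast"))
  bad <- is.na(merged$IF_ref) | is.na(merged$IF_contrast)
  if (any(bad))
    message(sum(bad), " isoform(s) skipped: IF undefined in one condition")
  merged <- merged[!bad, , drop = FALSE]
  merged$dIF <- merged$IF_contrast - merged$IF_ref
  rownames(merged) <- NULL
  merged[, c("transcript_id", "gene_id", "IF_ref", "IF_contrast", "dIF")]
}

#' Isoform-switch score: square root of the Jensen-Shannon divergence
#'
#' JSD is computed with base-2 logarithms on the two isoform-fraction
#' vectors renormalised to sum 1, so the score lies in [0, 1].
#'
#' @param p,q non-negative isoform-fraction vectors of the same gene
#' @return numeric(1) in [0, 1], or NA for a zero-sum vector
#' @export
switchScore <- function(p, q) {
  if (sum(p) <= 0 || sum(q) <= 0) {
    message("switchScore: zero-sum fraction vector; returning NA")
    return(NA_real_)
  }
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  sqrt(max(0, entropy2(m) - (entropy2(p) + entropy2(q)) / 2))
}

entropy2 <- function(x) {
  x <- x[x > 0]
  -sum(x * log2(x))
}

#' Call differentially alternatively spliced (DAS) genes
#'
#' A gene is DAS when its sqrt-JSD switch score between the two conditions is
#' significant (permutation test over replicate condition labels,
#' Benjamini-Hochberg FDR) and at least one isoform moves by more than
#' \code{difThreshold} percentage points of isoform fraction. Without
#' replicates (one sample per condition) only the dIF threshold applies and
#' the result is marked \code{mode = "threshold-only"}.
#'
#' @param expr an [ExpressionMatrix-class]
#' @param genes list of [GeneModel-class]
#' @param conditionPair character(2): (reference, contrast)
#' @param difThreshold dIF threshold in percentage points (default 20)
#' @param fdr BH false-discovery-rate cutoff (default 0.05)
#' @param maxExact maximum number of label assignments to enumerate
#'   exhaustively; larger designs fall back to \code{nPerm} random draws
#' @param nPerm random permutations when not exhaustive
#' @param seed RNG seed for the random-permutation fallback
#' @return list with \code{genes} (gene_id, jsd, p, padj, max_abs_dif, das),
#'   \code{isoforms} (the dIF table plus das_flag) and \code{mode}
#' @export
callDas <- function(expr, genes, conditionPair, difThreshold = 20,
                    fdr = 0.05, maxExact = 10000L, nPerm = 1000L, seed = 1L) {
  m <- fpkm(expr)
  conds <- sampleConditions(expr)
  sel <- conds %in% conditionPair
  m <- m[, sel, drop = FALSE]
  conds <- conds[sel]
  map <- txGeneMap(genes)
  ifTab <- isoformFractions(expr, genes)
  difTab <- computeDif(ifTab, conditionPair)
  n1 <- sum(conds == conditionPair[1L])
  n2 <- sum(conds == conditionPair[2L])
  hasReps <- n1 > 1L || n2 > 1L
  multi <- names(Filter(function(g) length(g@transcripts) > 1L, genes))
  geneRows <- lapply(multi, function(g) {
    txids <- intersect(names(genes[[g]]@transcripts), rownames(m))
    if (length(txids) < 2L) return(NULL)
    sub <- m[txids, , drop = FALSE]
    obs <- jsdBetweenLabels(sub, conds, conditionPair)
    p <- NA_real_
    if (hasReps && !is.na(obs)) {
      p <- permutationPvalue(sub, conds, conditionPair, obs,
                             maxExact = maxExact, nPerm = nPerm,
                             seed = seed + geneHash(g) %% 100000L)
    }
    data.frame(gene_id = g, jsd = obs, p = p, stringsAsFactors = FALSE)
  })
  geneTab <- do.call(rbind, geneRows)
  if (is.null(geneTab))
    geneTab <- data.frame(gene_id = character(0), jsd = numeric(0),
                          p = numeric(0))
  geneTab$padj <- stats::p.adjust(geneTab$p, method = "BH")
  maxDif <- tapply(abs(difTab$dIF), difTab$gene_id, max)
  geneTab$max_abs_dif <- as.numeric(maxDif[geneTab$gene_id])
  geneTab$max_abs_dif[is.na(geneTab$max_abs_dif)] <- 0
  if (hasReps) {
    geneTab$das <- !is.na(geneTab$padj) & geneTab$padj < fdr &
      geneTab$max_abs_dif > difThreshold
    mode <- "permutation"
  } else {
    geneTab$das <- geneTab$max_abs_dif > difThreshold
    mode <- "threshold-only"
  }
  dasGenes <- geneTab$gene_id[geneTab$das]
  difTab$das_flag <- difTab$gene_id %in% dasGenes &
    abs(difTab$dIF) > difThreshold
  list(genes = geneTab, isoforms = difTab, mode = mode)
}

## sqrt-JSD between condition-mean fraction vectors of one gene
jsdBetweenLabels <- function(sub, labels, pair) {
  p <- rowMeans(sub[, labels == pair[1L], drop = FALSE])
  q <- rowMeans(sub[, labels == pair[2L], drop = FALSE])
  if (sum(p) <= 0 || sum(q) <= 0) return(NA_real_)
  suppressMessages(switchScore(p, q))
}

## permutation p-value for the observed sqrt-JSD; exhaustive over label
## assignments when the design is small enough
permutationPvalue <- function(sub, labels, pair, obs, maxExact, nPerm, seed) {
  n <- length(labels)
  n1 <- sum(labels == pair[1L])
  nAssign <- choose(n, n1)
  stats <- if (nAssign <= maxExact) {
    apply(utils::combn(n, n1), 2L, function(ix) {
      lab <- rep(pair[2L], n); lab[ix] <- pair[1L]
      jsdBetweenLabels(sub, lab, pair)
    })
  } else {
    withSeed(seed, {
      replicate(nPerm, {
        lab <- sample(labels)
        jsdBetweenLabels(sub, lab, pair)
      })
    })
  }
  stats <- stats[!is.na(stats)]
  if (!length(stats)) return(NA_real_)
  mean(stats >= obs - 1e-12)
}

#' Call differentially expressed (DE) genes by fold change
#'
#' Gene FPKM (sum over isoforms, condition means) is clamped at \code{floor}
#' before the log-ratio; genes below the floor in both conditions are
#' excluded. DE iff |log2(FPKM_contrast / FPKM_ref)| > \code{lfc}.
#'
#' @param expr an [ExpressionMatrix-class]
#' @param genes list of [GeneModel-class]
#' @param conditionPair character(2): (reference, contrast)
#' @param floor FPKM floor (default 0.2)
#' @param lfc log2 fold-change threshold (default 2)
#' @return data.frame gene_id, fpkm_ref, fpkm_contrast, log2fc, de, direction
#' @export
callDe <- function(expr, genes, conditionPair, floor = 0.2, lfc = 2) {
  m <- fpkm(expr)
  conds <- sampleConditions(expr)
  map <- txGeneMap(genes)
  keep <- rownames(m) %in% names(map)
  m <- m[keep, , drop = FALSE]
  gid <- unname(map[rownames(m)])
  gm <- function(cc) {
    v <- rowMeans(m[, conds == cc, drop = FALSE])
    tapply(v, gid, sum)
  }
  a <- gm(conditionPair[1L]); b <- gm(conditionPair[2L])
  keepG <- !(a < floor & b < floor)
  a <- pmax(a[keepG], floor); b <- pmax(b[keepG], floor)
  l2 <- log2(b / a)
  data.frame(gene_id = names(a), fpkm_ref = as.numeric(a),
             fpkm_contrast = as.numeric(b), log2fc = as.numeric(l2),
             de = abs(l2) > lfc,
             direction = ifelse(l2 > 0, "up", ifelse(l2 < 0, "down", "none")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Association between 5'-UTR length and isoform expression
#'
#' Spearman rank correlation (average ranks for ties) between 5'-UTR length
#' and FPKM across isoforms, with a permutation p-value, reported per
#' condition.
#'
#' @param utr5 named numeric vector of 5'-UTR lengths (nt) per transcript
#' @param expr an [ExpressionMatrix-class]
#' @param nPerm number of permutations for the p-value
#' @param seed RNG seed
#' @return data.frame condition, n, rho, p
#' @export
utr5ExpressionAssociation <- function(utr5, expr, nPerm = 1000L, seed = 1L) {
  m <- fpkm(expr)
  conds <- sampleConditions(expr)
  common <- intersect(names(utr5), rownames(m))
  if (length(common) < 3L)
    stop("need >= 3 transcripts with both UTR length and expression")
  out <- do.call(rbind, lapply(unique(conds), function(cc) {
    v <- rowMeans(m[common, conds == cc, drop = FALSE])
    u <- utr5[common]
    if (stats::sd(v) == 0 || stats::sd(u) == 0)
      ## all ranks tied on one side: no monotone association
      return(data.frame(condition = cc, n = length(common), rho = 0,
                        p = 1, stringsAsFactors = FALSE))
    rho <- suppressWarnings(stats::cor(u, v, method = "spearman"))
    p <- withSeed(seed, {
      perm <- replicate(nPerm, suppressWarnings(
        stats::cor(u, sample(v), method = "spearman")))
      mean(abs(perm) >= abs(rho) - 1e-12)
    })
    data.frame(condition = cc, n = length(common), rho = rho, p = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## run expr with a local RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## stable, platform-independent hash of an id string
geneHash <- function(id) {
  h <- 0L
  for (c in utf8ToInt(id)) h <- (h * 131L + c) %% 2147483647L
  h
}
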