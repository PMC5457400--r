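## Position-probability-matrix scoring of splice-site motifs, used to type
## junctions as U2- (major) or U12- (minor) spliceosome dependent.

#' Load position-probability matrices from a YAML config
#'
#' The config carries one matrix per motif (U2_donor, U2_acceptor, U12_donor,
#' U12_branch). Each matrix is a list of per-position probability rows over
#' A/C/G/T; rows are renormalised and floored at \code{epsilon} on load.
#'
#' @param path YAML file; defaults to the matrices shipped with the package
#'   (plant U2 GT-AG and U12 AT-AC consensus)
#' @return list with \code{epsilon} and a \code{matrices} list; every matrix
#'   is 4 x L with rownames A,C,G,T and an \code{offset} attribute (window
#'   position of the first column relative to the splice site)
#' @export
loadPPM <- function(path = system.file("extdata", "ppm_default.yaml",
                                       package = "spliceomics")) {
  cfg <- yaml::read_yaml(path)
  eps <- if (is.null(cfg$epsilon)) 0.01 else cfg$epsilon
  mats <- lapply(cfg$matrices, function(m) {
    rows <- vapply(m$positions, function(p)
      c(A = p$A, C = p$C, G = p$G, T = p$T), numeric(4))
    rows <- pmax(rows, eps)
    rows <- sweep(rows, 2L, colSums(rows), "/")
    attr(rows, "offset") <- m$offset
    rows
  })
  list(epsilon = eps, matrices = mats)
}

#' Log-odds score of a sequence window against a PPM
#'
#' score = sum over positions of log2(p(base)/0.25); ambiguous bases (e.g. N)
#' contribute 0.
#'
#' @param window character(1), length must equal the PPM window
#' @param ppm a 4 x L probability matrix with rownames A,C,G,T
#' @return numeric(1), bits
#' @export
scorePPM <- function(window, ppm) {
  bases <- strsplit(toupper(window), "")[[1L]]
  if (length(bases) != ncol(ppm))
    stop("window length ", length(bases), " != PPM length ", ncol(ppm))
  s <- 0
  for (i in seq_along(bases)) {
    b <- bases[i]
    if (b %in% rownames(ppm)) s <- s + log2(ppm[[b, i]] / 0.25)
  }
  unname(s)
}

## transcription-oriented window around a splice boundary.
## side "donor": boundary = first intron base; window spans `upstream` exonic
## bases then (len - upstream) intronic bases. side "acceptor": boundary =
## last intron base; window spans `upstream` intronic bases then the rest
## exonic. Returns NA when out of chromosome bounds.
junctionWindow <- function(chromSeq, strand, intronStart, intronEnd,
                           side, upstream, len) {
  if (side == "donor") {
    if (strand == "+") { gs <- intronStart - upstream }
    else { gs <- intronEnd + upstream - len + 1L }
  } else {
    if (strand == "+") { gs <- intronEnd - upstream + 1L }
    else { gs <- intronStart + upstream - len }
  }
  ge <- gs + len - 1L
  if (gs < 1L || ge > length(chromSeq)) return(NA_character_)
  w <- as.character(Biostrings::subseq(chromSeq, gs, ge))
  if (strand == "-") w <- revcomp(w)
  w
}

## oriented intron sequence (5'->3' in transcription order)
orientedIntron <- function(chromSeq, strand, s, e) {
  if (s < 1L || e > length(chromSeq)) return(NA_character_)
  x <- as.character(Biostrings::subseq(chromSeq, s, e))
  if (strand == "-") revcomp(x) else x
}

#' Type splice junctions as U2- or U12-dependent
#'
#' For each junction the U2 score is donor + acceptor PPM score and the U12
#' score is donor + the best branch-point window scanned over -40..-10
#' upstream of the acceptor; the larger wins, ties go to U2 (the dominant
#' spliceosome), and junctions where both scores fall below \code{floor} or
#' whose sequence is unavailable stay unclassified.
#'
#' @param junctions data.frame from [catalogueJunctions]
#' @param gene the corresponding [GeneModel-class]
#' @param genome DNAStringSet (or FASTA path)
#' @param ppms result of [loadPPM]
#' @param floor minimum bit score to accept a classification
#' @return the junction data.frame with \code{subtype}, \code{u2_score} and
#'   \code{u12_score} filled in
#' @export
classifyJunctionSubtype <- function(junctions, gene, genome,
                                    ppms = loadPPM(), floor = 0) {
  if (!nrow(junctions)) {
    junctions$u2_score <- numeric(0)
    junctions$u12_score <- numeric(0)
    return(junctions)
  }
  genome <- asGenome(genome)
  chromSeq <- chromOf(genome, geneChrom(gene))
  strand <- geneStrand(gene)
  m <- ppms$matrices
  u2 <- u12 <- rep(NA_real_, nrow(junctions))
  subtype <- rep("unclassified", nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    s <- junctions$intron_start[i]; e <- junctions$intron_end[i]
    dWin2 <- junctionWindow(chromSeq, strand, s, e, "donor",
                            -attr(m$U2_donor, "offset"), ncol(m$U2_donor))
    aWin2 <- junctionWindow(chromSeq, strand, s, e, "acceptor",
                            -attr(m$U2_acceptor, "offset"),
                            ncol(m$U2_acceptor))
    dWin12 <- junctionWindow(chromSeq, strand, s, e, "donor",
                             -attr(m$U12_donor, "offset"), ncol(m$U12_donor))
    iseq <- orientedIntron(chromSeq, strand, s, e)
    if (is.na(dWin2) || is.na(aWin2) || is.na(dWin12) || is.na(iseq)) next
    u2[i] <- scorePPM(dWin2, m$U2_donor) + scorePPM(aWin2, m$U2_acceptor)
    u12[i] <- scorePPM(dWin12, m$U12_donor) +
      branchScan(iseq, m$U12_branch)
    if (max(u2[i], u12[i]) < floor) next
    subtype[i] <- if (u12[i] > u2[i]) "U12" else "U2"
  }
  junctions$subtype <- subtype
  junctions$u2_score <- u2
  junctions$u12_score <- u12
  junctions
}

## best branch-point window within -40..-10 of the acceptor (intron 3' end)
branchScan <- function(intronSeq, branchPpm) {
  w <- nchar(intronSeq)
  L <- ncol(branchPpm)
  lo <- max(1L, w - 40L + 1L)
  hi <- w - 10L - L + 1L
  if (hi < lo) return(-Inf)
  best <- -Inf
  for (o in lo:hi) {
    sc <- scorePPM(substr(intronSeq, o, o + L - 1L), branchPpm)
    if (sc > best) best <- sc
  }
  best
}
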