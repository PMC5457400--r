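## Independent oracles used to cross-check the package implementations.
## These deliberately avoid the code paths (and data structures) of the
## package: plain integer matrices and loops instead of IRanges, regexes
## instead of position scans, textbook DP instead of pairwiseAlignment.

## ---- brute-force AS event comparator --------------------------------------
## Exons given as a list (per transcript) of 2-column matrices (start, end),
## 1-based closed, genomic order. Returns a sorted key set
## "type:start:end". Definitions mirror the documented classification rules.
oracleEventKeys <- function(exonList, strand) {
  introns <- lapply(exonList, function(ex) {
    if (nrow(ex) < 2L) return(matrix(numeric(0), 0, 2))
    cbind(ex[-nrow(ex), 2] + 1, ex[-1, 1] - 1)
  })
  tss <- vapply(exonList, function(ex)
    if (strand == "+") min(ex[, 1]) else max(ex[, 2]), numeric(1))
  tts <- vapply(exonList, function(ex)
    if (strand == "+") max(ex[, 2]) else min(ex[, 1]), numeric(1))
  keys <- character(0)
  add <- function(type, s, e) keys <<- c(keys, paste(type, s, e, sep = ":"))
  n <- length(exonList)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    exA <- exonList[[i]]; exB <- exonList[[j]]
    inA <- introns[[i]]; inB <- introns[[j]]
    ## intron retention
    for (dir in 1:2) {
      ex <- if (dir == 1) exA else exB
      itr <- if (dir == 1) inB else inA
      if (nrow(itr)) for (k in seq_len(nrow(itr)))
        for (m in seq_len(nrow(ex)))
          if (ex[m, 1] <= itr[k, 1] && ex[m, 2] >= itr[k, 2])
            add("intron_retention", itr[k, 1], itr[k, 2])
    }
    ## skipped internal exons
    skipped <- function(ex, itr) {
      out <- matrix(numeric(0), 0, 2)
      if (nrow(ex) > 2 && nrow(itr)) {
        for (m in 2:(nrow(ex) - 1)) {
          for (k in seq_len(nrow(itr)))
            if (itr[k, 1] <= ex[m, 1] && itr[k, 2] >= ex[m, 2]) {
              out <- rbind(out, ex[m, , drop = FALSE]); break
            }
        }
      }
      out
    }
    skA <- skipped(exA, inB); skB <- skipped(exB, inA)
    meeIv <- matrix(numeric(0), 0, 2)
    if (nrow(skA) && nrow(skB)) {
      for (a in seq_len(nrow(skA))) for (b in seq_len(nrow(skB))) {
        if (skA[a, 2] < skB[b, 1] || skB[b, 2] < skA[a, 1]) {
          iv <- c(min(skA[a, 1], skB[b, 1]), max(skA[a, 2], skB[b, 2]))
          add("mutually_exclusive_exons", iv[1], iv[2])
          meeIv <- rbind(meeIv, iv)
        }
      }
    }
    for (sk in list(skA, skB)) {
      if (nrow(sk)) for (a in seq_len(nrow(sk)))
        add("exon_skipping", sk[a, 1], sk[a, 2])
    }
    ## alternative donors/acceptors with skipped-exon suppression
    if (nrow(inA) && nrow(inB)) {
      for (u in seq_len(nrow(inA))) for (v in seq_len(nrow(inB))) {
        su <- inA[u, 1]; eu <- inA[u, 2]; sv <- inB[v, 1]; ev <- inB[v, 2]
        if (su > ev || sv > eu) next
        if (su == sv && eu == ev) next
        ctx <- function(rs, re) {
          hasExonIn <- function(ex, os, oe) {
            any(ex[, 1] >= os & ex[, 2] <= oe & ex[, 1] <= re & ex[, 2] >= rs)
          }
          hasExonIn(exA, sv, ev) || hasExonIn(exB, su, eu)
        }
        if (su != sv) {
          rs <- min(su, sv); re <- max(su, sv) - 1
          if (!ctx(rs, re))
            add(if (strand == "+") "alt_donor" else "alt_acceptor", rs, re)
        }
        if (eu != ev) {
          rs <- min(eu, ev) + 1; re <- max(eu, ev)
          if (!ctx(rs, re))
            add(if (strand == "+") "alt_acceptor" else "alt_donor", rs, re)
        }
      }
    }
    if (tss[i] != tss[j]) {
      a <- min(tss[i], tss[j]); b <- max(tss[i], tss[j])
      if (strand == "+") add("alt_tss", a, b - 1) else add("alt_tss", a + 1, b)
    }
    if (tts[i] != tts[j]) {
      a <- min(tts[i], tts[j]); b <- max(tts[i], tts[j])
      if (strand == "+") add("alt_tts", a + 1, b) else add("alt_tts", a, b - 1)
    }
  }
  keys <- unique(keys)
  ## drop exon_skipping subsumed by a mutually-exclusive pair
  parts <- strsplit(keys, ":")
  mee <- Filter(function(p) p[1] == "mutually_exclusive_exons", parts)
  if (length(mee)) {
    drop <- vapply(parts, function(p) {
      p[1] == "exon_skipping" &&
        any(vapply(mee, function(m)
          as.numeric(p[2]) >= as.numeric(m[2]) &&
          as.numeric(p[3]) <= as.numeric(m[3]), logical(1)))
    }, logical(1))
    keys <- keys[!drop]
  }
  sort(keys)
}

## event keys from the package's classifier output
eventKeysOf <- function(events) {
  sort(unique(paste(events$event_type, events$start, events$end, sep = ":")))
}

## ---- random gene models for property tests --------------------------------
## base structure plus 1-3 derived isoforms obtained by random structural
## edits; guarantees model invariants (sorted, disjoint, gap >= 1)
randomGeneModel <- function(gid = "gX", nIso = sample(2:4, 1),
                            strand = sample(c("+", "-"), 1)) {
  nEx <- sample(3:5, 1)
  exLen <- sample(60:150, nEx, replace = TRUE)
  inLen <- sample(50:120, nEx - 1, replace = TRUE)
  starts <- cumsum(c(100, head(exLen, -1) + inLen))
  base <- cbind(starts, starts + exLen - 1)
  isoforms <- list(base)
  for (k in seq_len(nIso - 1)) {
    ex <- base
    nEdits <- sample(1:2, 1)
    for (e in seq_len(nEdits)) {
      op <- sample(c("ir", "skip", "donor", "acceptor", "tss", "tts"), 1)
      if (op == "ir" && nrow(ex) >= 2) {
        i <- sample(nrow(ex) - 1, 1)
        ex <- rbind(ex[seq_len(i - 1), , drop = FALSE],
                    c(ex[i, 1], ex[i + 1, 2]),
                    ex[-seq_len(i + 1), , drop = FALSE])
      } else if (op == "skip" && nrow(ex) >= 3) {
        i <- sample(2:(nrow(ex) - 1), 1)
        ex <- ex[-i, , drop = FALSE]
      } else if (op == "donor" && nrow(ex) >= 2) {
        i <- sample(nrow(ex) - 1, 1)
        d <- sample(3:15, 1)
        if (ex[i, 2] - d > ex[i, 1]) ex[i, 2] <- ex[i, 2] - d
      } else if (op == "acceptor" && nrow(ex) >= 2) {
        i <- sample(2:nrow(ex), 1)
        d <- sample(3:15, 1)
        if (ex[i, 1] + d < ex[i, 2]) ex[i, 1] <- ex[i, 1] + d
      } else if (op == "tss") {
        d <- sample(3:20, 1)
        if (ex[1, 1] + d < ex[1, 2]) ex[1, 1] <- ex[1, 1] + d
      } else if (op == "tts") {
        d <- sample(3:20, 1)
        if (ex[nrow(ex), 2] - d > ex[nrow(ex), 1]) {
          ex[nrow(ex), 2] <- ex[nrow(ex), 2] - d
        }
      }
    }
    isoforms[[k + 1]] <- ex
  }
  txs <- lapply(seq_along(isoforms), function(i)
    TranscriptModel(paste0(gid, ".", i), gid, "chr1", strand,
                    isoforms[[i]]))
  list(gene = GeneModel(gid, txs), exonList = isoforms, strand = strand)
}

## ---- tryptic digestion via regex ------------------------------------------
oracleDigest <- function(protein, maxMissed = 1) {
  frags <- strsplit(gsub("(?<=[KR])(?!P)", "|", protein,
                         perl = TRUE), "|", fixed = TRUE)[[1]]
  out <- character(0)
  for (i in seq_along(frags)) {
    for (mc in 0:maxMissed) {
      if (i + mc > length(frags)) break
      out <- c(out, paste(frags[i:(i + mc)], collapse = ""))
    }
  }
  out
}

## ---- exhaustive peptide specificity ---------------------------------------
## recomputes digests per ORF and scans all ORFs for every peptide
oracleSpecificity <- function(orfDb, bounds = c(7, 50), il = TRUE,
                              maxMissed = 1) {
  digests <- lapply(seq_len(nrow(orfDb)), function(i) {
    d <- unique(oracleDigest(orfDb$protein[i], maxMissed))
    d <- d[nchar(d) >= bounds[1] & nchar(d) <= bounds[2]]
    if (il) chartr("L", "I", d) else d
  })
  allPep <- sort(unique(unlist(digests)))
  res <- vapply(allPep, function(p) {
    holders <- which(vapply(digests, function(d) p %in% d, logical(1)))
    gs <- unique(orfDb$gene_id[holders])
    ts <- unique(orfDb$transcript_id[holders])
    if (length(gs) > 1) "multi_gene"
    else if (length(ts) == 1) "isoform_specific"
    else "gene_unique_shared"
  }, character(1))
  res
}

## ---- affine-gap local alignment (Gotoh) ------------------------------------
## returns only the optimal score; gap of length k costs open + k * ext
oracleLocalAlign <- function(q, s, mat, open = 20, ext = 8) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  M <- matrix(0, n + 1, m + 1)      # match state
  X <- matrix(-Inf, n + 1, m + 1)   # gap in subject (query consumed)
  Y <- matrix(-Inf, n + 1, m + 1)   # gap in query
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      sub <- mat[qc[i - 1], sc[j - 1]]
      M[i, j] <- max(0,
                     max(M[i - 1, j - 1], X[i - 1, j - 1],
                         Y[i - 1, j - 1]) + sub)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

## ---- two-sided Fisher exact p by hypergeometric enumeration ----------------
oracleFisherP <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, r1, n - r1, c1),
                  numeric(1))
  pObs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## random DNA/protein helpers for property tests
randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
randomProtein <- function(n) paste(sample(strsplit(
  "ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE), collapse = "")
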