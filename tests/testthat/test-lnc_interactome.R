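rcStr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

test_that("the pairing scheme carries the published scores", {
  sch <- pairingScheme()
  m <- sch$matrix
  expect_equal(m["G", "C"], 4); expect_equal(m["C", "G"], 4)
  expect_equal(m["A", "T"], 2); expect_equal(m["T", "A"], 2)
  expect_equal(m["G", "T"], 1); expect_equal(m["T", "G"], 1)
  expect_equal(m["A", "A"], -6); expect_equal(m["A", "G"], -6)
  expect_true(isSymmetric(m[1:4, 1:4]))
  expect_equal(sch$gapOpen, 20); expect_equal(sch$gapExtend, 8)
})

test_that("perfect antiparallel duplexes score 4 per G:C pair", {
  target <- strrep("G", 25)
  lnc <- rcStr(target)                       # CCC... (25 C)
  s <- alignDuplex(lnc, target)
  expect_equal(nrow(s), 1L)
  expect_equal(s$score, 100)
  expect_equal(s$length, 25L)
  expect_equal(c(s$target_start, s$target_end), c(1L, 25L))
  # poly-A against poly-A never pairs
  expect_equal(nrow(alignDuplex(strrep("A", 30), strrep("A", 30),
                                minScore = 1, minLen = 5)), 0L)
  # wobble-only pairing: 10 G:U pairs score 10, below the default floor
  expect_equal(nrow(alignDuplex(strrep("G", 10), strrep("T", 10))), 0L)
  w <- alignDuplex(strrep("G", 10), strrep("T", 10), minScore = 10,
                   minLen = 10)
  expect_equal(w$score, 10)
  # empty input
  expect_equal(nrow(alignDuplex("", target)), 0L)
})

test_that("duplex scores equal an independent affine-gap local DP", {
  set.seed(404)
  sch <- pairingScheme()
  for (i in 1:60) {
    n1 <- sample(15:60, 1); n2 <- sample(15:60, 1)
    a <- randomDna(n1); b <- randomDna(n2)
    got <- alignDuplex(a, b, minScore = 1, minLen = 1, maxSites = 1L)
    want <- oracleLocalAlign(paste(rev(strsplit(a, "")[[1]]), collapse = ""),
                             b, sch$matrix, sch$gapOpen, sch$gapExtend)
    if (want < 1) expect_equal(nrow(got), 0L)
    else expect_equal(got$score[1], want)
    # antiparallel symmetry: reversing both strands preserves the optimum
    ra <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
    rb <- paste(rev(strsplit(b, "")[[1]]), collapse = "")
    got2 <- alignDuplex(ra, rb, minScore = 1, minLen = 1, maxSites = 1L)
    if (nrow(got) && nrow(got2)) expect_equal(got2$score[1], got$score[1])
  }
})

test_that("iterative masking reports non-overlapping sites by score", {
  target <- paste0(randomDna(40), strrep("G", 30), randomDna(40),
                   strrep("A", 25), randomDna(30))
  lnc <- paste0(randomDna(20), rcStr(strrep("A", 25)),
                randomDna(15), rcStr(strrep("G", 30)), randomDna(20))
  s <- alignDuplex(lnc, target, minScore = 50, minLen = 20)
  expect_gte(nrow(s), 2L)
  expect_true(all(diff(s$score) <= 0))     # sorted by score
  # no overlapping target intervals
  if (nrow(s) > 1) {
    ivs <- s[order(s$target_start), ]
    expect_true(all(ivs$target_start[-1] > ivs$target_end[-nrow(ivs)]))
  }
})

test_that("planted sites with wobbles are recovered with >= 90% overlap", {
  sim <- generateGenomeAndGenes(nGenes = 12, seed = 51)
  specs <- data.frame(gene_id = c("g001", "g002", "g004"),
                      region = c("junction", "exonic", "intronic"),
                      length = c(50L, 60L, 50L), wobble = c(0.1, 0.08, 0),
                      stringsAsFactors = FALSE)
  lnc <- generateLncrnas(sim, siteSpecs = specs, nLnc = 5, seed = 52)
  st <- lnc$truth$sites
  for (i in seq_len(nrow(st))) {
    gene <- sim$genes[[st$gene_id[i]]]
    s <- alignDuplex(lnc$lncrnas[[st$lncrna_id[i]]]@sequence,
                     preMrnaSequence(gene, lnc$genome), minScore = 60)
    expect_gte(nrow(s), 1L)
    ov <- min(s$target_end[1], st$pre_end[i]) -
      max(s$target_start[1], st$pre_start[i]) + 1
    expect_gte(ov / (st$pre_end[i] - st$pre_start[i] + 1), 0.9)
  }
})

test_that("lncRNA candidate filters apply length, expression and coding rules", {
  mkTx <- function(id, len, seq = NULL) {
    if (is.null(seq)) seq <- randomDna(len)
    TranscriptModel(id, id, "chr9", "+", cbind(1000, 1000 + len - 1),
                    sequence = seq)
  }
  coding <- paste0("ATG", strrep("GCA", 300), "TAA")
  cands <- list(
    short = mkTx("short", 150),
    coding = mkTx("coding", nchar(coding) + 100,
                  paste0(coding, randomDna(100))),
    faint = mkTx("faint", 500),
    good = mkTx("good", 500),
    annot = mkTx("annot", 500))
  m <- matrix(c(2, 2, 2, 0.4, 0.6, 2), 6, 1,
              dimnames = list(c("short", "coding", "faint", "good",
                                "annot", "x"), "s1"))
  expr <- ExpressionMatrix(m[1:5, , drop = FALSE], c(s1 = "c1"))
  m2 <- fpkm(expr); m2["faint", ] <- 0.4; m2["good", ] <- 0.6
  expr <- ExpressionMatrix(m2, c(s1 = "c1"))
  res <- filterLncrnaCandidates(cands, expr,
                                classCodes = c(annot = "="))
  keep <- stats::setNames(res$keep, res$transcript_id)
  expect_false(keep[["short"]])     # 150 nt <= 200
  expect_false(keep[["coding"]])    # 301-codon ORF
  expect_false(keep[["faint"]])     # max FPKM 0.4 < 0.5
  expect_true(keep[["good"]])       # 0.6 passes
  expect_false(keep[["annot"]])     # annotated class code
})

test_that("cis-NAT calls require opposite-strand genomic overlap", {
  genes <- list(g1 = GeneModel("g1", list(
    TranscriptModel("g1.t", "g1", "chr1", "+",
                    cbind(c(1000, 2000), c(1500, 2500))))))
  anti <- TranscriptModel("l1", "l1", "chr1", "-", cbind(1600, 1900))
  far <- TranscriptModel("l2", "l2", "chr1", "-", cbind(9000, 9400))
  same <- TranscriptModel("l3", "l3", "chr1", "+", cbind(1600, 1900))
  res <- classifyCisNat(list(anti, far, same), genes)
  expect_identical(res$class, c("cis_NAT", "intergenic",
                                "same_strand_novel"))
  expect_identical(res$overlapped_genes[1], "g1")
})

test_that("site context classification follows the pre-mRNA structure", {
  sim <- generateGenomeAndGenes(nGenes = 12, seed = 51)
  irGene <- names(sim$truth$types)[sim$truth$types == "intron_retention"][1]
  gene <- sim$genes[[irGene]]
  jn <- catalogueJunctions(gene, sim$genome)
  pre <- buildPreMrna(gene)
  # a site inside the first exon
  sites <- data.frame(target_start = 10L, target_end = 30L)
  expect_identical(classifySite(sites, gene, jn)$site_class, "exonic")
  # a site across the retained intron's donor boundary is junction-spanning
  ev <- classifyASEvents(gene)
  ir <- ev[ev$event_type == "intron_retention", ][1, ]
  b <- if (spliceomics:::geneStrand(gene) == "+") ir$start else ir$end
  pb <- spliceomics:::premrnaCoord(gene, b)
  s2 <- data.frame(target_start = pb - 10L, target_end = pb + 10L)
  cl <- classifySite(s2, gene, jn)
  expect_identical(cl$site_class, "junction_spanning")
  expect_true(cl$spans_alternative_junction)
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  flat <- data.frame(is_alternative = rep(c(TRUE, FALSE), each = 20))
  inter <- rep(c(TRUE, FALSE), 20)
  res <- junctionEnrichment(flat, inter)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p, 1)
  # classic 9/1 vs 1/9 table
  jn <- data.frame(is_alternative = rep(c(TRUE, FALSE), each = 10))
  inter2 <- c(rep(TRUE, 9), FALSE, TRUE, rep(FALSE, 9))
  res2 <- junctionEnrichment(jn, inter2)
  # exact two-sided p = 2*(C(10,9)*C(10,1) + 1) / C(20,10) = 202/184756
  expect_equal(res2$p, 202 / 184756, tolerance = 1e-10)
  expect_equal(res2$p, oracleFisherP(res2$table))
  # random tables with margins <= 30 agree with the enumeration oracle
  set.seed(88)
  for (i in 1:80) {
    repeat {
      tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    jn_ <- data.frame(is_alternative = rep(c(TRUE, FALSE), rowSums(tab)))
    int_ <- c(rep(c(TRUE, FALSE), tab[1, ]), rep(c(TRUE, FALSE), tab[2, ]))
    r <- junctionEnrichment(jn_, int_)
    expect_equal(r$p, oracleFisherP(r$table), tolerance = 1e-10)
  }
  # zero cell: Haldane-corrected odds ratio is finite
  jn0 <- data.frame(is_alternative = rep(c(TRUE, FALSE), each = 10))
  int0 <- c(rep(TRUE, 10), rep(FALSE, 10))
  expect_true(is.finite(junctionEnrichment(jn0, int0)$odds_ratio))
  # empty margin: undefined, reported as NA
  expect_true(is.na(junctionEnrichment(
    data.frame(is_alternative = rep(TRUE, 5)), rep(TRUE, 5))$p))
})

test_that("interactions planted on alternative junctions are enriched", {
  sim <- generateGenomeAndGenes(nGenes = 30, seed = 61)
  irGenes <- names(sim$truth$types)[sim$truth$types == "intron_retention"]
  jnAll <- list(); interAll <- list()
  for (gid in names(sim$genes)) {
    gene <- sim$genes[[gid]]
    ev <- classifyASEvents(gene)
    jn <- catalogueJunctions(gene, events = ev)
    inter <- logical(nrow(jn))
    if (gid %in% irGenes && nrow(ev)) {
      # plant an interaction exactly on the retained intron's junction
      ir <- ev[ev$event_type == "intron_retention", ][1, ]
      hit <- jn$intron_start == ir$start & jn$intron_end == ir$end
      inter[hit] <- TRUE
    }
    jnAll[[gid]] <- jn; interAll[[gid]] <- inter
  }
  res <- junctionEnrichment(do.call(rbind, jnAll), unlist(interAll))
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p, 0.05)
})

test_that("expression correlation uses exact permutation p for small n", {
  m <- matrix(c(1, 2, 3, 4, 5,
                2, 4, 6, 8, 10,
                10, 8, 6, 4, 2), 3, 5, byrow = TRUE,
              dimnames = list(c("lnc1", "tA", "tB"), paste0("s", 1:5)))
  expr <- ExpressionMatrix(m, stats::setNames(paste0("c", 1:5),
                                              paste0("s", 1:5)))
  pairs <- data.frame(lncrna_id = c("lnc1", "lnc1"),
                      target_id = c("tA", "tB"),
                      stringsAsFactors = FALSE)
  res <- correlatePairs(pairs, expr)
  expect_equal(res$rho, c(1, -1))
  # exact p for perfect order with n = 5: 1/120 one-sided, 2/120 two-sided
  expect_equal(res$p[1], 2 / 120)
  expect_true(res$co_regulated[1])
  expect_false(res$co_regulated[2])      # rho = -1 fails rho > 0.8
  # n = 3: the exact two-sided p can never reach 0.05 -> warning
  m3 <- m[, 1:3]
  expr3 <- ExpressionMatrix(m3, stats::setNames(paste0("c", 1:3),
                                                paste0("s", 1:3)))
  expect_warning(res3 <- correlatePairs(pairs, expr3), "cannot")
  expect_gte(min(res3$p), 2 / 6)
  # constant vector: rho undefined, reported NA
  mC <- rbind(m, tC = rep(3, 5))
  exprC <- ExpressionMatrix(mC, stats::setNames(paste0("c", 1:5),
                                                paste0("s", 1:5)))
  expect_message(resC <- correlatePairs(
    data.frame(lncrna_id = "lnc1", target_id = "tC"), exprC), "constant")
  expect_true(is.na(resC$rho))
})

test_that("shared site fractions follow the overlap definition", {
  sa <- data.frame(lncrna_id = c("l1", "l1"), target_gene = c("g1", "g2"),
                   g_start = c(100, 500), g_end = c(140, 540))
  expect_equal(commonSiteFraction(sa, sa)$shared_fraction, 1)
  sb <- data.frame(lncrna_id = c("l1", "l2"), target_gene = c("g3", "g4"),
                   g_start = c(100, 500), g_end = c(140, 540))
  expect_equal(commonSiteFraction(sa, sb)$shared_fraction, 0)
  # 1 shared site among 4 distinct -> 0.25
  sc_ <- data.frame(lncrna_id = c("l1", "l9", "l8"),
                    target_gene = c("g1", "g9", "g8"),
                    g_start = c(120, 900, 700), g_end = c(160, 940, 740))
  res <- commonSiteFraction(sa, sc_)
  expect_equal(res$n_shared, 1L)
  expect_equal(res$shared_fraction, 0.25)
})
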