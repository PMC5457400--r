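test_that("ORF prediction finds the planted reading frame", {
  # no ATG anywhere: nothing qualifies
  expect_equal(nrow(predictOrfs(strrep("C", 400))), 0L)
  # ATG + 120 lysine codons + TAA at offset 30
  seqn <- paste0(strrep("C", 30), "ATG", strrep("AAA", 120), "TAA",
                 strrep("C", 21))
  orfs <- predictOrfs(seqn)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$utr5_length, 30L)
  expect_equal(nchar(orfs$protein), 121L)
  expect_identical(orfs$protein, paste0("M", strrep("K", 120)))
  expect_false(orfs$partial)
  # two ORFs: the longer one is primary
  two <- paste0("ATG", strrep("GGA", 120), "TAA",
                "ATG", strrep("GGA", 200), "TAA")
  o2 <- predictOrfs(two)
  expect_equal(nrow(o2), 2L)
  expect_equal(nchar(o2$protein[o2$primary]), 201L)
  # ORF running off the 3' end is flagged partial
  part <- paste0(strrep("C", 12), "ATG", strrep("AAA", 150))
  expect_true(predictOrfs(part)$partial)
  # below the length cutoff: rejected
  expect_equal(nrow(predictOrfs(paste0("ATG", strrep("AAA", 50), "TAA"))),
               0L)
})

test_that("tryptic digestion obeys the Keil rule and missed cleavages", {
  d <- digestTrypsin("AAKGGRCC")
  expect_setequal(d$peptide[d$missed == 0], c("AAK", "GGR", "CC"))
  expect_setequal(d$peptide[d$missed == 1], c("AAKGGR", "GGRCC"))
  # no cleavage before proline
  expect_equal(digestTrypsin("AAKPGG")$peptide, "AAKPGG")
  # no cut sites: the protein itself
  expect_equal(digestTrypsin("ACDEFG")$peptide, "ACDEFG")
  # terminal K produces no empty fragment
  expect_setequal(digestTrypsin("AAKGGK", maxMissed = 0)$peptide,
                  c("AAK", "GGK"))
})

test_that("digestion equals the regex oracle on random proteins", {
  set.seed(77)
  lens <- sample(10:2000, 150, replace = TRUE)
  for (n in lens) {
    p <- randomProtein(n)
    got <- sort(digestTrypsin(p)$peptide)
    want <- sort(oracleDigest(p))
    expect_identical(got, want)
  }
})

test_that("peptide specificity classes follow the uniqueness definitions", {
  # two identical ORFs: nothing isoform-specific
  db <- data.frame(orf_id = c("o1", "o2"), transcript_id = c("t1", "t2"),
                   gene_id = "g1",
                   protein = paste0("MAAAAAAK", "CCCCCCR", "DDDDDDD"),
                   stringsAsFactors = FALSE)
  recs <- classifyPeptides(db)
  expect_false(any(recs$specificity == "isoform_specific"))
  expect_true(all(recs$n_isoforms == 2))

  # insertion variant: inserted and junction peptides are isoform-specific,
  # shared terminal peptides gene-unique
  shared1 <- "MAAAAAAK"; ins <- "WWWWWWWK"; shared2 <- "CCCCCCCR"
  db2 <- data.frame(orf_id = c("o1", "o2"), transcript_id = c("t1", "t2"),
                    gene_id = "g1",
                    protein = c(paste0(shared1, shared2),
                                paste0(shared1, ins, shared2)),
                    stringsAsFactors = FALSE)
  recs2 <- classifyPeptides(db2)
  expect_identical(
    recs2$specificity[recs2$peptide == "WWWWWWWK"], "isoform_specific")
  expect_identical(
    recs2$specificity[recs2$peptide == shared1], "gene_unique_shared")
  # missed-cleavage junction peptide unique to the long isoform
  expect_identical(
    recs2$specificity[recs2$peptide == paste0(ins, shared2)],
    "isoform_specific")

  # a peptide present in two genes is multi_gene
  db3 <- rbind(db2, data.frame(orf_id = "o3", transcript_id = "t3",
                               gene_id = "g2",
                               protein = paste0(shared1, "YYYYYYY"),
                               stringsAsFactors = FALSE))
  recs3 <- classifyPeptides(db3)
  expect_identical(recs3$specificity[recs3$peptide == shared1],
                   "multi_gene")
})

test_that("I/L equivalence collapses otherwise-distinguishing peptides", {
  db <- data.frame(orf_id = c("o1", "o2"), transcript_id = c("t1", "t2"),
                   gene_id = "g1",
                   protein = c("MAAAIAAK", "MAAALAAK"),
                   stringsAsFactors = FALSE)
  collapsed <- classifyPeptides(db, ilEquivalence = TRUE)
  expect_false(any(collapsed$specificity == "isoform_specific"))
  strict <- classifyPeptides(db, ilEquivalence = FALSE)
  expect_equal(sum(strict$specificity == "isoform_specific"), 2L)
})

test_that("specificity equals the exhaustive all-pairs oracle", {
  set.seed(31)
  for (rep in 1:10) {
    nGenes <- sample(3:6, 1)
    rows <- list()
    for (g in seq_len(nGenes)) {
      nIso <- sample(1:3, 1)
      base <- randomProtein(sample(60:120, 1))
      for (t in seq_len(nIso)) {
        prot <- if (t == 1) base else
          paste0(substr(base, 1, 30), randomProtein(20),
                 substr(base, 31, nchar(base)))
        rows[[length(rows) + 1]] <- data.frame(
          orf_id = sprintf("g%d.t%d.o", g, t),
          transcript_id = sprintf("g%d.t%d", g, t),
          gene_id = sprintf("g%d", g), protein = prot,
          stringsAsFactors = FALSE)
      }
    }
    db <- do.call(rbind, rows)
    recs <- classifyPeptides(db)
    want <- oracleSpecificity(db)
    expect_identical(stats::setNames(recs$specificity, recs$key),
                     want[recs$key])
    expect_equal(nrow(recs), length(want))
  }
})

test_that("unique ORF count per gene never exceeds the isoform count", {
  # UTR-only isoform differences collapse to one unique ORF
  sim <- generateGenomeAndGenes(nGenes = 20, seed = 23)
  orfDb <- orfDatabase(sim$genes)
  for (g in unique(orfDb$gene_id)) {
    sub <- orfDb[orfDb$gene_id == g, ]
    expect_lte(length(unique(sub$protein)), length(
      transcripts(sim$genes[[g]])))
  }
  # alt_tss genes differ only in the 5' UTR: identical proteins
  tssGenes <- names(sim$truth$types)[sim$truth$types == "alt_tss"]
  for (g in intersect(tssGenes, orfDb$gene_id)) {
    sub <- orfDb[orfDb$gene_id == g, ]
    if (nrow(sub) == 2) expect_identical(sub$protein[1], sub$protein[2])
  }
})

test_that("observed peptides map to genes and isoforms correctly", {
  shared <- "MAAAAAAK"; insA <- "WWWWWWWK"; tailB <- "CCCCCCCR"
  db <- data.frame(orf_id = c("o1", "o2"), transcript_id = c("t1", "t2"),
                   gene_id = "g1",
                   protein = c(paste0(shared, insA, tailB, "DDDDDDDK"),
                               paste0(shared, tailB, "EEEEEEEK")),
                   stringsAsFactors = FALSE)
  recs <- classifyPeptides(db)
  obs <- data.frame(peptide_sequence = c(insA, "EEEEEEEK", shared,
                                         "QQQQQQQQ"),
                    sample_id = "ms1", spectral_count = c(3L, 2L, 5L, 1L),
                    stringsAsFactors = FALSE)
  expect_message(res <- mapObservedPeptides(obs, recs), "not in the database")
  expect_equal(res$n_unmapped, 1L)
  g <- res$genes[res$genes$gene_id == "g1", ]
  expect_true(g$confirmed)
  expect_true(g$as_confirmed)          # ISPs from both isoforms
  expect_equal(g$isoforms_with_isp, 2L)
  # only shared peptides: confirmed but not AS-confirmed
  res2 <- mapObservedPeptides(
    data.frame(peptide_sequence = shared, sample_id = "ms1",
               spectral_count = 2L, stringsAsFactors = FALSE), recs)
  expect_true(res2$genes$confirmed)
  expect_false(res2$genes$as_confirmed)
  # spectra per isoform aggregate ISP counts
  expect_equal(res$isoformSpectra$isp_spectra[
    res$isoformSpectra$transcript_id == "t1"], 3)
})

test_that("ISP spectra track isoform abundance when sampling is coupled", {
  sim <- generateGenomeAndGenes(nGenes = 20, seed = 29)
  ex <- generateExpression(sim$genes, noiseCv = 0.1, seed = 2)
  orfDb <- orfDatabase(sim$genes)
  recs <- classifyPeptides(orfDb)
  ab <- rowMeans(fpkm(ex$expr))[orfDb$transcript_id]
  names(ab) <- orfDb$transcript_id
  ms <- generateMsObservations(orfDb, recs, ab, nSpectra = 6000, seed = 8)
  mapped <- mapObservedPeptides(ms$observations, recs)
  corr <- spectraFpkmCorrelation(mapped$isoformSpectra, ex$expr,
                                 "protonema")
  expect_gt(corr$rho, 0)
})
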