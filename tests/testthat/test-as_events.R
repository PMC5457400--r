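mkGene <- function(..., strand = "+", gid = "g") {
  isoforms <- list(...)
  txs <- lapply(seq_along(isoforms), function(i)
    TranscriptModel(paste0("t", i), gid, "chr1", strand, isoforms[[i]]))
  GeneModel(gid, txs)
}

test_that("the hypothetical pre-mRNA is the exon union plus complement", {
  g1 <- mkGene(cbind(100, 200))
  pre <- buildPreMrna(g1)
  expect_equal(length(pre$introns), 0L)
  expect_equal(IRanges::start(pre$exons), 100L)

  g2 <- mkGene(cbind(c(100, 200), c(150, 250)),
               cbind(c(100, 180), c(150, 250)))
  pre2 <- buildPreMrna(g2)
  expect_equal(IRanges::start(pre2$exons), c(100L, 180L))
  expect_equal(IRanges::end(pre2$exons), c(150L, 250L))
  expect_equal(IRanges::start(pre2$introns), 151L)
  expect_equal(IRanges::end(pre2$introns), 179L)
  # union exonic length dominates every isoform's exonic length
  for (tx in transcripts(g2))
    expect_gte(sum(IRanges::width(pre2$exons)),
               sum(IRanges::width(exonRanges(tx))))
})

test_that("identical isoforms yield no AS events", {
  g <- mkGene(cbind(c(100, 300), c(200, 400)),
              cbind(c(100, 300), c(200, 400)))
  expect_equal(nrow(classifyASEvents(g)), 0L)
  # single-isoform genes too
  expect_equal(nrow(classifyASEvents(mkGene(cbind(100, 400)))), 0L)
})

test_that("hand-constructed events are classified with exact intervals", {
  # intron retention: t2 keeps intron 201..299
  ir <- mkGene(cbind(c(100, 300), c(200, 400)), cbind(100, 400))
  ev <- classifyASEvents(ir)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "intron_retention")
  expect_equal(c(ev$start, ev$end), c(201L, 299L))

  # alternative donor on plus strand: shared acceptor, donors 200 vs 190
  ad <- mkGene(cbind(c(100, 300), c(200, 400)),
               cbind(c(100, 300), c(190, 400)))
  ev <- classifyASEvents(ad)
  expect_equal(ev$event_type, "alt_donor")
  expect_equal(c(ev$start, ev$end), c(191L, 200L))
  # the same structure on the minus strand is an alternative acceptor
  adm <- mkGene(cbind(c(100, 300), c(200, 400)),
                cbind(c(100, 300), c(190, 400)), strand = "-")
  expect_equal(classifyASEvents(adm)$event_type, "alt_acceptor")

  # exon skipping: internal exon of t1 inside t2's intron
  es <- mkGene(cbind(c(100, 300, 500), c(200, 350, 600)),
               cbind(c(100, 500), c(200, 600)))
  ev <- classifyASEvents(es)
  expect_true("exon_skipping" %in% ev$event_type)
  sk <- ev[ev$event_type == "exon_skipping", ]
  expect_equal(c(sk$start, sk$end), c(300L, 350L))
  # the skipped-exon boundary shifts are not also alt donor/acceptor calls
  expect_false(any(ev$event_type %in% c("alt_donor", "alt_acceptor")))
})

test_that("classification equals the brute-force oracle on random genes", {
  set.seed(20240601)
  for (rep in 1:200) {
    rg <- randomGeneModel()
    got <- eventKeysOf(classifyASEvents(rg$gene))
    want <- oracleEventKeys(rg$exonList, rg$strand)
    expect_identical(got, want)
  }
})

test_that("planted synthetic event counts are recovered exactly by type", {
  sim <- generateGenomeAndGenes(nGenes = 40, seed = 99)
  found <- do.call(rbind, lapply(sim$genes, classifyASEvents))
  planted <- sim$truth$events
  expect_equal(nrow(found), nrow(planted))
  expect_equal(as.list(table(found$event_type)),
               as.list(table(planted$event_type)))
  # every planted (type, interval) is present verbatim
  fk <- paste(found$gene_id, found$event_type, found$start, found$end)
  pk <- paste(planted$gene_id, planted$event_type, planted$start,
              planted$end)
  expect_setequal(fk, pk)
})

test_that("junction catalogue flags alternative use and reads dinucleotides", {
  # constitutive intron in both isoforms
  genome <- NULL
  g <- mkGene(cbind(c(100, 300), c(200, 400)),
              cbind(c(100, 300), c(200, 400)))
  j <- catalogueJunctions(g)
  expect_equal(nrow(j), 1L)
  expect_false(j$is_alternative)

  # retained intron: junction flagged alternative
  ir <- mkGene(cbind(c(100, 300), c(200, 400)), cbind(100, 400))
  j <- catalogueJunctions(ir)
  expect_true(all(j$is_alternative))

  # minus-strand dinucleotides are reported in transcription orientation:
  # genomic CT..AC reads GT..AG on the minus strand
  chrom <- paste0(strrep("A", 99), strrep("C", 21),        # exon 100..120
                  "CT", strrep("A", 16), "AC",             # intron 121..140
                  strrep("G", 30), strrep("T", 100))
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  gm <- mkGene(cbind(c(100, 141), c(120, 170)),
               cbind(c(90, 141), c(120, 170)), strand = "-")
  j <- catalogueJunctions(gm, genome)
  expect_equal(unique(j$donor_dinucleotide), "GT")
  expect_equal(unique(j$acceptor_dinucleotide), "AG")
  # donor precedes acceptor in transcription order (minus strand: donor at
  # the genomic end of the intron)
  expect_equal(j$donor_pos[1], 140L)
  expect_equal(j$acceptor_pos[1], 121L)

  # tiny intron: warning, dinucleotides unclassified
  tiny <- mkGene(cbind(c(100, 124), c(120, 150)),
                 cbind(c(90, 124), c(120, 150)))
  expect_warning(jt <- catalogueJunctions(tiny, genome), "shorter than 4")
  expect_true(any(is.na(jt$donor_dinucleotide)))
})

test_that("first introns and retained-intron junctions are filterable", {
  sim <- generateGenomeAndGenes(nGenes = 12, seed = 3)
  irGene <- names(sim$truth$types)[sim$truth$types == "intron_retention"][1]
  g <- sim$genes[[irGene]]
  ev <- classifyASEvents(g)
  j <- catalogueJunctions(g, sim$genome, events = ev)
  jf <- filterJunctions(j, g, events = ev)
  expect_lt(nrow(jf), nrow(j))
  ir <- ev[ev$event_type == "intron_retention", ]
  expect_false(any(jf$intron_start == ir$start & jf$intron_end == ir$end))
})

test_that("PPM scoring follows the log-odds definition", {
  uni <- matrix(0.25, 4, 13, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(scorePPM(strrep("G", 13), uni), 0)
  one <- matrix(c(0.2, 0.2, 0.5, 0.1), 4, 1,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(scorePPM("G", one), 1)            # log2(0.5/0.25)
  expect_equal(scorePPM("N", one), 0)            # ambiguous base contributes 0
  # consensus score equals the hand-computed column sum
  m <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.1, 0.7, 0.1, 0.1,
                0.1, 0.1, 0.7, 0.1,
                0.1, 0.1, 0.1, 0.7), 4, 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(scorePPM("ACGT", m), 4 * log2(0.7 / 0.25))
  expect_error(scorePPM("ACG", m), "length")
})

test_that("junction subtypes separate U2 from U12 consensus introns", {
  simU2 <- generateGenomeAndGenes(nGenes = 10, u12Fraction = 0, seed = 21)
  simU12 <- generateGenomeAndGenes(nGenes = 10, u12Fraction = 1, seed = 21)
  ppms <- loadPPM()
  typeOf <- function(sim) {
    unlist(lapply(sim$genes, function(g) {
      j <- classifyJunctionSubtype(catalogueJunctions(g, sim$genome), g,
                                   sim$genome, ppms = ppms)
      # alt donor/acceptor variants carry non-consensus shifted boundaries;
      # restrict to junctions canonical at both ends
      j$subtype[j$donor_dinucleotide %in% c("GT", "AT") &
                j$acceptor_dinucleotide %in% c("AG", "AC")]
    }))
  }
  tU2 <- typeOf(simU2); tU12 <- typeOf(simU12)
  expect_true(all(tU2 == "U2"))
  expect_true(all(tU12 == "U12"))
  # ties go to U2: uniform matrices give equal scores everywhere
  uni <- function(L) {
    m <- matrix(0.25, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    attr(m, "offset") <- -3L
    m
  }
  flat <- list(epsilon = 0.01,
               matrices = list(U2_donor = uni(13), U2_acceptor = uni(17),
                               U12_donor = uni(13), U12_branch = uni(9)))
  attr(flat$matrices$U2_acceptor, "offset") <- -14L
  g <- simU2$genes[[1]]
  j <- classifyJunctionSubtype(catalogueJunctions(g, simU2$genome), g,
                               simU2$genome, ppms = flat, floor = -1)
  expect_true(all(j$subtype == "U2"))
  expect_true(all(j$u2_score == j$u12_score))
})
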