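## End-to-end orchestration: models_io -> as_events -> isoform_quant ->
## proteogenomics -> detect_sim -> lnc_interactome, with a run manifest.

#' Assemble a pipeline run configuration
#'
#' Thresholds default to the published analysis settings: dIF 20 percentage
#' points, gene FPKM floor 0.2, lncRNA FPKM 0.5, target mRNA FPKM 1, |log2
#' fold change| 2, FDR 0.05, duplex score 100 over >= 25 nt, 100
#' resampling replicates, Spearman rho 0.8.
#'
#' @param gtf,genomeFasta,expression input paths (required)
#' @param peptides optional observed-peptide TSV
#' @param lncGtf optional lncRNA annotation (GTF)
#' @param outDir output directory
#' @param conditionPair character(2) or NULL (first two conditions found)
#' @param difThreshold,fpkmFloor,lncFpkmMin,mrnaFpkmMin,lfc,fdr,minScore,minLen,reps,rhoMin thresholds
#' @param seed integer seed
#' @return a named list of class \code{spliceomicsConfig}
#' @export
runConfig <- function(gtf, genomeFasta, expression, peptides = NULL,
                      lncGtf = NULL, outDir = "spliceomics_run",
                      conditionPair = NULL, difThreshold = 20,
                      fpkmFloor = 0.2, lncFpkmMin = 0.5, mrnaFpkmMin = 1,
                      lfc = 2, fdr = 0.05, minScore = 100, minLen = 25,
                      reps = 100L, rhoMin = 0.8, seed = 1L) {
  cfg <- list(gtf = gtf, genomeFasta = genomeFasta, expression = expression,
              peptides = peptides, lncGtf = lncGtf, outDir = outDir,
              conditionPair = conditionPair, difThreshold = difThreshold,
              fpkmFloor = fpkmFloor, lncFpkmMin = lncFpkmMin,
              mrnaFpkmMin = mrnaFpkmMin, lfc = lfc, fdr = fdr,
              minScore = minScore, minLen = minLen, reps = as.integer(reps),
              rhoMin = rhoMin, seed = as.integer(seed))
  stopifnot(cfg$difThreshold >= 0, cfg$difThreshold <= 100,
            cfg$fpkmFloor >= 0, cfg$fdr > 0, cfg$fdr < 1, cfg$reps >= 1)
  class(cfg) <- "spliceomicsConfig"
  cfg
}

configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages run in a fixed order, each writing its TSV outputs before the
#' next starts; a JSON manifest records the stage list, configuration hash
#' and seed. Outputs are byte-identical across runs with the same inputs
#' and seed.
#'
#' @param config a [runConfig] object
#' @return invisibly, a list with the main in-memory results and the run
#'   directory
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "spliceomicsConfig"))
  for (p in c(config$gtf, config$genomeFasta, config$expression,
              config$peptides, config$lncGtf))
    if (!is.null(p) && !file.exists(p))
      stop("input file not found: ", p)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  runStage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  io <- runStage("models_io", function() {
    genes <- readGeneModels(config$gtf)
    genome <- asGenome(config$genomeFasta)
    genes <- extractSequences(genes, genome)
    known <- names(txGeneMap(genes))
    if (!is.null(config$lncGtf))
      known <- c(known, names(txGeneMap(readGeneModels(config$lncGtf))))
    expr <- readExpression(config$expression,
                           conditions = conditionsFromHeader(config$expression),
                           knownTranscripts = known)
    writeTsv(data.frame(
      transcript_id = names(txGeneMap(genes)),
      gene_id = unname(txGeneMap(genes))),
      file.path(config$outDir, "catalogue.tsv"))
    list(genes = genes, genome = genome, expr = expr)
  })

  asv <- runStage("as_events", function() {
    ppms <- loadPPM()
    ev <- list(); jn <- list()
    for (g in io$genes) {
      e <- classifyASEvents(g)
      j <- catalogueJunctions(g, io$genome, events = e)
      j <- classifyJunctionSubtype(j, g, io$genome, ppms = ppms)
      ev[[g@geneId]] <- e; jn[[g@geneId]] <- j
    }
    events <- do.call(rbind, ev); rownames(events) <- NULL
    junctions <- do.call(rbind, jn); rownames(junctions) <- NULL
    writeTsv(events, file.path(config$outDir, "as_events.tsv"))
    writeTsv(junctions, file.path(config$outDir, "junctions.tsv"))
    list(events = events, junctions = junctions)
  })

  quant <- runStage("isoform_quant", function() {
    conds <- unique(sampleConditions(io$expr))
    pair <- if (!is.null(config$conditionPair)) config$conditionPair
            else conds[1:2]
    das <- callDas(io$expr, io$genes, pair,
                   difThreshold = config$difThreshold, fdr = config$fdr,
                   seed = config$seed)
    de <- callDe(io$expr, io$genes, pair, floor = config$fpkmFloor,
                 lfc = config$lfc)
    writeTsv(das$isoforms, file.path(config$outDir, "isoform_usage.tsv"))
    writeTsv(das$genes, file.path(config$outDir, "das_genes.tsv"))
    writeTsv(de, file.path(config$outDir, "de_genes.tsv"))
    list(das = das, de = de, pair = pair)
  })

  prot <- runStage("proteogenomics", function() {
    orfDb <- orfDatabase(io$genes)
    records <- classifyPeptides(orfDb)
    writeTsv(orfDb[, c("orf_id", "transcript_id", "gene_id", "utr5_length",
                       "partial")],
             file.path(config$outDir, "orfs.tsv"))
    writeTsv(records, file.path(config$outDir, "peptides_db.tsv"))
    mapped <- NULL
    if (!is.null(config$peptides)) {
      obs <- utils::read.delim(config$peptides, stringsAsFactors = FALSE)
      mapped <- mapObservedPeptides(obs, records)
      writeTsv(mapped$genes,
               file.path(config$outDir, "proteome_evidence.tsv"))
    }
    list(orfDb = orfDb, records = records, mapped = mapped)
  })

  det <- runStage("detect_sim", function() {
    if (is.null(prot$mapped)) return(NULL)
    pools <- genePeptidePools(prot$orfDb, prot$records)
    counts <- stats::setNames(prot$mapped$genes$n_peptides,
                              prot$mapped$genes$gene_id)
    res <- simulateDetection(pools, counts, nReps = config$reps,
                             seed = config$seed)
    observed <- sum(prot$mapped$genes$as_confirmed)
    cmp <- compareToObserved(res, observed)
    writeTsv(data.frame(replicate = seq_len(res@nReps),
                        as_distinguishable = res@perReplicate,
                        any_isp = res@perReplicateAny),
             file.path(config$outDir, "detectability_replicates.tsv"))
    writeTsv(data.frame(mean = cmp$mean, sd = cmp$sd,
                        observed = cmp$observed, ratio = cmp$ratio,
                        verdict = cmp$verdict),
             file.path(config$outDir, "detectability_summary.tsv"))
    list(result = res, comparison = cmp)
  })

  lnc <- runStage("lnc_interactome", function() {
    if (is.null(config$lncGtf)) return(NULL)
    lncGenes <- readGeneModels(config$lncGtf)
    lncTx <- transcriptIndex(extractSequences(lncGenes, io$genome))
    filt <- filterLncrnaCandidates(lncTx, io$expr,
                                   minFpkm = config$lncFpkmMin)
    writeTsv(filt, file.path(config$outDir, "lncrna_filter.tsv"))
    nat <- classifyCisNat(lncTx, io$genes)
    writeTsv(nat, file.path(config$outDir, "lncrna_classes.tsv"))
    kept <- filt$transcript_id[filt$keep]
    ## targets: pre-mRNAs of genes expressed above the mRNA floor
    m <- fpkm(io$expr)
    conds <- sampleConditions(io$expr)
    condMean <- vapply(unique(conds), function(cc)
      rowMeans(m[, conds == cc, drop = FALSE]), numeric(nrow(m)))
    maxF <- apply(condMean, 1L, max)
    gmap <- txGeneMap(io$genes)
    geneMax <- tapply(maxF[names(gmap)], unname(gmap), max)
    targets <- names(geneMax)[!is.na(geneMax) & geneMax > config$mrnaFpkmMin]
    siteRows <- list()
    interVecs <- list()
    allJn <- list()
    for (gid in targets) {
      gene <- io$genes[[gid]]
      preSeq <- preMrnaSequence(gene, io$genome)
      jn <- asv$junctions[asv$junctions$gene_id == gid, , drop = FALSE]
      inter <- logical(nrow(jn))
      for (lid in kept) {
        s <- alignDuplex(lncTx[[lid]]@sequence, preSeq,
                         minScore = config$minScore,
                         minLen = config$minLen)
        if (!nrow(s)) next
        s <- classifySite(s, gene, jn)
        g <- t(vapply(seq_len(nrow(s)), function(i)
          premrnaToGenomic(gene, s$target_start[i], s$target_end[i]),
          integer(2)))
        s$g_start <- g[, 1L]; s$g_end <- g[, 2L]
        s$lncrna_id <- lid; s$target_gene <- gid
        siteRows[[length(siteRows) + 1L]] <- s
        inter <- inter | junctionsInteracted(jn, s, gene)
      }
      allJn[[gid]] <- jn
      interVecs[[gid]] <- inter
    }
    sites <- if (length(siteRows)) do.call(rbind, siteRows) else NULL
    enr <- NULL
    if (!is.null(sites)) {
      writeTsv(sites, file.path(config$outDir, "interaction_sites.tsv"))
      writeBed6(sites, file.path(config$outDir, "interaction_sites.bed"))
      jnAll <- do.call(rbind, allJn)
      enr <- junctionEnrichment(jnAll, unlist(interVecs))
    }
    list(filter = filt, classes = nat, sites = sites, enrichment = enr)
  })

  manifest <- list(package = "spliceomics",
                   version = as.character(utils::packageVersion("spliceomics")),
                   stages = stages, seed = config$seed,
                   config_hash = configHash(config))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = config$outDir, io = io, events = asv, quant = quant,
                 proteo = prot, detect = det, lnc = lnc,
                 manifest = manifest))
}

## condition labels from sample headers of the form <condition>_r<rep>
conditionsFromHeader <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1L]][-1L]
  stats::setNames(sub("_r[0-9]+$", "", hdr), hdr)
}

writeBed6 <- function(sites, path) {
  bed <- data.frame(chrom = sites$target_gene,
                    start = sites$g_start - 1L,   # BED is 0-based half-open
                    end = sites$g_end,
                    name = paste(sites$lncrna_id, sites$site_class,
                                 sep = "|"),
                    score = round(sites$score),
                    strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- command-line interface ------------------------------------------------

cliUsage <- function() {
  cat("usage: spliceomics-cli.R <command> [--flag value ...]\n",
      "commands:\n",
      "  generate        --out DIR [--genes N] [--seed S] [--noise CV]\n",
      "  run             --gtf F --genome F --expr F [--peptides F]\n",
      "                  [--lnc-gtf F] --out DIR [--seed S]\n",
      "  as-events       --gtf F\n",
      "  das             --gtf F --expr F [--dif-threshold X] [--fdr X]\n",
      "  digest          --fasta F [--missed N]\n",
      "  isp             --gtf F --genome F\n",
      "  simulate-detect --gtf F --genome F --peptides F [--reps N] [--seed S]\n",
      "  lnc-sites       --gtf F --genome F --lnc-gtf F [--min-score X] [--min-len X]\n",
      sep = "")
}

cliFlags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("flag ", a, " needs a value")
    flags[[sub("^--", "", a)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches the subcommands exposed by \code{inst/scripts/spliceomics-cli.R}.
#' Returns an exit status: 0 ok, 1 data error, 2 usage error.
#'
#' @param args character vector of command-line arguments
#' @return integer exit status, invisibly
#' @export
cliMain <- function(args) {
  if (!length(args) || args[1L] %in% c("--help", "-h", "help")) {
    cliUsage()
    return(invisible(0L))
  }
  cmd <- args[1L]
  status <- tryCatch({
    flags <- cliFlags(args[-1L])
    num <- function(name, default) if (!is.null(flags[[name]]))
      as.numeric(flags[[name]]) else default
    switch(cmd,
      generate = {
        d <- generateDataset(nGenes = as.integer(num("genes", 40)),
                             seed = as.integer(num("seed", 1)),
                             noiseCv = num("noise", 0.2))
        writeDataset(d, flags$out)
        cat("dataset written to", flags$out, "\n")
        0L
      },
      run = {
        cfg <- runConfig(gtf = flags$gtf, genomeFasta = flags$genome,
                         expression = flags$expr,
                         peptides = flags$peptides, lncGtf = flags$`lnc-gtf`,
                         outDir = flags$out,
                         seed = as.integer(num("seed", 1)))
        runPipeline(cfg)
        cat("pipeline finished; outputs in", flags$out, "\n")
        0L
      },
      `as-events` = {
        genes <- readGeneModels(flags$gtf)
        ev <- do.call(rbind, lapply(genes, classifyASEvents))
        utils::write.table(ev, stdout(), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        0L
      },
      das = {
        genes <- readGeneModels(flags$gtf)
        expr <- readExpression(flags$expr,
                               conditions = conditionsFromHeader(flags$expr))
        pair <- unique(sampleConditions(expr))[1:2]
        res <- callDas(expr, genes, pair,
                       difThreshold = num("dif-threshold", 20),
                       fdr = num("fdr", 0.05))
        utils::write.table(res$genes, stdout(), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        0L
      },
      digest = {
        prot <- Biostrings::readAAStringSet(flags$fasta)
        for (i in seq_along(prot)) {
          dg <- digestTrypsin(as.character(prot[[i]]),
                              maxMissed = as.integer(num("missed", 1)))
          dg$protein <- names(prot)[i]
          utils::write.table(dg, stdout(), sep = "\t", quote = FALSE,
                             row.names = FALSE, col.names = i == 1L)
        }
        0L
      },
      isp = {
        genes <- extractSequences(readGeneModels(flags$gtf), flags$genome)
        records <- classifyPeptides(orfDatabase(genes))
        utils::write.table(records, stdout(), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        0L
      },
      `simulate-detect` = {
        genes <- extractSequences(readGeneModels(flags$gtf), flags$genome)
        orfDb <- orfDatabase(genes)
        records <- classifyPeptides(orfDb)
        obs <- utils::read.delim(flags$peptides, stringsAsFactors = FALSE)
        mapped <- mapObservedPeptides(obs, records)
        pools <- genePeptidePools(orfDb, records)
        counts <- stats::setNames(mapped$genes$n_peptides,
                                  mapped$genes$gene_id)
        res <- simulateDetection(pools, counts,
                                 nReps = as.integer(num("reps", 100)),
                                 seed = as.integer(num("seed", 1)))
        cmp <- compareToObserved(res, sum(mapped$genes$as_confirmed))
        cat("mean:", cmp$mean, "sd:", cmp$sd, "observed:", cmp$observed,
            "ratio:", cmp$ratio, "\n")
        0L
      },
      `lnc-sites` = {
        genes <- extractSequences(readGeneModels(flags$gtf), flags$genome)
        lncTx <- transcriptIndex(
          extractSequences(readGeneModels(flags$`lnc-gtf`), flags$genome))
        genome <- asGenome(flags$genome)
        for (gene in genes) {
          preSeq <- preMrnaSequence(gene, genome)
          for (lid in names(lncTx)) {
            s <- alignDuplex(lncTx[[lid]]@sequence, preSeq,
                             minScore = num("min-score", 100),
                             minLen = num("min-len", 25))
            if (!nrow(s)) next
            s$lncrna_id <- lid; s$target_gene <- gene@geneId
            utils::write.table(s, stdout(), sep = "\t", quote = FALSE,
                               row.names = FALSE)
          }
        }
        0L
      },
      {
        cliUsage()
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
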