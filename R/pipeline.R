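# Orchestration layer: six rerunnable stages over a working directory,
# mirroring the analysis order (simulate -> build -> annotate -> splice ->
# network -> report). Each stage reads the standard files written by its
# upstream stage, so stages can also be fed externally produced inputs in
# the same formats.

pipelineHeader <- function(seed) {
  c(sprintf(" isoforge %s", as.character(utils::packageVersion("isoforge"))),
    sprintf(" seed=%d", seed),
    sprintf(" date=%s", format(Sys.time(), "%Y-%m-%d")))
}

requireArtifact <- function(path, stage) {
  if (!file.exists(path))
    stopf("dependency error: %s required by stage '%s' is missing; run the upstream stage first",
          path, stage)
  path
}

#' Pipeline stage: simulate
#'
#' Generates a labelled [TruthBundle-class] and writes it under `dir`.
#' @param dir Working directory.
#' @param config A [simulationConfig()].
#' @return The bundle, invisibly.
#' @export
pipelineSimulate <- function(dir, config = simulationConfig()) {
  bundle <- simulateTruthBundle(config)
  writeTruthBundle(bundle, dir)
  invisible(bundle)
}

#' Pipeline stage: build the filtered transcriptome
#'
#' Reads genome, reference, candidates and junction tables from `dir`,
#' classifies, filters and collapses, and writes `transcriptome.gtf` (with
#' class codes) plus `provenance.tsv`.
#' @param dir Working directory.
#' @param config A [filterConfig()].
#' @param seed Seed recorded in output headers.
#' @return The [applyFilters()] result, invisibly.
#' @export
pipelineBuild <- function(dir, config = filterConfig(), seed = 1L) {
  genome <- readGenomeFasta(requireArtifact(file.path(dir, "genome.fa"),
                                            "build"))
  reference <- readTranscriptGTF(requireArtifact(
    file.path(dir, "reference.gtf"), "build"))
  candidates <- readTranscriptGTF(requireArtifact(
    file.path(dir, "candidates.gtf"), "build"))
  sjFiles <- list.files(file.path(dir, "sj"), full.names = TRUE)
  if (length(sjFiles) == 0L)
    stopf("dependency error: no junction tables under %s",
          file.path(dir, "sj"))
  junctions <- readJunctionTables(sjFiles,
    sub("\\.SJ\\.out\\.tab$", "", basename(sjFiles)))
  index <- buildReferenceIndex(reference)
  res <- applyFilters(candidates, genome, junctions, index, config)
  writeTranscriptGTF(res$transcriptome, file.path(dir, "transcriptome.gtf"),
                     header = pipelineHeader(seed))
  write.table(res$provenance, file.path(dir, "provenance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(res)
}

#' Pipeline stage: annotate sequence features
#'
#' Trains a coding model on the transcriptome's own sequences partitioned
#' by ORF quality (see [trainCodingModelFromSet()]), scores all surviving
#' isoforms and writes `features.tsv`.
#' @param dir Working directory.
#' @param seed Seed controlling the training split.
#' @return The feature table, invisibly.
#' @export
pipelineAnnotate <- function(dir, seed = 1L) {
  genome <- readGenomeFasta(requireArtifact(file.path(dir, "genome.fa"),
                                            "annotate"))
  ts <- readTranscriptGTF(requireArtifact(
    file.path(dir, "transcriptome.gtf"), "annotate"))
  repeats <- if (file.exists(file.path(dir, "repeats.bed")))
    readRepeatsBed(file.path(dir, "repeats.bed")) else NULL
  model <- trainCodingModelFromSet(ts, genome, seed = seed)
  feats <- isoformFeatureTable(ts, genome, model, repeats)
  write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(feats)
}

#' Train a coding model from a transcript set
#'
#' Self-supervised surrogate labelling used by the pipeline: transcripts
#' with long, high-coverage ORFs are taken as the coding training class and
#' their codon-shuffled counterparts as the noncoding class; the logistic
#' model then scores all isoforms on the standard four features.
#' @param ts A [TranscriptSet-class].
#' @param genome `DNAStringSet`.
#' @param min_orf ORF length cutoff for the surrogate coding class.
#' @param seed Seed for the shuffling.
#' @return A `CodingModel`.
#' @export
trainCodingModelFromSet <- function(ts, genome, min_orf = 300L, seed = 1L) {
  seqs <- as.character(splicedSequence(ts, genome))
  orfLen <- vapply(seqs, function(s) {
    o <- findBestOrf(s)
    if (is.null(o)) 0L else o$length
  }, 0L)
  coding <- seqs[orfLen >= min_orf]
  if (length(coding) < 5L) coding <- seqs[order(-orfLen)][seq_len(
    min(5L, length(seqs)))]
  noncoding <- withSeed(seed, vapply(coding, function(s) {
    paste(shuffle(strsplit(s, "")[[1]]), collapse = "")
  }, ""))
  trainCodingModel(coding, noncoding)
}

#' Pipeline stage: splicing analysis
#'
#' Extracts AS events, computes event and isoform PSI, tests consecutive
#' stage transitions and clusters switching isoforms; writes `events.tsv`,
#' `event_psi.tsv`, `diff_psi.tsv`.
#' @param dir Working directory.
#' @param c Cluster count for switching isoforms.
#' @param seed Seed for the permutation tests and clustering.
#' @return List with events, PSI matrices, differential results, clusters.
#' @export
pipelineSplice <- function(dir, c = 4L, seed = 1L) {
  ts <- readTranscriptGTF(requireArtifact(
    file.path(dir, "transcriptome.gtf"), "splice"))
  tpmSE <- readExpressionMatrix(requireArtifact(file.path(dir, "tpm.tsv"),
                                                "splice"),
                                requireArtifact(file.path(dir, "design.tsv"),
                                                "splice"), unit = "TPM")
  tpm <- SummarizedExperiment::assay(tpmSE)
  design <- data.frame(sample = colnames(tpm),
                       stage = as.character(tpmSE$stage))
  tpm <- tpm[intersect(rownames(tpm), txIds(ts)), , drop = FALSE]
  events <- extractEvents(ts)
  epsi <- if (nrow(events)) eventPsi(events, tpm) else
    matrix(numeric(), 0, ncol(tpm))
  ipsi <- isoformPsi(ts, tpm)
  stages <- intersect(STAGE_LEVELS, unique(design$stage))
  diffs <- list()
  for (i in seq_len(length(stages) - 1L)) {
    d <- diffPsi(ipsi, design, stages[i], stages[i + 1L], seed = seed)
    d$transition <- paste(stages[i], stages[i + 1L], sep = "_vs_")
    diffs[[i]] <- d
  }
  diffAll <- do.call(rbind, diffs)
  clusters <- clusterSwitchingIsoforms(diffAll, ipsi, design, c = c,
                                       seed = seed)
  write.table(events, file.path(dir, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(events)) writeMatrixTSV(epsi, file.path(dir, "event_psi.tsv"),
                                   "event_id")
  write.table(diffAll, file.path(dir, "diff_psi.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(events = events, event_psi = epsi, isoform_psi = ipsi,
                 diff = diffAll, clusters = clusters, design = design))
}

#' Pipeline stage: co-expression network
#'
#' Normalizes counts, builds the signed TOM, detects and merges modules,
#' tests novelty enrichment; writes `modules.tsv` and `enrichment.tsv`.
#' @param dir Working directory.
#' @param beta Soft-threshold power (default 13).
#' @param min_module_size,cut_height Module detection parameters.
#' @return List with modules, eigengenes, enrichment.
#' @export
pipelineNetwork <- function(dir, beta = 13, min_module_size = 10L,
                            cut_height = 0.99) {
  countsSE <- readExpressionMatrix(
    requireArtifact(file.path(dir, "counts.tsv"), "network"),
    requireArtifact(file.path(dir, "design.tsv"), "network"))
  counts <- SummarizedExperiment::assay(countsSE)
  ts <- readTranscriptGTF(requireArtifact(
    file.path(dir, "transcriptome.gtf"), "network"))
  gene <- setNames(as.character(txData(ts)$gene_id), txIds(ts))
  common <- intersect(rownames(counts), names(gene))
  geneCounts <- rowsum(counts[common, , drop = FALSE], gene[common])
  keep <- rowSums(geneCounts) > 10
  geneCounts <- geneCounts[keep, , drop = FALSE]
  sf <- medianRatioSizeFactors(geneCounts + 1)
  norm <- normalizeLog10(geneCounts, sf)
  adj <- signedAdjacency(norm, beta)
  tom <- topologicalOverlap(adj)
  det <- detectModules(tom, min_module_size, cut_height)
  merged <- mergeModules(norm[rownames(tom), , drop = FALSE], det$module)
  cls <- setNames(as.character(txData(ts)$class_code), txIds(ts))
  geneNovel <- vapply(split(cls[common], gene[common]),
                      function(x) any(x != "known"), NA)
  enr <- if (any(merged$module > 0))
    moduleNovelEnrichment(merged$module,
                          geneNovel[names(merged$module)]) else NULL
  modTab <- data.frame(gene = names(merged$module),
                       module = merged$module,
                       is_novel = as.logical(geneNovel[names(merged$module)]))
  write.table(modTab, file.path(dir, "modules.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(enr))
    write.table(enr, file.path(dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(list(modules = merged$module, eigengenes = merged$eigengenes,
                 enrichment = enr, normalized = norm))
}

#' Pipeline stage: summary report
#'
#' Assembles the class-count/percentage table, per-gene summaries and AS
#' event counts into `report.tsv` files under `dir`.
#' @param dir Working directory.
#' @return List of summary tables, invisibly.
#' @export
pipelineReport <- function(dir) {
  ts <- readTranscriptGTF(requireArtifact(
    file.path(dir, "transcriptome.gtf"), "report"))
  summ <- summarizeClasses(ts)
  write.table(summ$class_table, file.path(dir, "report_classes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summ$gene_table))
    write.table(summ$gene_table, file.path(dir, "report_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  eventsPath <- file.path(dir, "events.tsv")
  if (file.exists(eventsPath)) {
    ev <- read.delim(eventsPath)
    if (nrow(ev)) {
      tab <- as.data.frame(table(ev$type))
      colnames(tab) <- c("type", "count")
      write.table(tab, file.path(dir, "report_events.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  invisible(summ)
}
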