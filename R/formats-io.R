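# Readers and writers for the external formats the pipeline touches. All
# coordinate conversions happen here and nowhere else: internally everything
# is GRanges (1-based closed). GTF and STAR SJ.out.tab are natively 1-based
# closed; BED is 0-based half-open and converted on read.

STAGE_LEVELS <- c("1C", "2C", "4C", "8C", "morula", "blastocyst")

#' Developmental stage order
#'
#' The closed vocabulary of developmental stages used by the stage design,
#' ordered from zygote to blastocyst.
#' @return Character vector of stage names.
#' @export
stageLevels <- function() STAGE_LEVELS

#' Read transcript models from a GTF file
#'
#' Parses GTF2.2 `exon` features carrying `gene_id` and `transcript_id`
#' attributes into a [TranscriptSet-class]. Exons are grouped per transcript
#' and sorted; malformed rows are rejected, not repaired.
#'
#' @param path Path to a GTF file (plain or gzip).
#' @return A `TranscriptSet`. A `class_code` attribute, when present on exon
#'   rows, is carried into `txData`.
#' @export
readTranscriptGTF <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L)
    return(TranscriptSet(GenomicRanges::GRangesList(),
                         S4Vectors::DataFrame(transcript_id = character(),
                                              gene_id = character())))
  if (is.null(gr$gene_id) || is.null(gr$transcript_id))
    stopf("GTF parse error: exon records lack gene_id/transcript_id attributes")
  bad <- which(is.na(gr$gene_id) | is.na(gr$transcript_id))
  if (length(bad))
    stopf("GTF parse error: exon record(s) %s missing gene_id/transcript_id",
          paste(head(bad, 5), collapse = ","))
  txid <- as.character(gr$transcript_id)
  multi <- tapply(seq_along(gr), txid, length) > 1L
  undet <- tapply(as.character(BiocGenerics::strand(gr)), txid,
                  function(s) any(s == "*"))
  if (any(multi & undet))
    stopf("GTF validation error: multi-exon transcript(s) with strand '.': %s",
          paste(names(which(multi & undet)), collapse = ","))
  ord <- unique(txid)
  ex <- GenomicRanges::split(gr, factor(txid, levels = ord))
  td <- S4Vectors::DataFrame(
    transcript_id = ord,
    gene_id = vapply(ex, function(g) as.character(g$gene_id[1]), ""))
  if (!is.null(gr$class_code))
    td$class_code <- vapply(ex, function(g) as.character(g$class_code[1]), "")
  ex <- GenomicRanges::GRangesList(lapply(ex, function(g) {
    GenomicRanges::granges(BiocGenerics::sort(g))
  }))
  TranscriptSet(ex, td)
}

#' Write transcript models to a GTF file
#'
#' Emits `gene`, `transcript` and `exon` lines in 1-based inclusive GTF
#' coordinates with `gene_id` and `transcript_id` first in the attribute
#' field; a `class_code` column of `txData`, when present, is written on
#' every feature of the transcript. Exons are written ascending by coordinate
#' on both strands (GTF convention).
#'
#' @param ts A [TranscriptSet-class].
#' @param path Output path.
#' @param header Optional comment lines (without leading `#`).
#' @return `path`, invisibly.
#' @export
writeTranscriptGTF <- function(ts, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("#", h), con)
  if (length(ts) == 0L) return(invisible(path))
  td <- txData(ts)
  hasClass <- "class_code" %in% colnames(td)
  lines <- character()
  genes <- split(seq_len(length(ts)), as.character(td$gene_id))
  for (g in names(genes)) {
    idx <- genes[[g]]
    allex <- BiocGenerics::unlist(ts@exons[idx], use.names = FALSE)
    contig <- as.character(GenomicRanges::seqnames(allex))[1]
    strand <- as.character(BiocGenerics::strand(allex))[1]
    attrG <- sprintf('gene_id "%s";', g)
    lines <- c(lines, paste(contig, "isoforge", "gene",
                            min(BiocGenerics::start(allex)),
                            max(BiocGenerics::end(allex)),
                            ".", strand, ".", attrG, sep = "\t"))
    for (i in idx) {
      ex <- ts@exons[[i]]
      attrT <- sprintf('gene_id "%s"; transcript_id "%s";', g,
                       td$transcript_id[i])
      if (hasClass && !is.na(td$class_code[i]))
        attrT <- sprintf('%s class_code "%s";', attrT, td$class_code[i])
      lines <- c(lines, paste(contig, "isoforge", "transcript",
                              min(BiocGenerics::start(ex)),
                              max(BiocGenerics::end(ex)),
                              ".", strand, ".", attrT, sep = "\t"))
      lines <- c(lines, paste(contig, "isoforge", "exon",
                              BiocGenerics::start(ex), BiocGenerics::end(ex),
                              ".", strand, ".", attrT, sep = "\t"))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet` (names truncated at first whitespace).
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read STAR splice-junction tables
#'
#' Reads one SJ.out.tab-style file per sample (9 tab-separated columns:
#' contig, 1-based intron start, 1-based intron end, strand code 0/1/2,
#' motif code, annotated flag, unique-read count, multi-read count, max
#' overhang) into one long-format junction evidence table. Strand code 0
#' (undetermined, what STAR emits for noncanonical junctions) is retained as
#' `*`; junction matching downstream is on coordinates only.
#'
#' @param paths Character vector of file paths.
#' @param sample_ids Sample identifiers, defaults to basenames.
#' @return A data.frame with columns `sample`, `contig`, `start`, `end`,
#'   `strand`, `unique_count`, `multi_count`.
#' @export
readJunctionTables <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- sub("\\.tab(\\.gz)?$", "", basename(paths))
  stopifnot(length(paths) == length(sample_ids))
  out <- lapply(seq_along(paths), function(i) {
    p <- paths[i]
    if (!file.exists(p)) stopf("SJ table not found: %s", p)
    df <- read.table(p, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE, fill = TRUE)
    if (ncol(df) != 9L || anyNA(df))
      stopf("SJ parse error in %s: expected 9 columns, got %d", p, ncol(df))
    df[[1]] <- as.character(df[[1]])
    bad <- which(df[[3]] < df[[2]])
    if (length(bad))
      stopf("SJ parse error in %s, line %d: intron end < start", p, bad[1])
    data.frame(sample = sample_ids[i], contig = df[[1]],
               start = df[[2]], end = df[[3]],
               strand = c("*", "+", "-")[df[[4]] + 1L],
               unique_count = df[[7]], multi_count = df[[8]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write STAR-style splice-junction tables
#'
#' One SJ.out.tab-dialect file per sample under `dir`.
#' @param junctions Long-format junction table as from [readJunctionTables()].
#' @param dir Output directory.
#' @return Named vector of written paths.
#' @export
writeJunctionTables <- function(junctions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- unique(junctions$sample)
  paths <- setNames(file.path(dir, paste0(samples, ".SJ.out.tab")), samples)
  for (s in samples) {
    df <- junctions[junctions$sample == s, , drop = FALSE]
    out <- data.frame(df$contig, df$start, df$end,
                      match(df$strand, c("*", "+", "-")) - 1L,
                      0L, 0L, df$unique_count, df$multi_count, 20L)
    write.table(out, paths[[s]], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  paths
}

#' Read a repeat annotation (BED6+2)
#'
#' BED6 plus two extra columns (repeat class, repeat family); the BED `name`
#' column is the repeat name. BED's 0-based half-open coordinates are
#' converted to 1-based closed.
#'
#' @param path Path to the BED file.
#' @return A `GRanges` with metadata columns `repeat_name`, `repeat_class`,
#'   `repeat_family`.
#' @export
readRepeatsBed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) != 8L)
    stopf("BED parse error in %s: expected 8 columns, got %d", path, ncol(df))
  bad <- which(df[[3]] <= df[[2]])
  if (length(bad))
    stopf("BED parse error in %s, line %d: end <= start", path, bad[1])
  GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]),
                         strand = df[[6]], repeat_name = df[[4]],
                         repeat_class = df[[7]], repeat_family = df[[8]])
}

#' Write a repeat annotation as BED6+2
#' @param repeats `GRanges` with `repeat_name`, `repeat_class`,
#'   `repeat_family` metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRepeatsBed <- function(repeats, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(repeats)),
                   BiocGenerics::start(repeats) - 1L,
                   BiocGenerics::end(repeats),
                   repeats$repeat_name, 0L,
                   as.character(BiocGenerics::strand(repeats)),
                   repeats$repeat_class, repeats$repeat_family)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix with its stage design
#'
#' The matrix is a TSV with a header row of sample ids and row ids in the
#' first column; the design a two-column TSV (`sample`, `stage`) over the
#' closed stage vocabulary [stageLevels()]. Every matrix sample must appear
#' in the design.
#'
#' @param path Path to the matrix TSV.
#' @param design_path Path to the design TSV.
#' @param unit Unit tag, e.g. `"counts"` or `"TPM"`.
#' @return A `SummarizedExperiment` with one assay named `unit` and `stage`
#'   in `colData`.
#' @export
readExpressionMatrix <- function(path, design_path, unit = "counts") {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  mat <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  if (anyDuplicated(rownames(mat))) stopf("duplicate row ids in %s", path)
  if (any(mat < 0)) stopf("negative values in %s", path)
  design <- readStageDesign(design_path)
  missing <- setdiff(colnames(mat), design$sample)
  if (length(missing))
    stopf("validation error: sample(s) %s absent from design",
          paste(missing, collapse = ","))
  design <- design[match(colnames(mat), design$sample), ]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = setNames(list(mat), unit),
    colData = S4Vectors::DataFrame(sample = design$sample,
                                   stage = design$stage,
                                   row.names = design$sample))
  se
}

#' Read a two-column stage design TSV
#' @param path Path to a TSV with columns `sample` and `stage`.
#' @return data.frame with `sample` and ordered-factor `stage`.
#' @export
readStageDesign <- function(path) {
  if (!file.exists(path)) stopf("design file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "stage") %in% colnames(df)))
    stopf("design must have columns sample, stage")
  unknown <- setdiff(df$stage, STAGE_LEVELS)
  if (length(unknown))
    stopf("validation error: unknown stage(s): %s",
          paste(unique(unknown), collapse = ","))
  df$stage <- factor(df$stage, levels = STAGE_LEVELS, ordered = TRUE)
  df
}

#' Read a tabular alignment-hit table
#'
#' BLAST-like TSV with header columns `query_id`, `target_genome`,
#' `align_length`, `percent_identity`, `evalue`.
#' @param path Path to the TSV.
#' @return data.frame with those columns.
#' @export
readHitTable <- function(path) {
  if (!file.exists(path)) stopf("hit table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "target_genome", "align_length",
            "percent_identity", "evalue")
  if (!all(need %in% colnames(df)))
    stopf("hit-table parse error: missing column(s) %s",
          paste(setdiff(need, colnames(df)), collapse = ","))
  if (!is.numeric(df$align_length) || !is.numeric(df$percent_identity) ||
      !is.numeric(df$evalue))
    stopf("hit-table parse error: non-numeric alignment statistics")
  df
}

#' Read BED6 peak intervals (eCLIP-style)
#' @param path Path to a BED6 file; the name column identifies the binding
#'   factor.
#' @return `GRanges` with a `factor_id` metadata column.
#' @export
readPeaksBed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L)
    stopf("BED parse error in %s: expected >= 6 columns", path)
  GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]),
                         strand = df[[6]], factor_id = df[[4]])
}

# Write a matrix as row-id TSV.
writeMatrixTSV <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
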