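# Isoform-level quality filters applied in a fixed order with per-isoform
# provenance: minimum spliced length, intra-priming (genomic A-rich tract
# downstream of the TES), short-read junction support, and structural-class
# exclusion.

#' Filter configuration
#'
#' @param min_length Minimum spliced length in bp; isoforms shorter than
#'   this are flagged (default 200; "at least 200 bp" passes).
#' @param a_fraction_threshold Intra-priming flag when the A fraction of the
#'   downstream window is strictly greater than this (default 0.6).
#' @param a_window Window length in bases downstream of the TES, in
#'   transcript orientation (default 20).
#' @param min_supported_samples Number of samples in which each junction
#'   needs uniquely mapped spliced reads (default 3).
#' @param min_unique_reads Minimum unique-read count per sample (default 1).
#' @param drop_classes Structural classes excluded from the final
#'   transcriptome (default ISM and mono_exonic_novel).
#' @param per_sample_complete If `TRUE`, a stricter junction rule: at least
#'   `min_supported_samples` samples must each support *all* junctions of
#'   the isoform (default `FALSE`: each junction independently needs support
#'   in enough samples).
#' @return A validated list of class `FilterConfig`.
#' @export
filterConfig <- function(min_length = 200L, a_fraction_threshold = 0.6,
                         a_window = 20L, min_supported_samples = 3L,
                         min_unique_reads = 1L,
                         drop_classes = c("ISM", "mono_exonic_novel"),
                         per_sample_complete = FALSE) {
  if (min_length <= 0 || a_window <= 0 || min_supported_samples <= 0 ||
      min_unique_reads <= 0)
    stopf("configuration error: filter thresholds must be positive")
  if (a_fraction_threshold < 0 || a_fraction_threshold > 1)
    stopf("configuration error: a_fraction_threshold must be in [0,1]")
  if (!all(drop_classes %in% STRUCTURAL_CLASSES))
    stopf("configuration error: unknown drop class(es): %s",
          paste(setdiff(drop_classes, STRUCTURAL_CLASSES), collapse = ","))
  structure(list(min_length = as.integer(min_length),
                 a_fraction_threshold = a_fraction_threshold,
                 a_window = as.integer(a_window),
                 min_supported_samples = as.integer(min_supported_samples),
                 min_unique_reads = as.integer(min_unique_reads),
                 drop_classes = drop_classes,
                 per_sample_complete = per_sample_complete),
            class = "FilterConfig")
}

#' Flag isoforms below the minimum spliced length
#'
#' @param ts A [TranscriptSet-class].
#' @param config A [filterConfig()].
#' @return Named logical: `TRUE` where the spliced length (sum of exon
#'   lengths) is strictly below `min_length`.
#' @export
flagMinLength <- function(ts, config = filterConfig()) {
  splicedLength(ts) < config$min_length
}

#' Flag intra-priming artifacts
#'
#' Takes the `a_window` genomic bases immediately downstream of the TES in
#' transcript orientation (plus strand: after the last exon end, read
#' as-is; minus strand: before the first exon start, reverse-complemented)
#' and flags the isoform when the A fraction is strictly greater than the
#' threshold. A window truncated by the contig end is computed on the
#' available bases; an empty window is never flagged.
#'
#' @param ts A [TranscriptSet-class].
#' @param genome A `DNAStringSet`.
#' @param config A [filterConfig()].
#' @return Named logical per isoform, with the observed A fraction as a
#'   `a_fraction` attribute.
#' @export
flagIntraPriming <- function(ts, genome, config = filterConfig()) {
  pc <- txChainsPlain(ts)
  out <- logical(length(ts))
  frac <- numeric(length(ts))
  seqCache <- list()
  for (i in seq_len(length(ts))) {
    contig <- pc$contig[i]
    if (!contig %in% names(genome))
      stopf("coordinate error: contig %s absent from genome", contig)
    if (is.null(seqCache[[contig]]))
      seqCache[[contig]] <- as.character(genome[[contig]])
    cl <- nchar(seqCache[[contig]])
    strand <- pc$strand[i]
    if (strand == "+") {
      tes <- pc$exEnds[[i]][length(pc$exEnds[[i]])]
      lo <- tes + 1L; hi <- min(tes + config$a_window, cl)
    } else {
      tes <- pc$exStarts[[i]][1]
      lo <- max(1L, tes - config$a_window); hi <- tes - 1L
    }
    if (lo > hi) { out[i] <- FALSE; frac[i] <- 0; next }
    win <- substr(seqCache[[contig]], lo, hi)
    if (strand == "-") win <- revComp(win)
    nA <- sum(strsplit(win, "")[[1]] == "A")
    frac[i] <- nA / nchar(win)
    out[i] <- frac[i] > config$a_fraction_threshold
  }
  names(out) <- txIds(ts)
  attr(out, "a_fraction") <- setNames(frac, txIds(ts))
  out
}

#' Flag isoforms lacking short-read junction support
#'
#' For each intron, counts the samples whose unique spliced-read count at
#' the exactly matching intron coordinates is at least `min_unique_reads`;
#' the isoform is flagged when any intron is supported in fewer than
#' `min_supported_samples` samples. Matching is on (contig, start, end)
#' only, so junctions whose table strand is undetermined still match.
#' Mono-exonic isoforms are vacuously unflagged.
#'
#' @param ts A [TranscriptSet-class].
#' @param junctions Long-format junction table (see
#'   [readJunctionTables()]).
#' @param config A [filterConfig()].
#' @return Named logical per isoform, with the per-isoform minimum
#'   supported-sample count as a `min_junction_samples` attribute
#'   (`NA` for mono-exonic isoforms).
#' @export
flagJunctionSupport <- function(ts, junctions, config = filterConfig()) {
  pc <- txChainsPlain(ts)
  jx <- junctions[junctions$unique_count >= config$min_unique_reads, ,
                  drop = FALSE]
  jkey <- paste(jx$contig, jx$start, jx$end)
  # samples with qualifying unique counts, per junction key
  supCount <- vapply(split(jx$sample, jkey),
                     function(s) length(unique(s)), 0L)
  bySample <- if (config$per_sample_complete) split(jkey, jx$sample)
              else NULL
  out <- logical(length(ts))
  minSup <- rep(NA_integer_, length(ts))
  for (i in seq_len(length(ts))) {
    if (length(pc$intrStarts[[i]]) == 0L) { out[i] <- FALSE; next }
    keys <- paste(pc$contig[i], pc$intrStarts[[i]], pc$intrEnds[[i]])
    if (config$per_sample_complete) {
      nComplete <- sum(vapply(bySample, function(k) all(keys %in% k), NA))
      minSup[i] <- nComplete
      out[i] <- nComplete < config$min_supported_samples
    } else {
      nSup <- supCount[keys]
      nSup[is.na(nSup)] <- 0L
      minSup[i] <- min(nSup)
      out[i] <- any(nSup < config$min_supported_samples)
    }
  }
  names(out) <- txIds(ts)
  attr(out, "min_junction_samples") <- setNames(minSup, txIds(ts))
  out
}

#' Apply all isoform filters in pipeline order
#'
#' Pipeline order: minimum length, intra-priming, transcript-model collapse,
#' structural classification (and novel-gene assignment), junction support,
#' and class exclusion. An isoform survives iff no flag is set and its class
#' is not excluded; every flag is recorded for every input isoform (no
#' short-circuiting of provenance). Collapsed-away members inherit the
#' record of their representative and are marked in the provenance.
#'
#' @param candidates An unclassified candidate [TranscriptSet-class].
#' @param genome A `DNAStringSet`.
#' @param junctions Long-format junction table.
#' @param index A [ReferenceIndex-class].
#' @param config A [filterConfig()].
#' @param collapse_wobble Terminal wobble for [collapseModels()].
#' @return List with `transcriptome` (surviving classified `TranscriptSet`),
#'   `classified` (all collapsed candidates, classified), `provenance`
#'   (data.frame: isoform_id, class, spliced_length, a_fraction,
#'   min_junction_samples, flags, collapsed_into, survived) and `map` (the
#'   collapse map).
#' @export
applyFilters <- function(candidates, genome, junctions, index,
                         config = filterConfig(), collapse_wobble = 1000L) {
  # Every flag is computed for every input isoform. Classification and
  # junction support are invariant under the collapse (merged models share
  # the intron chain that both depend on), so flags are evaluated per
  # member and the collapse then reduces the surviving members to final
  # representative models.
  shortFlag <- flagMinLength(candidates, config)
  ipFlag <- flagIntraPriming(candidates, genome, config)
  aFrac <- attr(ipFlag, "a_fraction")
  classified <- classifyTranscripts(candidates, index)
  classified <- assignNovelGenes(classified)
  jFlag <- flagJunctionSupport(classified, junctions, config)
  minJ <- attr(jFlag, "min_junction_samples")
  td <- txData(classified)
  cls <- as.character(td$class_code)
  exFlag <- cls %in% config$drop_classes

  ids <- txIds(candidates)
  flagsTab <- data.frame(
    isoform_id = ids,
    class = cls,
    spliced_length = as.integer(splicedLength(candidates)[ids]),
    a_fraction = round(aFrac[ids], 4),
    min_junction_samples = as.integer(minJ[ids]),
    short_length = as.logical(shortFlag[ids]),
    intra_priming = as.logical(ipFlag[ids]),
    junction_unsupported = as.logical(jFlag[ids]),
    excluded_class = exFlag,
    stringsAsFactors = FALSE)
  flagsTab$flags <- apply(flagsTab[, c("short_length", "intra_priming",
                                       "junction_unsupported",
                                       "excluded_class")], 1, function(fl)
    paste(c("short_length", "intra_priming", "junction_unsupported",
            "excluded_class")[as.logical(fl)], collapse = ";"))
  flagsTab$survived <- as.integer(!flagsTab$short_length &
    !flagsTab$intra_priming & !flagsTab$junction_unsupported &
    !flagsTab$excluded_class)

  surviving <- flagsTab$isoform_id[flagsTab$survived == 1L]
  kept <- classified[match(surviving, txIds(classified))]
  col <- collapseModels(kept, collapse_wobble)
  repOf <- setNames(col$map$representative, col$map$member)
  flagsTab$collapsed_into <- ""
  hit <- match(flagsTab$isoform_id, names(repOf))
  present <- which(!is.na(hit))
  reps <- repOf[hit[present]]
  merged <- present[reps != flagsTab$isoform_id[present]]
  flagsTab$collapsed_into[merged] <- repOf[hit[merged]]
  rownames(flagsTab) <- NULL
  list(transcriptome = col$collapsed, classified = classified,
       provenance = flagsTab, map = col$map)
}
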