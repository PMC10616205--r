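#' TranscriptSet: a collection of transcript models
#'
#' A `TranscriptSet` holds one transcript model per element: an ordered set of
#' exons on one contig and strand, together with per-transcript metadata
#' (`transcript_id`, `gene_id`, and any annotation columns added downstream,
#' e.g. the structural `class_code`). Exons are stored as a
#' [GenomicRanges::GRangesList] in the usual Bioconductor 1-based closed
#' convention; introns are the gaps between consecutive exons.
#'
#' @slot exons A `GRangesList`, one element per transcript, names equal to
#'   `transcript_id`.
#' @slot txData A `DataFrame` parallel to `exons` with at least columns
#'   `transcript_id` and `gene_id`.
#'
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @export
setClass("TranscriptSet",
  representation(exons = "GRangesList", txData = "DataFrame"))

setValidity("TranscriptSet", function(object) {
  ex <- object@exons
  td <- object@txData
  if (length(ex) != nrow(td))
    return("exons and txData lengths differ")
  if (!all(c("transcript_id", "gene_id") %in% colnames(td)))
    return("txData must have transcript_id and gene_id columns")
  if (length(ex) == 0L) return(TRUE)
  if (anyDuplicated(td$transcript_id))
    return("duplicate transcript_id")
  if (!identical(names(ex), as.character(td$transcript_id)))
    return("names(exons) must equal txData$transcript_id")
  n <- S4Vectors::elementNROWS(ex)
  if (any(n < 1L)) return("every transcript needs >= 1 exon")
  # one contig+strand per transcript, exons sorted and disjoint
  flat <- BiocGenerics::unlist(ex, use.names = FALSE)
  grp <- rep(seq_along(ex), n)
  if (any(tapply(as.character(GenomicRanges::seqnames(flat)), grp,
                 function(x) length(unique(x))) > 1L))
    return("transcript spans multiple contigs")
  if (any(tapply(as.character(BiocGenerics::strand(flat)), grp,
                 function(x) length(unique(x))) > 1L))
    return("transcript mixes strands")
  st <- BiocGenerics::start(flat); en <- BiocGenerics::end(flat)
  bad <- tapply(seq_along(st), grp, function(i) {
    s <- st[i]; e <- en[i]
    any(e < s) || is.unsorted(s, strictly = TRUE) ||
      (length(i) > 1L && any(s[-1] <= e[-length(i)]))
  })
  if (any(bad))
    return(paste0("unsorted or overlapping exons in transcript(s): ",
                  paste(names(ex)[which(bad)], collapse = ", ")))
  TRUE
})

#' Construct a TranscriptSet
#'
#' @param exons `GRangesList` of exons, one element per transcript.
#' @param txData `DataFrame` or data.frame with `transcript_id`, `gene_id` and
#'   optional annotation columns, parallel to `exons`.
#' @return A [TranscriptSet-class] object.
#' @export
TranscriptSet <- function(exons, txData) {
  if (is.data.frame(txData)) txData <- S4Vectors::DataFrame(txData)
  exons <- GenomicRanges::GRangesList(lapply(exons, function(gr) {
    BiocGenerics::sort(gr)
  }))
  names(exons) <- as.character(txData$transcript_id)
  new("TranscriptSet", exons = exons, txData = txData)
}

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object@exons), "transcripts from",
      length(unique(object@txData$gene_id)), "genes\n")
  if ("class_code" %in% colnames(object@txData)) {
    tb <- table(object@txData$class_code)
    cat("  classes:", paste(names(tb), tb, sep = ":", collapse = " "), "\n")
  }
})

#' @describeIn TranscriptSet Number of transcripts.
#' @param x,object A `TranscriptSet`.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' Accessors for TranscriptSet
#'
#' `txExons()` returns the exon `GRangesList`; `txData()` the per-transcript
#' metadata; `txIds()` the transcript identifiers; `txSpans()` one genomic
#' range per transcript; `txIntrons()` the intron `GRangesList` (empty
#' elements for mono-exonic models); `splicedLength()` the summed exon length.
#'
#' @param ts A `TranscriptSet`.
#' @return See individual descriptions.
#' @export
txExons <- function(ts) ts@exons

#' @rdname txExons
#' @export
txData <- function(ts) ts@txData

#' @rdname txExons
#' @export
txIds <- function(ts) as.character(ts@txData$transcript_id)

#' @rdname txExons
#' @export
txSpans <- function(ts) {
  if (length(ts) == 0L)
    return(GenomicRanges::GRanges())
  sp <- BiocGenerics::unlist(range(ts@exons), use.names = FALSE)
  names(sp) <- txIds(ts)
  sp
}

#' @rdname txExons
#' @export
txIntrons <- function(ts) {
  ex <- ts@exons
  res <- lapply(seq_along(ex), function(i) {
    gr <- ex[[i]]
    if (length(gr) < 2L) {
      out <- gr[0]
    } else {
      out <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(gr)[1],
        IRanges::IRanges(BiocGenerics::end(gr)[-length(gr)] + 1L,
                         BiocGenerics::start(gr)[-1] - 1L),
        strand = BiocGenerics::strand(gr)[1])
    }
    out
  })
  names(res) <- names(ex)
  GenomicRanges::GRangesList(res)
}

#' @rdname txExons
#' @export
splicedLength <- function(ts) {
  setNames(vapply(ts@exons, function(gr) sum(BiocGenerics::width(gr)), 0L),
           txIds(ts))
}

#' Subset a TranscriptSet
#' @param i Index, logical vector or transcript ids.
#' @param j,drop,... Ignored.
#' @rdname TranscriptSet-class
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, txIds(x))
  new("TranscriptSet", exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

# Plain-vector view of a TranscriptSet (no per-element S4 access): exon and
# intron start/end integer vectors per transcript plus contig/strand.
# Internal fast path for the hot loops.
txChainsPlain <- function(ts) {
  ex <- ts@exons
  n <- length(ex)
  nEx <- S4Vectors::elementNROWS(ex)
  flat <- BiocGenerics::unlist(ex, use.names = FALSE)
  grp <- rep(seq_len(n), nEx)
  first <- !duplicated(grp)
  st <- unname(split(BiocGenerics::start(flat), factor(grp, seq_len(n))))
  en <- unname(split(BiocGenerics::end(flat), factor(grp, seq_len(n))))
  list(contig = as.character(GenomicRanges::seqnames(flat))[first],
       strand = as.character(BiocGenerics::strand(flat))[first],
       exStarts = st, exEnds = en,
       intrStarts = lapply(en, function(e)
         if (length(e) < 2L) integer() else e[-length(e)] + 1L),
       intrEnds = lapply(st, function(s)
         if (length(s) < 2L) integer() else s[-1] - 1L))
}

# Intron chain key: canonical string identity of an intron chain used for
# known/ISM matching and collapse grouping. Mono-exonic -> "".
intronChainKey <- function(introns, contig, strand) {
  if (length(introns) == 0L) return(sprintf("%s:%s:", contig, strand))
  sprintf("%s:%s:%s", contig, strand,
          paste(BiocGenerics::start(introns), BiocGenerics::end(introns),
                sep = "-", collapse = ","))
}

#' ReferenceIndex: lookup structures over a reference annotation
#'
#' Splice-site sets, the intron-chain registry and interval indexes derived
#' from a reference [TranscriptSet-class], used by [classifyTranscripts()].
#' Donors and acceptors are strand-resolved genomic positions: for a `+`
#' intron the donor is its first base and the acceptor its last base; on `-`
#' the roles swap.
#'
#' @slot reference The reference `TranscriptSet`.
#' @slot donors,acceptors Named lists keyed `contig:strand` of sorted
#'   integer positions.
#' @slot geneDonors,geneAcceptors Named lists keyed by gene id.
#' @slot chains Named character: intron-chain key -> comma-joined reference
#'   transcript ids.
#' @slot chainList Per-reference-transcript intron chains (list of
#'   two-column matrices) for contiguous-subchain (ISM) matching.
#' @slot geneSpans `GRanges` of gene extents (strand-resolved).
#' @slot txSpans `GRanges` of transcript extents.
#' @slot exons The reference exon `GRangesList`.
#' @export
setClass("ReferenceIndex",
  representation(reference = "TranscriptSet", donors = "list",
                 acceptors = "list", geneDonors = "list",
                 geneAcceptors = "list", chains = "character",
                 chainList = "list", geneSpans = "GRanges",
                 txSpans = "GRanges", exons = "GRangesList"))

setValidity("ReferenceIndex", function(object) {
  if (length(object@geneSpans) != length(unique(txData(object@reference)$gene_id)))
    return("geneSpans does not match reference gene set")
  TRUE
})

setMethod("show", "ReferenceIndex", function(object) {
  cat("ReferenceIndex:", length(object@reference), "reference transcripts,",
      length(object@geneSpans), "genes,",
      sum(lengths(object@donors)), "donor and",
      sum(lengths(object@acceptors)), "acceptor sites\n")
})

#' TruthBundle: a fully labelled synthetic dataset
#'
#' Output of [simulateTruthBundle()]: a toy genome, reference annotation,
#' candidate isoforms with truth structural-class labels, per-sample junction
#' evidence, repeat annotation, stage-structured expression and per-isoform
#' expected filter outcomes, so every pipeline stage has a ground-truth
#' oracle.
#'
#' @slot genome `DNAStringSet` of contig sequences.
#' @slot reference,candidates `TranscriptSet`s; candidate `txData` carries
#'   `true_class`.
#' @slot junctions Junction evidence table (see [readJunctionTables()]).
#' @slot repeats `GRanges` of repeat intervals with `repeat_name`,
#'   `repeat_class`, `repeat_family`.
#' @slot expression List with `counts`, `tpm`, `length`, `design`.
#' @slot truth `DataFrame` of per-candidate expected filter outcomes.
#' @slot config The `SimulationConfig` used.
#' @export
setClass("TruthBundle",
  representation(genome = "DNAStringSet", reference = "TranscriptSet",
                 candidates = "TranscriptSet", junctions = "data.frame",
                 repeats = "GRanges", expression = "list",
                 truth = "DataFrame", config = "list"))

setMethod("show", "TruthBundle", function(object) {
  cat("TruthBundle (seed ", object@config$seed, "): ",
      length(object@reference), " reference tx, ",
      length(object@candidates), " candidates, ",
      length(unique(object@junctions$sample)), " junction samples\n", sep = "")
})
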