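# Structural classification of candidate isoforms against a reference
# annotation: known / ISM / NIC / NNC / antisense / intergenic /
# mono_exonic_novel, plus novel-gene formation, transcript-model collapsing,
# splice-site canonicality auditing and printed-summary arithmetic.

#' Build a ReferenceIndex
#'
#' Derives strand-resolved donor/acceptor site sets (globally and per gene),
#' the intron-chain registry, per-transcript chains for contiguous-subchain
#' (ISM) matching, and gene/transcript span indexes from a reference
#' annotation. Idempotent: rebuilding from the same reference yields an
#' identical index.
#'
#' @param reference A reference [TranscriptSet-class].
#' @return A [ReferenceIndex-class].
#' @export
buildReferenceIndex <- function(reference) {
  td <- txData(reference)
  geneIds <- as.character(td$gene_id)
  ex <- txExons(reference)
  if (length(reference) > 0L) {
    strandByGene <- tapply(vapply(seq_along(ex), function(i)
      as.character(BiocGenerics::strand(ex[[i]]))[1], ""), geneIds,
      function(s) length(unique(s)))
    if (any(strandByGene > 1L))
      stopf("validation error: strand-inconsistent gene(s): %s",
            paste(names(which(strandByGene > 1L)), collapse = ","))
  }
  intr <- txIntrons(reference)
  donors <- list(); acceptors <- list()
  chains <- character(); chainList <- list()
  for (i in seq_along(intr)) {
    gr <- intr[[i]]
    contig <- as.character(GenomicRanges::seqnames(ex[[i]]))[1]
    strand <- as.character(BiocGenerics::strand(ex[[i]]))[1]
    key <- sprintf("%s:%s", contig, strand)
    if (length(gr) > 0L) {
      s <- BiocGenerics::start(gr); e <- BiocGenerics::end(gr)
      if (strand == "+") {
        donors[[key]] <- c(donors[[key]], s)
        acceptors[[key]] <- c(acceptors[[key]], e)
      } else {
        donors[[key]] <- c(donors[[key]], e)
        acceptors[[key]] <- c(acceptors[[key]], s)
      }
      chainList[[txIds(reference)[i]]] <- cbind(start = s, end = e)
    } else {
      chainList[[txIds(reference)[i]]] <- cbind(start = integer(),
                                                end = integer())
    }
    ck <- intronChainKey(gr, contig, strand)
    chains[ck] <- if (is.na(chains[ck])) txIds(reference)[i]
                  else paste(chains[ck], txIds(reference)[i], sep = ",")
  }
  donors <- lapply(donors, function(x) sort(unique(x)))
  acceptors <- lapply(acceptors, function(x) sort(unique(x)))
  gs <- geneSiteSets(reference)
  geneSpans <- GenomicRanges::GRanges()
  if (length(reference) > 0L) {
    flat <- BiocGenerics::unlist(ex, use.names = FALSE)
    grp <- factor(rep(geneIds, S4Vectors::elementNROWS(ex)))
    geneSpans <- BiocGenerics::unlist(
      range(GenomicRanges::split(flat, grp)))
    names(geneSpans) <- levels(grp)
  }
  new("ReferenceIndex", reference = reference, donors = donors,
      acceptors = acceptors, geneDonors = gs$donors,
      geneAcceptors = gs$acceptors, chains = chains[!is.na(chains)],
      chainList = chainList, geneSpans = geneSpans,
      txSpans = txSpans(reference), exons = ex)
}

# Is `sub` (k x 2 matrix) a contiguous run of `full` (m x 2)? Proper or not.
isContiguousSubchain <- function(sub, full) {
  k <- nrow(sub); m <- nrow(full)
  if (k > m || k == 0L) return(FALSE)
  for (off in 0:(m - k)) {
    if (all(full[off + seq_len(k), 1] == sub[, 1]) &&
        all(full[off + seq_len(k), 2] == sub[, 2])) return(TRUE)
  }
  FALSE
}

# Reference gene with maximal same-strand exonic overlap with `exons`;
# ties -> smallest gene span, then lexicographic id. NA when no overlap.
assignGeneByOverlap <- function(exons, index) {
  refFlat <- BiocGenerics::unlist(index@exons, use.names = FALSE)
  refGene <- rep(as.character(txData(index@reference)$gene_id),
                 S4Vectors::elementNROWS(index@exons))
  hits <- GenomicRanges::findOverlaps(exons, refFlat, ignore.strand = FALSE)
  if (length(hits) == 0L) return(NA_character_)
  ov <- BiocGenerics::width(IRanges::pintersect(
    exons[S4Vectors::queryHits(hits)], refFlat[S4Vectors::subjectHits(hits)]))
  byGene <- tapply(ov, refGene[S4Vectors::subjectHits(hits)], sum)
  best <- max(byGene)
  tied <- names(byGene)[byGene == best]
  if (length(tied) > 1L) {
    w <- BiocGenerics::width(index@geneSpans[tied])
    tied <- tied[w == min(w)]
    tied <- sort(tied)
  }
  tied[1]
}

#' Classify candidate isoforms into structural classes
#'
#' Applies the structural decision procedure per candidate: an intron chain
#' identical to a reference chain is `known`; a contiguous proper subchain of
#' a reference chain is `ISM`; a novel chain whose donors and acceptors are
#' all individually present in the assigned gene's site sets is `NIC`
#' (novel in catalog); a chain with at least one novel splice site on a
#' candidate overlapping a same-strand reference transcript is `NNC` (novel
#' not in catalog); candidates with no same-strand reference-transcript
#' overlap are `antisense` when they overlap a gene on the opposite strand
#' and `intergenic` otherwise. Single-exon candidates in antisense or
#' intergenic position are `mono_exonic_novel`; single-exon candidates
#' overlapping a same-strand reference are `known` when matching a
#' mono-exonic reference model and `ISM` (a terminal fragment) otherwise.
#' The assigned gene is the reference gene with maximal same-strand exonic
#' overlap (ties: smallest span, then lexicographic id).
#'
#' @param candidates A [TranscriptSet-class] of candidates.
#' @param index A [ReferenceIndex-class].
#' @param site_scope `"gene"` (default): NIC requires all sites within the
#'   assigned gene's site sets; `"genome"`: sites may come from any gene on
#'   the same contig/strand.
#' @return `candidates` with `txData` columns `class_code`, `assigned_gene`
#'   and `mono_exonic` added. Classification is a total, deterministic,
#'   order-independent function.
#' @export
classifyTranscripts <- function(candidates, index,
                                site_scope = c("gene", "genome")) {
  site_scope <- match.arg(site_scope)
  n <- length(candidates)
  cls <- character(n); gene <- rep(NA_character_, n)
  ex <- txExons(candidates)
  nEx <- S4Vectors::elementNROWS(ex)
  flat <- BiocGenerics::unlist(ex, use.names = FALSE)
  grp <- rep(seq_len(n), nEx)
  first <- !duplicated(grp)
  txContig <- as.character(GenomicRanges::seqnames(flat))[first]
  txStrand <- as.character(BiocGenerics::strand(flat))[first]
  exStarts <- unname(split(BiocGenerics::start(flat), grp))
  exEnds <- unname(split(BiocGenerics::end(flat), grp))
  refTx <- index@txSpans
  refTxMono <- vapply(index@chainList, nrow, 0L)[names(refTx)] == 0L

  spans <- txSpans(candidates)
  sameHits <- GenomicRanges::findOverlaps(spans, refTx,
                                          ignore.strand = FALSE)
  oppSpans <- spans
  BiocGenerics::strand(oppSpans) <- ifelse(txStrand == "+", "-", "+")
  oppHits <- GenomicRanges::findOverlaps(oppSpans, refTx,
                                         ignore.strand = FALSE)
  hasSame <- tabulate(S4Vectors::queryHits(sameHits), n) > 0L
  hasOpp <- tabulate(S4Vectors::queryHits(oppHits), n) > 0L
  sameList <- split(S4Vectors::subjectHits(sameHits),
                    factor(S4Vectors::queryHits(sameHits), seq_len(n)))

  # batch same-strand exonic-overlap gene assignment
  refFlat <- BiocGenerics::unlist(index@exons, use.names = FALSE)
  refGene <- rep(as.character(txData(index@reference)$gene_id),
                 S4Vectors::elementNROWS(index@exons))
  eh <- GenomicRanges::findOverlaps(flat, refFlat, ignore.strand = FALSE)
  geneWidth <- setNames(BiocGenerics::width(index@geneSpans),
                        names(index@geneSpans))
  assigned <- rep(NA_character_, n)
  if (length(eh)) {
    qh <- S4Vectors::queryHits(eh); sh <- S4Vectors::subjectHits(eh)
    ov <- pmin(BiocGenerics::end(flat)[qh], BiocGenerics::end(refFlat)[sh]) -
      pmax(BiocGenerics::start(flat)[qh],
           BiocGenerics::start(refFlat)[sh]) + 1L
    ci <- grp[qh]; gi <- refGene[sh]
    agg <- rowsum(ov, paste(ci, gi, sep = "\r"))
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    aggCand <- as.integer(vapply(parts, `[`, "", 1L))
    aggGene <- vapply(parts, `[`, "", 2L)
    for (i in unique(aggCand)) {
      sel <- aggCand == i
      g <- aggGene[sel]; o <- agg[sel, 1]
      best <- g[o == max(o)]
      if (length(best) > 1L) {
        w <- geneWidth[best]
        best <- sort(best[w == min(w)])
      }
      assigned[i] <- best[1]
    }
  }

  # intron chains as plain vectors
  intrStarts <- lapply(seq_len(n), function(i) {
    s <- exStarts[[i]]; e <- exEnds[[i]]
    if (length(s) < 2L) integer() else e[-length(e)] + 1L
  })
  intrEnds <- lapply(seq_len(n), function(i) {
    s <- exStarts[[i]]
    if (length(s) < 2L) integer() else s[-1] - 1L
  })

  for (i in seq_len(n)) {
    contig <- txContig[i]; strand <- txStrand[i]
    is_ <- intrStarts[[i]]; ie_ <- intrEnds[[i]]
    if (length(is_) == 0L) {               # single exon
      if (!hasSame[i]) {
        cls[i] <- "mono_exonic_novel"
      } else {
        gene[i] <- assigned[i]
        cls[i] <- if (any(refTxMono[sameList[[i]]])) "known" else "ISM"
      }
      next
    }
    key <- sprintf("%s:%s:%s", contig, strand,
                   paste(is_, ie_, sep = "-", collapse = ","))
    chainMat <- cbind(start = is_, end = ie_)
    if (!is.na(index@chains[key])) {
      cls[i] <- "known"
      gene[i] <- assigned[i]
      next
    }
    isISM <- FALSE
    for (j in sameList[[i]]) {
      full <- index@chainList[[names(refTx)[j]]]
      if (isContiguousSubchain(chainMat, full)) { isISM <- TRUE; break }
    }
    if (isISM) {
      cls[i] <- "ISM"
      gene[i] <- assigned[i]
      next
    }
    if (hasSame[i]) {
      g <- assigned[i]
      gene[i] <- g
      if (strand == "+") { dn <- is_; ac <- ie_ }
      else { dn <- ie_; ac <- is_ }
      if (site_scope == "gene") {
        dset <- index@geneDonors[[g]]; aset <- index@geneAcceptors[[g]]
      } else {
        key2 <- sprintf("%s:%s", contig, strand)
        dset <- index@donors[[key2]]; aset <- index@acceptors[[key2]]
      }
      cls[i] <- if (all(dn %in% dset) && all(ac %in% aset)) "NIC" else "NNC"
    } else if (hasOpp[i]) {
      cls[i] <- "antisense"
    } else {
      cls[i] <- "intergenic"
    }
  }
  td <- txData(candidates)
  td$class_code <- cls
  td$assigned_gene <- gene
  td$mono_exonic <- nEx == 1L
  # the assigned reference gene becomes the working gene id (novel classes
  # get theirs from assignNovelGenes)
  td$gene_id <- ifelse(is.na(gene), td$gene_id, gene)
  candidates@txData <- td
  candidates
}

#' Group antisense and intergenic isoforms into novel genes
#'
#' Single-linkage clustering on same-strand genomic span overlap (>= 1 bp):
#' each connected cluster becomes one novel gene with a stable id
#' `NOVELG<zero-padded integer>`, numbered by (contig, start) of the
#' cluster. Isoforms on different strands never share a cluster.
#'
#' @param classified A classified `TranscriptSet` (from
#'   [classifyTranscripts()]).
#' @param pad Width of the zero-padded integer.
#' @return `classified` with `assigned_gene` filled for antisense,
#'   intergenic and mono-exonic-novel isoforms.
#' @export
assignNovelGenes <- function(classified, pad = 4L) {
  td <- txData(classified)
  sel <- which(td$class_code %in% c("antisense", "intergenic",
                                    "mono_exonic_novel"))
  if (length(sel) == 0L) return(classified)
  spans <- txSpans(classified[sel])
  # reduce() performs exactly single-linkage merging of overlapping,
  # same-strand intervals
  clusters <- GenomicRanges::reduce(spans, ignore.strand = FALSE)
  ord <- order(as.character(GenomicRanges::seqnames(clusters)),
               BiocGenerics::start(clusters))
  clusters <- clusters[ord]
  ids <- sprintf(paste0("NOVELG%0", pad, "d"), seq_along(clusters))
  hits <- GenomicRanges::findOverlaps(spans, clusters, ignore.strand = FALSE)
  stopifnot(length(hits) == length(spans))
  td$assigned_gene[sel] <- ids[S4Vectors::subjectHits(hits)]
  td$gene_id[sel] <- td$assigned_gene[sel]
  classified@txData <- td
  classified
}

#' Collapse redundant transcript models
#'
#' Multi-exon models with identical intron chains whose transcript start
#' positions differ by at most `wobble` bp AND whose end positions differ by
#' at most `wobble` bp are merged under transitive closure; the
#' representative keeps the most extreme 5' and 3' ends among members.
#' Mono-exonic models are left untouched. Idempotent.
#'
#' @param candidates A [TranscriptSet-class].
#' @param wobble Terminal wobble in bp (default 1000, applied to both
#'   termini independently).
#' @return List with `collapsed` (a `TranscriptSet`) and `map` (data.frame
#'   `member` -> `representative`).
#' @export
collapseModels <- function(candidates, wobble = 1000L) {
  n <- length(candidates)
  ids <- txIds(candidates)
  if (n == 0L)
    return(list(collapsed = candidates,
                map = data.frame(member = character(),
                                 representative = character())))
  pc <- txChainsPlain(candidates)
  spanStart <- vapply(pc$exStarts, `[`, 0L, 1L)
  spanEnd <- vapply(pc$exEnds, function(e) e[length(e)], 0L)
  keys <- vapply(seq_len(n), function(i)
    sprintf("%s:%s:%s", pc$contig[i], pc$strand[i],
            paste(pc$intrStarts[[i]], pc$intrEnds[[i]], sep = "-",
                  collapse = ",")), "")
  group <- seq_len(n)        # union-find
  findRoot <- function(i) { while (group[i] != i) i <- group[i]; i }
  multi <- lengths(pc$intrStarts) > 0L
  for (k in unique(keys[multi])) {
    members <- which(keys == k & multi)
    if (length(members) < 2L) next
    st <- spanStart[members]
    en <- spanEnd[members]
    for (a in seq_along(members)) for (b in seq_len(a - 1L)) {
      if (abs(st[a] - st[b]) <= wobble && abs(en[a] - en[b]) <= wobble) {
        ra <- findRoot(members[a]); rb <- findRoot(members[b])
        if (ra != rb) group[rb] <- ra
      }
    }
  }
  root <- vapply(seq_len(n), findRoot, 0L)
  keep <- logical(n)
  rep_of <- character(n)
  newEx <- list()
  for (r in unique(root)) {
    members <- which(root == r)
    # representative id: lexicographically smallest member, so the result
    # is invariant under input permutation
    i1 <- members[order(ids[members])][1]
    st <- pc$exStarts[[i1]]; en <- pc$exEnds[[i1]]
    if (length(members) > 1L) {
      st[1] <- min(spanStart[members])
      en[length(en)] <- max(spanEnd[members])
    }
    keep[i1] <- TRUE
    rep_of[members] <- ids[i1]
    newEx[[ids[i1]]] <- GenomicRanges::GRanges(pc$contig[i1],
      IRanges::IRanges(st, en), strand = pc$strand[i1])
  }
  td <- txData(candidates)[keep, , drop = FALSE]
  collapsed <- TranscriptSet(
    GenomicRanges::GRangesList(newEx[as.character(td$transcript_id)]), td)
  list(collapsed = collapsed,
       map = data.frame(member = ids, representative = rep_of,
                        stringsAsFactors = FALSE))
}

#' Audit splice-site canonicality
#'
#' For every intron, the strand-oriented donor-acceptor dinucleotide pair is
#' canonical iff it is GT-AG, GC-AG or AT-AC; minus-strand introns are read
#' reverse-complemented. An isoform is canonical iff all its introns are.
#'
#' @param ts A [TranscriptSet-class].
#' @param genome A `DNAStringSet` covering the transcripts' contigs.
#' @return List with `per_junction` (list of logical vectors, one per
#'   transcript) and `isoform` (named logical; mono-exonic models are
#'   vacuously canonical).
#' @export
auditCanonical <- function(ts, genome) {
  canonicalPairs <- c("GT-AG", "GC-AG", "AT-AC")
  intr <- txIntrons(ts)
  perJ <- vector("list", length(ts))
  iso <- logical(length(ts))
  for (i in seq_along(intr)) {
    gr <- intr[[i]]
    if (length(gr) == 0L) { perJ[[i]] <- logical(); iso[i] <- TRUE; next }
    contig <- as.character(GenomicRanges::seqnames(gr))[1]
    if (!contig %in% names(genome))
      stopf("coordinate error: contig %s absent from genome", contig)
    cl <- length(genome[[contig]])
    s <- BiocGenerics::start(gr); e <- BiocGenerics::end(gr)
    if (any(s < 1L) || any(e > cl))
      stopf("coordinate error: intron outside contig %s", contig)
    strand <- as.character(BiocGenerics::strand(gr))[1]
    seqs <- as.character(Biostrings::extractAt(genome[[contig]],
      IRanges::IRanges(s, e)))
    if (strand == "+") {
      pair <- paste0(substr(seqs, 1, 2), "-",
                     substr(seqs, nchar(seqs) - 1, nchar(seqs)))
    } else {
      rc <- revComp(seqs)
      pair <- paste0(substr(rc, 1, 2), "-",
                     substr(rc, nchar(rc) - 1, nchar(rc)))
    }
    perJ[[i]] <- pair %in% canonicalPairs
    iso[i] <- all(perJ[[i]])
  }
  names(perJ) <- txIds(ts)
  names(iso) <- txIds(ts)
  list(per_junction = perJ, isoform = iso)
}

#' Summarize structural class composition
#'
#' Per-class counts and percentages (half-up rounding to one decimal),
#' aggregate novel-of-known (NIC+NNC) and novel-loci (antisense+intergenic)
#' totals, and per-gene isoform averages.
#'
#' @param counts Named numeric of per-class isoform counts, or a classified
#'   [TranscriptSet-class] (counted by `class_code`).
#' @param gene_counts Optional named numeric of gene counts per gene class
#'   (e.g. `c(antisense = 2466, intergenic = 2773)`) used for per-gene
#'   isoform averages; derived from `assigned_gene` when a `TranscriptSet`
#'   is given.
#' @return List with `class_table` (class, count, percent), `total`,
#'   `novel_known_isoforms`, `novel_loci_isoforms`, `novel_genes` and
#'   `gene_table` (gene_class, genes, isoforms, mean_isoforms_per_gene).
#' @export
summarizeClasses <- function(counts, gene_counts = NULL) {
  if (is(counts, "TranscriptSet")) {
    td <- txData(counts)
    cls <- as.character(td$class_code)
    cnt <- table(cls)
    counts2 <- setNames(as.numeric(cnt), names(cnt))
    if (is.null(gene_counts) && "assigned_gene" %in% colnames(td)) {
      gene_counts <- vapply(split(as.character(td$assigned_gene), cls),
                            function(g) length(unique(g)), 0)
    }
    counts <- counts2
  }
  if (length(counts) == 0L)
    return(list(class_table = data.frame(class = character(),
                                         count = numeric(),
                                         percent = numeric()),
                total = 0, novel_known_isoforms = 0,
                novel_loci_isoforms = 0, novel_genes = 0,
                gene_table = NULL))
  total <- sum(counts)
  ord <- intersect(STRUCTURAL_CLASSES, names(counts))
  counts <- counts[c(ord, setdiff(names(counts), ord))]
  classTable <- data.frame(class = names(counts),
                           count = as.numeric(counts),
                           percent = roundHalfUp(100 * counts / total, 1),
                           row.names = NULL)
  gv <- function(x, nm) if (nm %in% names(x)) x[[nm]] else 0
  novelKnown <- gv(counts, "NIC") + gv(counts, "NNC")
  novelLoci <- gv(counts, "antisense") + gv(counts, "intergenic")
  geneTable <- NULL
  novelGenes <- 0
  if (!is.null(gene_counts)) {
    shared <- intersect(names(gene_counts), names(counts))
    geneTable <- data.frame(gene_class = shared,
      genes = as.numeric(gene_counts[shared]),
      isoforms = as.numeric(counts[shared]),
      mean_isoforms_per_gene = roundHalfUp(
        as.numeric(counts[shared]) / as.numeric(gene_counts[shared]), 1),
      row.names = NULL)
    novelGenes <- sum(gene_counts[intersect(c("antisense", "intergenic"),
                                            names(gene_counts))])
  }
  list(class_table = classTable, total = total,
       novel_known_isoforms = novelKnown,
       novel_loci_isoforms = novelLoci,
       novel_genes = novelGenes, gene_table = geneTable)
}
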