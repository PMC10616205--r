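# Per-isoform sequence characterization: spliced sequences, ORF calling,
# Fickett TESTCODE and hexamer usage scores feeding a trainable logistic
# coding model, poly(A) motif scanning, repeat projection with
# transposable-element role assignment, and conservation hit calling from
# tabular alignment records.

#' Extract spliced transcript sequences
#'
#' Exon slices concatenated 5'->3' in transcript orientation; minus-strand
#' transcripts are reverse-complemented.
#'
#' @param ts A [TranscriptSet-class].
#' @param genome A `DNAStringSet`.
#' @return A `DNAStringSet`, one sequence per transcript.
#' @export
splicedSequence <- function(ts, genome) {
  ex <- txExons(ts)
  out <- character(length(ts))
  for (i in seq_along(ex)) {
    e <- ex[[i]]
    contig <- as.character(GenomicRanges::seqnames(e))[1]
    if (!contig %in% names(genome))
      stopf("coordinate error: contig %s absent from genome", contig)
    cl <- length(genome[[contig]])
    if (any(BiocGenerics::start(e) < 1L) || any(BiocGenerics::end(e) > cl))
      stopf("coordinate error: exon outside contig %s in %s", contig,
            txIds(ts)[i])
    parts <- as.character(Biostrings::extractAt(genome[[contig]],
      IRanges::IRanges(BiocGenerics::start(e), BiocGenerics::end(e))))
    s <- paste(parts, collapse = "")
    if (as.character(BiocGenerics::strand(e))[1] == "-") s <- revComp(s)
    out[i] <- s
  }
  Biostrings::DNAStringSet(setNames(out, txIds(ts)))
}

#' Find the best open reading frame
#'
#' Scans the three sense-strand frames for ATG..stop ORFs; the best ORF is
#' the longest, with ties broken by the 5'-most start. By default an ORF
#' must end at a stop codon; `allow_open_end = TRUE` additionally reports
#' ORFs running off the 3' end (truncated models).
#'
#' @param sequence A single character string or `DNAString` over
#'   A/C/G/T/N.
#' @param allow_open_end Report stop-less ORFs reaching the 3' end.
#' @return `NULL` when no ORF exists, else a list with `start`, `end`
#'   (1-based inclusive transcript coordinates), `length`, `coverage`
#'   (length / transcript length) and `peptide` (without the stop).
#' @export
findBestOrf <- function(sequence, allow_open_end = FALSE) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (n < 6L) return(NULL)
  best <- NULL
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    i <- frame + 1L
    codons <- substring(s, seq(i, n - 2L, by = 3L), seq(i + 2L, n, by = 3L))
    startIdx <- which(codons == "ATG")
    stopIdx <- which(codons %in% stops)
    for (a in startIdx) {
      nxt <- stopIdx[stopIdx > a]
      if (length(nxt)) {
        b <- nxt[1]
        len <- (b - a + 1L) * 3L
        st <- i + (a - 1L) * 3L
      } else if (allow_open_end) {
        b <- length(codons)
        len <- (b - a + 1L) * 3L
        st <- i + (a - 1L) * 3L
      } else next
      if (is.null(best) || len > best$length ||
          (len == best$length && st < best$start)) {
        best <- list(start = st, end = st + len - 1L, length = len,
                     coverage = len / n,
                     peptide = paste(vapply(codons[a:b], function(cd)
                       if (cd %in% stops) "" else GENETIC_CODE_MAP[[cd]] %||% "X",
                       ""), collapse = ""))
      }
    }
  }
  best
}

GENETIC_CODE_MAP <- as.list(Biostrings::GENETIC_CODE)

# Fickett (1982) TESTCODE lookup tables, as used by standard coding
# potential assessment tools.
FICKETT_POSITION_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_POSITION_PARA <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
FICKETT_CONTENT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
FICKETT_CONTENT_PARA <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                          0.17, 0)

#' Fickett TESTCODE score
#'
#' Position-bias and composition statistic over the four bases using the
#' published lookup tables; higher values indicate codon-like periodicity.
#'
#' @param sequence Character string or `DNAString`.
#' @return Numeric score (0 for sequences shorter than 2 codons).
#' @export
fickettScore <- function(sequence) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (n < 6L) return(0)
  b <- strsplit(s, "")[[1]]
  score <- 0
  for (base in c("A", "C", "G", "T")) {
    # position parameter: max over the three phase counts / (min + 1)
    phase <- vapply(0:2, function(ph)
      sum(b[seq(ph + 1L, n, by = 3L)] == base), 0L)
    posPar <- max(phase) / (min(phase) + 1)
    idx <- which(posPar >= FICKETT_POSITION_PARA)[1]
    score <- score + FICKETT_POSITION_PROB[[base]][idx] *
      FICKETT_POSITION_WEIGHT[[base]]
    contPar <- sum(b == base) / n
    idx <- which(contPar >= FICKETT_CONTENT_PARA)[1]
    score <- score + FICKETT_CONTENT_PROB[[base]][idx] *
      FICKETT_CONTENT_WEIGHT[[base]]
  }
  score
}

# In-frame hexamers (step 3) of a sequence.
hexamersOf <- function(s) {
  n <- nchar(s)
  if (n < 6L) return(character())
  substring(s, seq(1L, n - 5L, by = 3L), seq(6L, n, by = 3L))
}

#' Hexamer usage score
#'
#' Mean over the in-frame hexamers of `sequence` of
#' `log(coding_freq / noncoding_freq)` from a trained hexamer table;
#' 0 when no hexamer applies (sequence shorter than 6, or hexamers
#' containing N).
#'
#' @param sequence Character string or `DNAString` (typically the best ORF).
#' @param table Named numeric of 4096 log-ratio values (from
#'   [trainCodingModel()] or [buildHexamerTable()]).
#' @return Numeric score.
#' @export
hexamerScore <- function(sequence, table) {
  hx <- hexamersOf(toupper(as.character(sequence)))
  hx <- hx[hx %in% names(table)]
  if (length(hx) == 0L) return(0)
  mean(table[hx])
}

#' Build a hexamer log-ratio table
#'
#' In-frame hexamer frequencies with pseudo-count 1 in each class;
#' the table maps each of the 4096 hexamers to
#' `log(freq_coding / freq_noncoding)`.
#'
#' @param coding_seqs,noncoding_seqs Character vectors of sequences (coding
#'   sequences should be in reading frame).
#' @return Named numeric of length 4096.
#' @export
buildHexamerTable <- function(coding_seqs, noncoding_seqs) {
  alphabet <- c("A", "C", "G", "T")
  allHex <- apply(expand.grid(alphabet, alphabet, alphabet, alphabet,
                              alphabet, alphabet), 1, paste, collapse = "")
  countIn <- function(seqs) {
    cnt <- setNames(rep(1, length(allHex)), allHex)   # pseudo-count 1
    for (s in seqs) {
      hx <- hexamersOf(toupper(s))
      hx <- hx[hx %in% allHex]
      if (length(hx)) {
        t <- table(hx)
        cnt[names(t)] <- cnt[names(t)] + as.numeric(t)
      }
    }
    cnt / sum(cnt)
  }
  log(countIn(coding_seqs) / countIn(noncoding_seqs))
}

#' Train a coding-potential model
#'
#' Builds a hexamer log-ratio table from the training sequences and fits a
#' logistic regression of coding status on four features of the best ORF:
#' ORF length, ORF coverage, Fickett score and hexamer score. The decision
#' threshold defaults to a coding probability of 0.364.
#'
#' @param coding_seqs,noncoding_seqs Character vectors (or `DNAStringSet`s)
#'   of labelled transcript sequences; both classes must be nonempty.
#' @param threshold Probability threshold for the coding label.
#' @return A list of class `CodingModel` with elements `hexamer_table`,
#'   `fit` (the glm), and `threshold`.
#' @export
trainCodingModel <- function(coding_seqs, noncoding_seqs, threshold = 0.364) {
  coding_seqs <- as.character(coding_seqs)
  noncoding_seqs <- as.character(noncoding_seqs)
  if (length(coding_seqs) == 0L || length(noncoding_seqs) == 0L)
    stopf("training error: both coding and noncoding sequences are required")
  orfOf <- function(s) {
    o <- findBestOrf(s)
    if (is.null(o)) "" else substr(s, o$start, o$end)
  }
  codingOrfs <- vapply(coding_seqs, orfOf, "")
  tab <- buildHexamerTable(codingOrfs[nzchar(codingOrfs)], noncoding_seqs)
  feat <- function(seqs) {
    t(vapply(seqs, function(s) codingFeatures(s, tab), numeric(4)))
  }
  X <- rbind(feat(coding_seqs), feat(noncoding_seqs))
  df <- data.frame(X, label = rep(c(1L, 0L), c(length(coding_seqs),
                                               length(noncoding_seqs))))
  fit <- suppressWarnings(glm(label ~ orf_length + orf_coverage + fickett +
                                hexamer, data = df, family = binomial()))
  structure(list(hexamer_table = tab, fit = fit, threshold = threshold),
            class = "CodingModel")
}

# The four features of the best ORF of a transcript sequence.
codingFeatures <- function(sequence, hexamer_table) {
  s <- toupper(as.character(sequence))
  o <- findBestOrf(s)
  if (is.null(o))
    return(c(orf_length = 0, orf_coverage = 0, fickett = fickettScore(s),
             hexamer = 0))
  orfSeq <- substr(s, o$start, o$end)
  c(orf_length = o$length, orf_coverage = o$coverage,
    fickett = fickettScore(s),
    hexamer = hexamerScore(orfSeq, hexamer_table))
}

#' Classify coding potential
#'
#' @param sequences Character vector or `DNAStringSet`.
#' @param model A `CodingModel` from [trainCodingModel()].
#' @return data.frame with `coding_probability`, `coding_label`
#'   (`TRUE` iff probability >= threshold), `orf_length`, `orf_coverage`,
#'   `fickett`, `hexamer`. ORF-less sequences get probability 0 and a
#'   noncoding label.
#' @export
classifyCoding <- function(sequences, model) {
  seqs <- as.character(sequences)
  X <- t(vapply(seqs, function(s) codingFeatures(s, model$hexamer_table),
                numeric(4)))
  df <- as.data.frame(X)
  p <- as.numeric(predict(model$fit, newdata = df, type = "response"))
  p[df$orf_length == 0] <- 0
  out <- data.frame(coding_probability = p,
                    coding_label = p >= model$threshold, df,
                    row.names = NULL)
  if (!is.null(names(sequences))) out <- cbind(id = names(sequences), out)
  out
}

#' Default poly(A) signal motifs
#'
#' The canonical AATAAA hexamer and eleven common single-substitution or
#' known variant signals.
#' @return Character vector of 12 motifs.
#' @export
polyAMotifs <- function() {
  c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA", "AATACA",
    "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA")
}

#' Scan for poly(A) motifs near the 3' end
#'
#' Exact-match scan of the final `window` nucleotides of each sequence.
#'
#' @param sequences Character vector or `DNAStringSet`.
#' @param motifs Motif set (default [polyAMotifs()]).
#' @param window Number of 3'-terminal nucleotides scanned (default 50).
#' @return data.frame with one row per occurrence: `id`, `motif`,
#'   `position` (1-based in the full sequence) and `distance` (from motif
#'   end to the 3' end).
#' @export
scanPolyA <- function(sequences, motifs = polyAMotifs(), window = 50L) {
  if (length(motifs) == 0L) stopf("motifs must be nonempty")
  seqs <- toupper(as.character(sequences))
  ids <- names(sequences) %||% as.character(seq_along(seqs))
  rows <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    n <- nchar(s)
    from <- max(1L, n - window + 1L)
    tailSeq <- substr(s, from, n)
    for (m in motifs) {
      hits <- gregexpr(m, tailSeq, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      for (h in hits) {
        pos <- from + h - 1L
        rows[[length(rows) + 1L]] <- data.frame(id = ids[i], motif = m,
          position = pos, distance = n - (pos + nchar(m) - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(id = character(), motif = character(),
                      position = integer(), distance = integer()))
  do.call(rbind, rows)
}

#' Project repeat annotations onto transcripts
#'
#' For each repeat interval intersecting an exon, computes the
#' transcript-space overlap; the repeat fraction is the union of covered
#' spliced bases over the spliced length. A repeat covering the first
#' transcribed base acts as an alternative promoter, one covering the last
#' transcribed base as a terminator, otherwise as an internal element.
#' Repeat strand is ignored for the overlap (chimeric TE transcription uses
#' elements on either strand) unless `same_strand_only = TRUE`.
#'
#' @param ts A [TranscriptSet-class].
#' @param repeats `GRanges` with `repeat_name`, `repeat_class`,
#'   `repeat_family`.
#' @param same_strand_only Restrict to same-strand repeats.
#' @return List with `fraction` (named numeric per isoform) and `roles`
#'   (data.frame: id, repeat_name, repeat_class, repeat_family, role,
#'   overlap_bases).
#' @export
projectRepeats <- function(ts, repeats, same_strand_only = FALSE) {
  ex <- txExons(ts)
  frac <- setNames(numeric(length(ts)), txIds(ts))
  rows <- list()
  for (i in seq_along(ex)) {
    e <- ex[[i]]
    strand <- as.character(BiocGenerics::strand(e))[1]
    hits <- GenomicRanges::findOverlaps(e, repeats,
                                        ignore.strand = !same_strand_only)
    if (same_strand_only) {
      keep <- as.character(BiocGenerics::strand(
        repeats[S4Vectors::subjectHits(hits)])) == strand
      hits <- hits[keep]
    }
    if (length(hits) == 0L) next
    covered <- IRanges::reduce(IRanges::pintersect(
      IRanges::ranges(e)[S4Vectors::queryHits(hits)],
      IRanges::ranges(repeats)[S4Vectors::subjectHits(hits)]))
    frac[i] <- sum(BiocGenerics::width(covered)) /
      sum(BiocGenerics::width(e))
    tss <- if (strand == "+") BiocGenerics::start(e)[1]
           else BiocGenerics::end(e)[length(e)]
    tes <- if (strand == "+") BiocGenerics::end(e)[length(e)]
           else BiocGenerics::start(e)[1]
    for (k in unique(S4Vectors::subjectHits(hits))) {
      r <- repeats[k]
      qh <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == k]
      ov <- sum(BiocGenerics::width(IRanges::pintersect(
        IRanges::ranges(e)[qh],
        rep(IRanges::ranges(r), length(qh)))))
      role <- if (BiocGenerics::start(r) <= tss &&
                  BiocGenerics::end(r) >= tss) "promoter"
              else if (BiocGenerics::start(r) <= tes &&
                       BiocGenerics::end(r) >= tes) "terminator"
              else "internal"
      rows[[length(rows) + 1L]] <- data.frame(id = txIds(ts)[i],
        repeat_name = r$repeat_name, repeat_class = r$repeat_class,
        repeat_family = r$repeat_family, role = role, overlap_bases = ov,
        stringsAsFactors = FALSE)
    }
  }
  roles <- if (length(rows)) do.call(rbind, rows)
           else data.frame(id = character(), repeat_name = character(),
                           repeat_class = character(),
                           repeat_family = character(), role = character(),
                           overlap_bases = integer())
  list(fraction = frac, roles = roles)
}

#' Call conservation hits from alignment records
#'
#' An (isoform, target genome) pair is a hit iff at least one record has
#' alignment length strictly greater than `min_length`, identity strictly
#' greater than `min_identity` and E-value below `max_evalue`.
#'
#' @param hit_table data.frame as from [readHitTable()].
#' @param classes Optional named character mapping isoform id -> structural
#'   class, for per-class hit percentages.
#' @param min_length,min_identity,max_evalue Thresholds (defaults 100 bp,
#'   95 percent, 0.05).
#' @return List with `calls` (query_id, target_genome, hit, best alignment
#'   stats) and, when `classes` is given, `percent_by_class`
#'   (target_genome x class matrix of hit percentages over that class's
#'   isoforms).
#' @export
callConservationHits <- function(hit_table, classes = NULL,
                                 min_length = 100, min_identity = 95,
                                 max_evalue = 0.05) {
  ht <- hit_table
  ok <- ht$align_length > min_length & ht$percent_identity > min_identity &
    ht$evalue < max_evalue
  keyAll <- paste(ht$query_id, ht$target_genome, sep = "\r")
  keys <- unique(keyAll)
  calls <- data.frame(do.call(rbind, strsplit(keys, "\r")),
                      stringsAsFactors = FALSE)
  colnames(calls) <- c("query_id", "target_genome")
  calls$hit <- vapply(keys, function(k) any(ok[keyAll == k]), NA)
  calls$best_align_length <- vapply(keys, function(k)
    max(ht$align_length[keyAll == k]), 0)
  calls$best_identity <- vapply(keys, function(k)
    max(ht$percent_identity[keyAll == k]), 0)
  calls$best_evalue <- vapply(keys, function(k)
    min(ht$evalue[keyAll == k]), 0)
  rownames(calls) <- NULL
  out <- list(calls = calls)
  if (!is.null(classes)) {
    genomes <- unique(calls$target_genome)
    clsLevels <- unique(classes)
    pct <- matrix(NA_real_, length(genomes), length(clsLevels),
                  dimnames = list(genomes, clsLevels))
    for (g in genomes) for (cl in clsLevels) {
      isoA <- names(classes)[classes == cl]
      sub <- calls[calls$target_genome == g & calls$query_id %in% isoA, ]
      hitIds <- sub$query_id[sub$hit]
      pct[g, cl] <- roundHalfUp(100 * length(unique(hitIds)) /
                                  length(isoA), 1)
    }
    out$percent_by_class <- pct
  }
  out
}

#' Per-isoform feature table
#'
#' Convenience wrapper assembling the sequence-feature outputs into one
#' table per isoform: coding potential, best-ORF statistics, the closest
#' 3'-end poly(A) motif, repeat fraction and roles.
#'
#' @param ts A [TranscriptSet-class].
#' @param genome `DNAStringSet`.
#' @param model A `CodingModel`.
#' @param repeats Optional repeat `GRanges`.
#' @return data.frame, one row per isoform.
#' @export
isoformFeatureTable <- function(ts, genome, model, repeats = NULL) {
  seqs <- splicedSequence(ts, genome)
  cod <- classifyCoding(seqs, model)
  pa <- scanPolyA(seqs)
  paBest <- if (nrow(pa)) do.call(rbind, lapply(split(pa, pa$id), function(d)
    d[which.min(d$distance), ])) else NULL
  out <- data.frame(id = txIds(ts), cod[, -1, drop = FALSE],
                    polya_motif = NA_character_,
                    polya_distance = NA_integer_,
                    repeat_fraction = 0,
                    repeat_roles = "", stringsAsFactors = FALSE)
  if (!is.null(paBest)) {
    m <- match(out$id, paBest$id)
    out$polya_motif <- paBest$motif[m]
    out$polya_distance <- paBest$distance[m]
  }
  if (!is.null(repeats)) {
    rp <- projectRepeats(ts, repeats)
    out$repeat_fraction <- as.numeric(rp$fraction[out$id])
    if (nrow(rp$roles)) {
      agg <- vapply(split(rp$roles, rp$roles$id), function(d)
        paste(sprintf("%s:%s:%s", d$repeat_name, d$repeat_class, d$role),
              collapse = ";"), "")
      out$repeat_roles[match(names(agg), out$id)] <- agg
    }
  }
  out
}
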