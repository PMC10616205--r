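# Synthetic-data generator: fully labelled toy genomes, annotations,
# candidate isoforms, junction evidence, repeats and stage-structured
# expression, so every downstream stage has a ground-truth oracle.

STRUCTURAL_CLASSES <- c("known", "ISM", "NIC", "NNC", "antisense",
                        "intergenic", "mono_exonic_novel")

#' Structural class vocabulary
#' @return Character vector of the structural classes.
#' @export
structuralClasses <- function() STRUCTURAL_CLASSES

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults define the
#' standard simulated study: 30 multi-exon genes on a 200 kb contig, 200
#' candidate isoforms spanning every structural class, six developmental
#' stages with `n_samples_per_stage` samples each, and an EGA-like
#' expression shift applied from the 8C stage onward to a subset of genes
#' whose pre-activation baseline is low (zygotically activated genes are
#' near-silent before EGA).
#'
#' @param seed Integer seed; fully determines the generated bundle.
#' @param n_genes Number of reference genes.
#' @param contig_length Contig length in bases (>= 10000).
#' @param exons_per_transcript Integer range `c(lo, hi)`.
#' @param exon_length,intron_length Base ranges `c(lo, hi)`.
#' @param fraction_noncanonical Proportion of reference introns whose donor
#'   GT is mutated to a non-GT dinucleotide (coordinates unchanged).
#' @param class_mix Named proportions over [structuralClasses()]; must sum
#'   to 1.
#' @param n_candidates Number of candidate isoforms.
#' @param n_samples_per_stage Samples per developmental stage.
#' @param ega_shift_magnitude Fold-change applied to EGA genes from the 8C
#'   stage onward (1 = no effect).
#' @param ega_gene_fraction Fraction of genes receiving the shift.
#' @param a_tract_rate Proportion of candidate TES neighbourhoods made
#'   A-rich (16 of the 20 downstream bases, in transcript orientation).
#' @param te_insertion_rate Proportion of novel-gene TSSs placed inside a
#'   simulated repeat.
#' @param unsupported_rate Proportion of multi-exon candidates given a
#'   junction with short-read support in at most two samples.
#' @param short_rate Proportion of intergenic candidates built with spliced
#'   length below 200 bp.
#' @param second_isoform_rate Probability that a gene with >= 3 exons gets a
#'   second, exon-skipped reference isoform.
#' @param dispersion Negative-binomial dispersion of the counts (0.2 is a
#'   typical bulk RNA-seq scale).
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, n_genes = 30L,
                             contig_length = 200000L,
                             exons_per_transcript = c(3L, 6L),
                             exon_length = c(100L, 300L),
                             intron_length = c(200L, 500L),
                             fraction_noncanonical = 0,
                             class_mix = c(known = 0.25, ISM = 0.10,
                                           NIC = 0.20, NNC = 0.20,
                                           antisense = 0.10,
                                           intergenic = 0.10,
                                           mono_exonic_novel = 0.05),
                             n_candidates = 200L,
                             n_samples_per_stage = 3L,
                             ega_shift_magnitude = 8,
                             ega_gene_fraction = 0.1,
                             a_tract_rate = 0.15,
                             te_insertion_rate = 0.2,
                             unsupported_rate = 0.15,
                             short_rate = 0.05,
                             second_isoform_rate = 0.4,
                             dispersion = 0.2) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              contig_length = as.integer(contig_length),
              exons_per_transcript = as.integer(exons_per_transcript),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              fraction_noncanonical = fraction_noncanonical,
              class_mix = class_mix,
              n_candidates = as.integer(n_candidates),
              n_samples_per_stage = as.integer(n_samples_per_stage),
              ega_shift_magnitude = ega_shift_magnitude,
              ega_gene_fraction = ega_gene_fraction,
              a_tract_rate = a_tract_rate,
              te_insertion_rate = te_insertion_rate,
              unsupported_rate = unsupported_rate,
              short_rate = short_rate,
              second_isoform_rate = second_isoform_rate,
              dispersion = dispersion)
  validateSimulationConfig(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validateSimulationConfig <- function(cfg) {
  if (cfg$contig_length < 10000L)
    stopf("configuration error: contig_length must be >= 10000")
  for (f in c("exons_per_transcript", "exon_length", "intron_length")) {
    r <- cfg[[f]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L)
      stopf("configuration error: invalid range for %s", f)
  }
  if (cfg$exons_per_transcript[1] < 2L)
    stopf("configuration error: reference transcripts must be multi-exon")
  cm <- cfg$class_mix
  if (is.null(names(cm)) || !all(names(cm) %in% STRUCTURAL_CLASSES))
    stopf("configuration error: class_mix names must be structural classes")
  if (abs(sum(cm) - 1) > 1e-9)
    stopf("configuration error: class_mix must sum to 1")
  props <- c("fraction_noncanonical", "ega_gene_fraction", "a_tract_rate",
             "te_insertion_rate", "unsupported_rate", "short_rate",
             "second_isoform_rate")
  for (f in props)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stopf("configuration error: %s must be in [0,1]", f)
  if (cfg$ega_shift_magnitude <= 0)
    stopf("configuration error: ega_shift_magnitude must be positive")
  if (cfg$n_samples_per_stage < 1L)
    stopf("configuration error: need >= 1 sample per stage")
  invisible(TRUE)
}

#' Simulate a genome
#'
#' Uniform-random A/C/G/T contig, deterministic given the config seed.
#' @param config A [simulationConfig()].
#' @return A `DNAStringSet` with one contig, `chrS`.
#' @export
simulateGenome <- function(config) {
  validateSimulationConfig(config)
  withSeed(config$seed, {
    seq <- paste(sample(c("A", "C", "G", "T"), config$contig_length,
                        replace = TRUE), collapse = "")
    Biostrings::DNAStringSet(setNames(seq, "chrS"))
  })
}

# genome <-> mutable character-vector helpers used during generation
genomeToChars <- function(genome) strsplit(as.character(genome[[1]]), "")[[1]]
charsToGenome <- function(chars, name = "chrS")
  Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""), name))

# Dinucleotide positions of an intron's donor/acceptor on the genome.
intronSitePositions <- function(s, e) c(s, s + 1L, e - 1L, e)

# Plant canonical GT..AG dinucleotides (transcript orientation) for introns.
# On '-' the plus-strand genome gets CT..AC so the reverse complement reads
# GT..AG.
plantSpliceSites <- function(chars, starts, ends, strand) {
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    if (strand == "+") {
      chars[s] <- "G"; chars[s + 1L] <- "T"
      chars[e - 1L] <- "A"; chars[e] <- "G"
    } else {
      chars[s] <- "C"; chars[s + 1L] <- "T"
      chars[e - 1L] <- "A"; chars[e] <- "C"
    }
  }
  chars
}

#' Simulate a reference annotation
#'
#' Places non-overlapping multi-exon genes on both strands along the first
#' 68% of the contig, plants canonical GT..AG dinucleotides at every intron
#' (transcript orientation), mutates the donor GT of a
#' `fraction_noncanonical` subset to CC (coordinates unchanged), and gives a
#' fraction of genes a second, exon-skipped isoform.
#'
#' @param config A [simulationConfig()].
#' @param genome `DNAStringSet` from [simulateGenome()].
#' @return List with `reference` (a [TranscriptSet-class]), `genome` (the
#'   modified `DNAStringSet`), and `canonical_introns` (data.frame of all
#'   reference introns with their planted canonicality).
#' @export
simulateReference <- function(config, genome) {
  validateSimulationConfig(config)
  withSeed(config$seed + 1L, {
    contig <- names(genome)[1]
    gl <- Biostrings::width(genome)[1]
    genesEnd <- floor(gl * 0.68)
    if (config$n_genes == 0L) {
      return(list(reference = TranscriptSet(
        GenomicRanges::GRangesList(),
        S4Vectors::DataFrame(transcript_id = character(),
                             gene_id = character())),
        genome = genome,
        canonical_introns = data.frame(start = integer(), end = integer(),
                                       strand = character(),
                                       canonical = logical())))
    }
    cursor <- 1000L
    exList <- list(); tds <- list()
    for (i in seq_len(config$n_genes)) {
      nEx <- sample(seq(config$exons_per_transcript[1],
                        config$exons_per_transcript[2]), 1L)
      exw <- sample(seq(config$exon_length[1], config$exon_length[2]),
                    nEx, replace = TRUE)
      inw <- sample(seq(config$intron_length[1], config$intron_length[2]),
                    max(nEx - 1L, 0L), replace = TRUE)
      span <- sum(exw) + sum(inw)
      if (cursor + span > genesEnd)
        stopf("placement error: cannot place gene %d of %d on a %d bp contig",
              i, config$n_genes, gl)
      strand <- sample(c("+", "-"), 1L)
      starts <- cursor + cumsum(c(0L, head(exw, -1L) + inw))
      gid <- sprintf("GENE%03d", i)
      ex1 <- GenomicRanges::GRanges(contig,
        IRanges::IRanges(starts, starts + exw - 1L), strand = strand)
      exList[[length(exList) + 1L]] <- ex1
      tds[[length(tds) + 1L]] <- c(paste0(gid, ".1"), gid)
      if (nEx >= 3L && runif(1) < config$second_isoform_rate) {
        k <- if (nEx == 3L) 2L else sample(2:(nEx - 1L), 1L)
        exList[[length(exList) + 1L]] <- ex1[-k]
        tds[[length(tds) + 1L]] <- c(paste0(gid, ".2"), gid)
      }
      cursor <- cursor + span + sample(1500:2500, 1L)
    }
    td <- S4Vectors::DataFrame(
      transcript_id = vapply(tds, `[`, "", 1L),
      gene_id = vapply(tds, `[`, "", 2L))
    names(exList) <- td$transcript_id
    ref <- TranscriptSet(GenomicRanges::GRangesList(exList), td)

    # plant splice sites for all unique introns, then mutate a subset
    intr <- txIntrons(ref)
    flat <- BiocGenerics::unlist(intr, use.names = FALSE)
    key <- paste(BiocGenerics::start(flat), BiocGenerics::end(flat),
                 as.character(BiocGenerics::strand(flat)))
    uniq <- !duplicated(key)
    us <- BiocGenerics::start(flat)[uniq]; ue <- BiocGenerics::end(flat)[uniq]
    ustr <- as.character(BiocGenerics::strand(flat))[uniq]
    chars <- genomeToChars(genome)
    for (st in c("+", "-")) {
      sel <- ustr == st
      chars <- plantSpliceSites(chars, us[sel], ue[sel], st)
    }
    canonical <- rep(TRUE, sum(uniq))
    nNc <- round(config$fraction_noncanonical * length(canonical))
    if (nNc > 0L) {
      pick <- sample(seq_along(canonical), nNc)
      for (j in pick) {
        if (ustr[j] == "+") {           # donor GT -> CC
          chars[us[j]] <- "C"; chars[us[j] + 1L] <- "C"
        } else {                        # '-' donor at intron end: AC -> GG
          chars[ue[j] - 1L] <- "G"; chars[ue[j]] <- "G"
        }
        canonical[j] <- FALSE
      }
    }
    list(reference = ref, genome = charsToGenome(chars, contig),
         canonical_introns = data.frame(start = us, end = ue, strand = ustr,
                                        canonical = canonical))
  })
}

# Per-gene splice-site sets of a reference (strand-resolved genomic
# positions of donors and acceptors).
geneSiteSets <- function(reference) {
  td <- txData(reference)
  intr <- txIntrons(reference)
  genes <- unique(as.character(td$gene_id))
  don <- list(); acc <- list()
  for (g in genes) {
    flat <- BiocGenerics::unlist(intr[td$gene_id == g], use.names = FALSE)
    if (length(flat) == 0L) { don[[g]] <- integer(); acc[[g]] <- integer(); next }
    st <- as.character(BiocGenerics::strand(flat))
    d <- ifelse(st == "+", BiocGenerics::start(flat), BiocGenerics::end(flat))
    a <- ifelse(st == "+", BiocGenerics::end(flat), BiocGenerics::start(flat))
    don[[g]] <- unique(d); acc[[g]] <- unique(a)
  }
  list(donors = don, acceptors = acc)
}

#' Simulate labelled candidate isoforms
#'
#' Emits candidates of each structural class per `class_mix`: jittered exact
#' intron-chain copies (known), 5'/3' truncations (ISM), exon-skipping
#' recombinations of known donors/acceptors (NIC), splice-site shifts (NNC),
#' opposite-strand models inside gene bodies (antisense), models placed
#' >= 1 kb from any reference transcript (intergenic), and mono-exonic
#' decoys. A-rich tracts are written downstream of a subset of TESs and
#' simulated repeats are inserted at a subset of novel-gene TSSs.
#'
#' @param config A [simulationConfig()].
#' @param reference Reference `TranscriptSet` from [simulateReference()].
#' @param genome The (reference-modified) genome.
#' @return List with `candidates` (a `TranscriptSet` whose `txData` carries
#'   `true_class`, `true_gene`, `true_intra_priming`), `genome` (further
#'   modified), and `repeats` (`GRanges`).
#' @export
simulateCandidates <- function(config, reference, genome) {
  validateSimulationConfig(config)
  if (length(reference) == 0L)
    stopf("generation error: reference annotation is empty")
  withSeed(config$seed + 2L, {
    contig <- names(genome)[1]
    gl <- Biostrings::width(genome)[1]
    chars <- genomeToChars(genome)

    td <- txData(reference)
    geneIds <- as.character(td$gene_id)
    rp <- txChainsPlain(reference)
    nIntrons <- lengths(rp$intrStarts)
    nRef <- length(reference)
    chainKeyOf <- function(is_, ie_, strand)
      sprintf("%s:%s:%s", contig, strand,
              paste(is_, ie_, sep = "-", collapse = ","))
    chainKeys <- vapply(seq_len(nRef), function(i)
      chainKeyOf(rp$intrStarts[[i]], rp$intrEnds[[i]], rp$strand[i]), "")
    sites <- geneSiteSets(reference)
    refIntronKeysByGene <- lapply(split(seq_len(nRef), geneIds),
      function(idx) unlist(lapply(idx, function(i)
        paste(rp$intrStarts[[i]], rp$intrEnds[[i]]))))
    # protected positions: reference splice dinucleotides
    allS <- unlist(rp$intrStarts); allE <- unlist(rp$intrEnds)
    protected <- unique(c(allS, allS + 1L, allE - 1L, allE))

    # per-class counts
    mix <- config$class_mix
    nc <- floor(mix * config$n_candidates)
    rem <- config$n_candidates - sum(nc)
    if (rem > 0) {
      ord <- order(mix * config$n_candidates - nc, decreasing = TRUE)
      nc[ord[seq_len(rem)]] <- nc[ord[seq_len(rem)]] + 1L
    }

    jitterEnds <- function(st, en) {
      w1 <- en[1] - st[1] + 1L
      wn <- en[length(en)] - st[length(st)] + 1L
      st[1] <- st[1] + pickOne(0:min(40L, w1 - 2L))
      en[length(en)] <- en[length(en)] - pickOne(0:min(40L, wn - 2L))
      list(st = st, en = en)
    }

    outSt <- list(); outEn <- list(); outStrand <- character()
    outClass <- character(); outGene <- character()
    addCand <- function(st, en, strand, cls, gene) {
      outSt[[length(outSt) + 1L]] <<- st
      outEn[[length(outEn) + 1L]] <<- en
      outStrand[length(outStrand) + 1L] <<- strand
      outClass[length(outClass) + 1L] <<- cls
      outGene[length(outGene) + 1L] <<- gene
    }

    multiIdx <- which(nIntrons >= 1L)
    ge2Idx <- which(nIntrons >= 2L)

    for (k in seq_len(mixN(nc, "known"))) {
      i <- pickOne(multiIdx)
      j <- jitterEnds(rp$exStarts[[i]], rp$exEnds[[i]])
      addCand(j$st, j$en, rp$strand[i], "known", geneIds[i])
    }

    for (k in seq_len(mixN(nc, "ISM"))) {
      i <- pickOne(ge2Idx)
      st <- rp$exStarts[[i]]; en <- rp$exEnds[[i]]
      if (runif(1) < 0.5) { st <- st[-1]; en <- en[-1] }
      else { st <- st[-length(st)]; en <- en[-length(en)] }
      j <- jitterEnds(st, en)
      addCand(j$st, j$en, rp$strand[i], "ISM", geneIds[i])
    }

    for (k in seq_len(mixN(nc, "NIC"))) {
      placed <- FALSE
      for (attempt in shuffle(ge2Idx)) {
        st <- rp$exStarts[[attempt]]; en <- rp$exEnds[[attempt]]
        nEx <- length(st)
        for (skip in shuffle(2:(nEx - 1L))) {
          nst <- st[-skip]; nen <- en[-skip]
          is_ <- nen[-length(nen)] + 1L; ie_ <- nst[-1] - 1L
          key <- chainKeyOf(is_, ie_, rp$strand[attempt])
          mergedKey <- paste(is_[skip - 1L], ie_[skip - 1L])
          g <- geneIds[attempt]
          if (!(key %in% chainKeys) &&
              !(mergedKey %in% refIntronKeysByGene[[g]])) {
            j <- jitterEnds(nst, nen)
            addCand(j$st, j$en, rp$strand[attempt], "NIC", g)
            placed <- TRUE; break
          }
        }
        if (placed) break
      }
      if (!placed)
        stopf("generation error: cannot generate class NIC (no eligible gene)")
    }

    for (k in seq_len(mixN(nc, "NNC"))) {
      i <- pickOne(multiIdx)
      st <- rp$exStarts[[i]]; en <- rp$exEnds[[i]]
      g <- geneIds[i]
      j <- pickOne(seq_len(length(st) - 1L))
      off <- 6L
      siteSet <- c(sites$donors[[g]], sites$acceptors[[g]])
      e <- st[j + 1L] - 1L                  # genomic intron end
      while ((e - off) %in% siteSet) off <- off + 1L
      st[j + 1L] <- st[j + 1L] - off
      jj <- jitterEnds(st, en)
      addCand(jj$st, jj$en, rp$strand[i], "NNC", g)
    }

    # antisense: opposite strand, inside a gene span, non-overlapping per gene
    geneStart <- tapply(vapply(rp$exStarts, `[`, 0L, 1L), geneIds, min)
    geneEnd <- tapply(vapply(rp$exEnds, function(e) e[length(e)], 0L),
                      geneIds, max)
    geneStrand <- tapply(rp$strand, geneIds, `[`, 1L)
    usedAS <- list()
    for (k in seq_len(mixN(nc, "antisense"))) {
      placed <- FALSE
      for (g in shuffle(names(geneStart))) {
        spanLen <- 150L + 250L + 150L
        gs <- geneStart[[g]]; gend <- geneEnd[[g]]
        if (gend - gs + 1L < spanLen + 40L) next
        lo <- gs; hi <- gend - spanLen
        cand <- NULL
        for (try in seq_len(20L)) {
          s0 <- pickOne(lo:hi)
          iv <- c(s0, s0 + spanLen - 1L)
          ok <- TRUE
          for (u in usedAS[[g]] %||% list())
            if (iv[1] <= u[2] && u[1] <= iv[2]) { ok <- FALSE; break }
          if (ok) { cand <- iv; break }
        }
        if (is.null(cand)) next
        stx <- if (geneStrand[[g]] == "+") "-" else "+"
        usedAS[[g]] <- c(usedAS[[g]] %||% list(), list(cand))
        addCand(c(cand[1], cand[1] + 150L + 250L),
                c(cand[1] + 149L, cand[1] + 150L + 250L + 149L),
                stx, "antisense", NA_character_)
        placed <- TRUE
        break
      }
      if (!placed)
        stopf("generation error: cannot generate class antisense")
    }

    # intergenic zone: >= 1 kb beyond all reference transcripts
    zoneStart <- max(unlist(rp$exEnds)) + 1001L
    zoneEnd <- gl - 1050L
    cursor <- zoneStart
    nShort <- round((config$short_rate) * mixN(nc, "intergenic"))
    for (k in seq_len(mixN(nc, "intergenic"))) {
      if (k <= nShort) { exw <- c(80L, 90L) } else {
        exw <- sample(seq(config$exon_length[1], config$exon_length[2]),
                      sample(2:3, 1L), replace = TRUE)
      }
      inw <- sample(200:400, length(exw) - 1L, replace = TRUE)
      span <- sum(exw) + sum(inw)
      if (cursor + span > zoneEnd)
        stopf("generation error: cannot place class intergenic (zone full)")
      stx <- sample(c("+", "-"), 1L)
      starts <- cursor + cumsum(c(0L, head(exw, -1L) + inw))
      ends <- starts + exw - 1L
      is_ <- ends[-length(ends)] + 1L; ie_ <- starts[-1] - 1L
      chars <- plantSpliceSites(chars, is_, ie_, stx)
      protected <- c(protected, is_, is_ + 1L, ie_ - 1L, ie_)
      addCand(starts, ends, stx, "intergenic", NA_character_)
      cursor <- cursor + span + sample(200:500, 1L)
    }

    for (k in seq_len(mixN(nc, "mono_exonic_novel"))) {
      w <- sample(250:600, 1L)
      if (cursor + w > zoneEnd)
        stopf("generation error: cannot place class mono_exonic_novel")
      stx <- sample(c("+", "-"), 1L)
      addCand(cursor, cursor + w - 1L, stx, "mono_exonic_novel",
              NA_character_)
      cursor <- cursor + w + sample(200:500, 1L)
    }

    nCand <- length(outSt)
    ids <- sprintf("CAND%04d", seq_len(nCand))
    ctd <- S4Vectors::DataFrame(
      transcript_id = ids,
      gene_id = ifelse(is.na(outGene), ids, outGene),
      true_class = outClass, true_gene = outGene)
    exList <- lapply(seq_len(nCand), function(i)
      GenomicRanges::GRanges(contig,
        IRanges::IRanges(outSt[[i]], outEn[[i]]), strand = outStrand[i]))
    names(exList) <- ids
    candidates <- TranscriptSet(GenomicRanges::GRangesList(exList), ctd)

    tesWindowPlain <- function(st, en, strand)
      if (strand == "+") {
        tes <- en[length(en)]
        if (tes + 1L > gl) integer() else seq(tes + 1L, min(tes + 20L, gl))
      } else {
        tes <- st[1]
        if (tes - 1L < 1L) integer() else seq(max(1L, tes - 20L), tes - 1L)
      }

    # A-rich tracts downstream of selected TESs (transcript orientation);
    # windows hitting protected splice dinucleotides are skipped.
    nA <- round(config$a_tract_rate * nCand)
    nDone <- 0L
    for (i in shuffle(seq_len(nCand))) {
      if (nDone >= nA) break
      win <- tesWindowPlain(outSt[[i]], outEn[[i]], outStrand[i])
      if (length(win) < 20L || any(win %in% protected)) next
      pos <- sort(sample(win, 16L))
      chars[pos] <- if (outStrand[i] == "+") "A" else "T"
      nDone <- nDone + 1L
    }

    # simulated repeats: TE insertions at a fraction of novel-gene TSSs,
    # internal elements on some multi-exon candidates
    novelIdx <- which(outClass %in% c("antisense", "intergenic",
                                      "mono_exonic_novel"))
    nTE <- round(config$te_insertion_rate * length(novelIdx))
    reps <- list()
    ltrNames <- c("LTR7", "HERVH-int", "MLT2A1", "THE1D")
    for (i in head(shuffle(novelIdx), nTE)) {
      tss <- if (outStrand[i] == "+") outSt[[i]][1]
             else outEn[[i]][length(outEn[[i]])]
      reps[[length(reps) + 1L]] <- GenomicRanges::GRanges(contig,
        IRanges::IRanges(max(1L, tss - 100L), min(gl, tss + 100L)),
        strand = sample(c("+", "-"), 1L),
        repeat_name = sample(ltrNames, 1L), repeat_class = "LTR",
        repeat_family = sample(c("ERV1", "ERVL-MaLR"), 1L))
    }
    for (i in head(shuffle(seq_len(nCand)), 10L)) {   # internal elements
      if (length(outSt[[i]]) < 2L) next
      reps[[length(reps) + 1L]] <- GenomicRanges::GRanges(contig,
        IRanges::IRanges(outSt[[i]][2],
                         min(outEn[[i]][2], outSt[[i]][2] + 120L)),
        strand = sample(c("+", "-"), 1L),
        repeat_name = sample(c("L1M5", "AluY", "MIR"), 1L),
        repeat_class = sample(c("LINE", "SINE"), 1L),
        repeat_family = sample(c("L1", "Alu", "MIR"), 1L))
    }
    repeats <- if (length(reps)) do.call(c, reps) else GenomicRanges::GRanges()

    genome2 <- charsToGenome(chars, contig)

    # truth intra-priming by direct window slicing of the final genome
    ip <- vapply(seq_len(nCand), function(i) {
      win <- tesWindowPlain(outSt[[i]], outEn[[i]], outStrand[i])
      if (length(win) == 0L) return(FALSE)
      b <- chars[win]
      if (outStrand[i] == "-") b <- rev(chartr("ACGT", "TGCA", b))
      (sum(b == "A") / length(b)) > 0.6
    }, NA)
    ctd$true_intra_priming <- ip
    candidates@txData <- ctd
    list(candidates = candidates, genome = genome2, repeats = repeats)
  })
}

mixN <- function(nc, cls) if (cls %in% names(nc)) as.integer(nc[[cls]]) else 0L
`%||%` <- function(a, b) if (is.null(a)) b else a


#' Simulate per-sample splice-junction evidence
#'
#' Junctions of candidates marked supported receive at least one uniquely
#' mapped read in at least three samples; each unsupported candidate owns a
#' private junction with unique-read counts in at most two samples.
#'
#' @param config A [simulationConfig()].
#' @param candidates Candidate `TranscriptSet` from [simulateCandidates()].
#' @return List with `junctions` (long-format table as from
#'   [readJunctionTables()]) and `supported` (named logical per candidate;
#'   mono-exonic candidates are vacuously supported).
#' @export
simulateJunctions <- function(config, candidates) {
  validateSimulationConfig(config)
  withSeed(config$seed + 3L, {
    samples <- as.vector(t(outer(STAGE_LEVELS,
      seq_len(config$n_samples_per_stage),
      function(s, i) sprintf("%s_r%d", s, i))))
    nS <- length(samples)
    n <- length(candidates)
    if (n == 0L)
      return(list(junctions = data.frame(sample = character(),
        contig = character(), start = integer(), end = integer(),
        strand = character(), unique_count = integer(),
        multi_count = integer()), supported = logical()))
    pc <- txChainsPlain(candidates)
    nIn <- lengths(pc$intrStarts)
    contig <- pc$contig[1]
    candKeys <- lapply(seq_len(n), function(i)
      if (nIn[i] == 0L) character()
      else paste(pc$intrStarts[[i]], pc$intrEnds[[i]], sep = "-"))
    # junction -> candidate users
    users <- list()
    jstrand <- list()
    for (i in seq_len(n)) {
      for (k in candKeys[[i]]) {
        users[[k]] <- c(users[[k]], i)
        jstrand[[k]] <- pc$strand[i]
      }
    }
    supported <- rep(TRUE, n)
    weak <- character()
    target <- round(config$unsupported_rate * sum(nIn > 0L))
    nDone <- 0L
    for (i in shuffle(which(nIn > 0L))) {
      if (nDone >= target) break
      priv <- Filter(function(k) all(users[[k]] == i | !supported[users[[k]]]),
                     candKeys[[i]])
      if (length(priv) == 0L) next
      supported[i] <- FALSE
      weak <- c(weak, priv[[1]])
      nDone <- nDone + 1L
    }
    rows <- list()
    for (k in names(users)) {
      se <- as.integer(strsplit(k, "-")[[1]])
      if (k %in% weak) {
        sel <- sample(nS, 2L)
        uc <- 1L + rpois(2L, 1)
      } else {
        ns <- max(3L, rbinom(1L, nS, 0.7))
        sel <- sample(nS, ns)
        uc <- 1L + rpois(length(sel), 4)
      }
      rows[[length(rows) + 1L]] <- data.frame(sample = samples[sel],
        contig = contig, start = se[1], end = se[2],
        strand = jstrand[[k]], unique_count = uc,
        multi_count = rpois(length(sel), 1), stringsAsFactors = FALSE)
    }
    junctions <- do.call(rbind, rows)
    junctions <- junctions[order(junctions$sample, junctions$start), ]
    rownames(junctions) <- NULL
    # truth support by direct recount from the emitted tables
    withSup <- junctions[junctions$unique_count >= 1L, , drop = FALSE]
    supCount <- vapply(split(withSup$sample,
                             paste(withSup$start, withSup$end, sep = "-")),
                       function(s) length(unique(s)), 0L)
    for (i in which(nIn > 0L)) {
      nSup <- supCount[candKeys[[i]]]
      nSup[is.na(nSup)] <- 0L
      supported[i] <- all(nSup >= 3L)
    }
    names(supported) <- txIds(candidates)
    list(junctions = junctions, supported = supported)
  })
}

#' Simulate stage-structured expression
#'
#' Negative-binomial counts with stage-specific means and a TPM matrix whose
#' columns each sum to 1e6. A fraction of genes (the EGA set) is up-shifted
#' by `ega_shift_magnitude` from the 8C stage onward; their pre-activation
#' baseline is low.
#'
#' @param config A [simulationConfig()].
#' @param candidates Candidate `TranscriptSet`.
#' @return List with `counts`, `tpm` (isoform x sample matrices), `length`
#'   (spliced lengths), `design` (sample/stage data.frame) and `ega_genes`
#'   (character vector of shifted gene labels; novel candidates count as
#'   their own gene).
#' @export
simulateExpression <- function(config, candidates) {
  validateSimulationConfig(config)
  withSeed(config$seed + 4L, {
    samples <- as.vector(t(outer(STAGE_LEVELS,
      seq_len(config$n_samples_per_stage),
      function(s, i) sprintf("%s_r%d", s, i))))
    stage <- rep(STAGE_LEVELS, each = config$n_samples_per_stage)
    design <- data.frame(sample = samples, stage = stage,
                         stringsAsFactors = FALSE)
    n <- length(candidates)
    lens <- splicedLength(candidates)
    if (n == 0L) {
      return(list(counts = matrix(0, 0, length(samples),
                                  dimnames = list(NULL, samples)),
                  tpm = matrix(0, 0, length(samples),
                               dimnames = list(NULL, samples)),
                  length = lens, design = design, ega_genes = character()))
    }
    gene <- as.character(txData(candidates)$gene_id)
    genes <- unique(gene)
    egaGenes <- sample(genes, round(config$ega_gene_fraction * length(genes)))
    muBase <- rlnorm(n, meanlog = log(100), sdlog = 1)
    isEga <- gene %in% egaGenes
    muBase[isEga] <- muBase[isEga] * 0.2
    post <- stage %in% c("8C", "morula", "blastocyst")
    counts <- matrix(0L, n, length(samples),
                     dimnames = list(txIds(candidates), samples))
    size <- 1 / config$dispersion
    for (j in seq_along(samples)) {
      mu <- muBase
      if (post[j]) mu[isEga] <- mu[isEga] * config$ega_shift_magnitude
      counts[, j] <- rnbinom(n, mu = mu, size = size)
    }
    rate <- counts / lens
    cs <- colSums(rate)
    cs[cs == 0] <- 1
    tpm <- sweep(rate, 2, cs, "/") * 1e6
    list(counts = counts, tpm = tpm, length = lens, design = design,
         ega_genes = egaGenes)
  })
}

#' Simulate a complete labelled bundle
#'
#' Orchestrates [simulateGenome()], [simulateReference()],
#' [simulateCandidates()], [simulateJunctions()] and [simulateExpression()]
#' into a [TruthBundle-class] whose truth table records, per candidate, the
#' expected outcome of every downstream filter.
#'
#' @param config A [simulationConfig()].
#' @return A `TruthBundle`.
#' @export
simulateTruthBundle <- function(config) {
  genome <- simulateGenome(config)
  ref <- simulateReference(config, genome)
  cand <- simulateCandidates(config, ref$reference, ref$genome)
  jx <- simulateJunctions(config, cand$candidates)
  expr <- simulateExpression(config, cand$candidates)
  ctd <- txData(cand$candidates)
  lens <- splicedLength(cand$candidates)
  truth <- S4Vectors::DataFrame(
    transcript_id = ctd$transcript_id,
    true_class = ctd$true_class,
    spliced_length = as.integer(lens),
    short_length = lens < 200L,
    intra_priming = ctd$true_intra_priming,
    junction_unsupported = !jx$supported[ctd$transcript_id],
    excluded_class = ctd$true_class %in% c("ISM", "mono_exonic_novel"))
  truth$survives <- !truth$short_length & !truth$intra_priming &
    !truth$junction_unsupported & !truth$excluded_class
  new("TruthBundle", genome = cand$genome, reference = ref$reference,
      candidates = cand$candidates, junctions = jx$junctions,
      repeats = cand$repeats, expression = expr, truth = truth,
      config = unclass(config))
}

#' Write a TruthBundle to standard files
#'
#' Writes genome FASTA, reference and candidate GTFs, per-sample STAR-style
#' junction tables, a BED6+2 repeat annotation, counts/TPM TSVs, the stage
#' design TSV and the truth table.
#'
#' @param bundle A [TruthBundle-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTruthBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenomeFasta(bundle@genome, file.path(dir, "genome.fa"))
  writeTranscriptGTF(bundle@reference, file.path(dir, "reference.gtf"))
  writeTranscriptGTF(bundle@candidates, file.path(dir, "candidates.gtf"))
  writeJunctionTables(bundle@junctions, file.path(dir, "sj"))
  writeRepeatsBed(bundle@repeats, file.path(dir, "repeats.bed"))
  writeMatrixTSV(bundle@expression$counts, file.path(dir, "counts.tsv"),
                 "transcript_id")
  writeMatrixTSV(bundle@expression$tpm, file.path(dir, "tpm.tsv"),
                 "transcript_id")
  write.table(bundle@expression$design, file.path(dir, "design.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(bundle@truth), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
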