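# Structural classification against the reference: site sets, decision
# procedure, novel-gene formation, collapsing, canonicality and printed
# summary arithmetic.

test_that("donor and acceptor sites are strand-resolved intron boundaries", {
  plus <- makeTS(list(starts = c(101, 301), ends = c(200, 400),
                      strand = "+", id = "t1", gene = "g1"))
  idx <- buildReferenceIndex(plus)
  expect_equal(idx@donors[["chrS:+"]], 201)
  expect_equal(idx@acceptors[["chrS:+"]], 300)
  minus <- makeTS(list(starts = c(101, 301), ends = c(200, 400),
                       strand = "-", id = "t1", gene = "g1"))
  idx2 <- buildReferenceIndex(minus)
  expect_equal(idx2@donors[["chrS:-"]], 300)
  expect_equal(idx2@acceptors[["chrS:-"]], 201)
})

test_that("index site sets equal brute-force enumeration on a simulated reference", {
  ref <- sharedBundle(7)@reference
  idx <- buildReferenceIndex(ref)
  brute <- bruteSiteSets(ref)
  for (k in names(brute$donors)) {
    expect_equal(idx@donors[[k]], brute$donors[[k]])
    expect_equal(idx@acceptors[[k]], brute$acceptors[[k]])
  }
  expect_error(buildReferenceIndex(makeTS(
    list(starts = 1, ends = 100, strand = "+", id = "a", gene = "g"),
    list(starts = 200, ends = 300, strand = "-", id = "b", gene = "g"))),
    "strand-inconsistent")
})

test_that("the decision procedure matches the class definitions", {
  # reference gene with two transcripts contributing introns
  # (201,300) and (401,500)
  ref <- makeTS(
    list(starts = c(101, 301), ends = c(200, 400), strand = "+",
         id = "r1", gene = "g1"),
    list(starts = c(301, 501), ends = c(400, 600), strand = "+",
         id = "r2", gene = "g1"))
  idx <- buildReferenceIndex(ref)
  classOf <- function(starts, ends, strand = "+") {
    ts <- makeTS(list(starts = starts, ends = ends, strand = strand,
                      id = "c", gene = "c"))
    as.character(txData(classifyTranscripts(ts, idx))$class_code)
  }
  # exact chain -> known
  expect_equal(classOf(c(101, 301), c(200, 400)), "known")
  # novel pairing of known donor 201 and known acceptor 500 -> NIC
  expect_equal(classOf(c(101, 501), c(200, 600)), "NIC")
  # novel acceptor 450 -> NNC
  expect_equal(classOf(c(101, 451), c(200, 600)), "NNC")
  # opposite strand inside the gene span -> antisense
  expect_equal(classOf(c(150, 350), c(250, 450), "-"), "antisense")
  # far away -> intergenic
  expect_equal(classOf(c(5101, 5301), c(5200, 5400)), "intergenic")
  # contiguous proper subchain -> ISM
  ref3 <- makeTS(list(starts = c(101, 301, 501), ends = c(200, 400, 600),
                      strand = "+", id = "r1", gene = "g1"))
  idx3 <- buildReferenceIndex(ref3)
  ts <- makeTS(list(starts = c(301, 501), ends = c(400, 600),
                    strand = "+", id = "c", gene = "c"))
  expect_equal(as.character(
    txData(classifyTranscripts(ts, idx3))$class_code), "ISM")
  # single exon overlapping nothing -> mono_exonic_novel
  ts1 <- makeTS(list(starts = 5000, ends = 5400, strand = "+",
                     id = "c", gene = "c"))
  expect_equal(as.character(
    txData(classifyTranscripts(ts1, idx))$class_code), "mono_exonic_novel")
})

test_that("classification recovers generator truth and ignores input order", {
  b <- sharedBundle(7)
  idx <- buildReferenceIndex(b@reference)
  cl <- classifyTranscripts(b@candidates, idx)
  expect_equal(as.character(txData(cl)$class_code),
               as.character(txData(b@candidates)$true_class))
  perm <- withr::with_seed(1, sample(length(b@candidates)))
  clP <- classifyTranscripts(b@candidates[perm], idx)
  expect_equal(as.character(txData(clP)$class_code),
               as.character(txData(cl)$class_code)[perm])
})

test_that("class lattice consistency holds on simulated bundles", {
  for (seed in c(2, 5)) {
    b <- sharedBundle(seed)
    idx <- buildReferenceIndex(b@reference)
    cl <- classifyTranscripts(b@candidates, idx)
    td <- txData(cl)
    sites <- bruteSiteSets(b@reference)
    intr <- txIntrons(cl)
    for (i in which(td$class_code == "known")) {
      gr <- intr[[i]]
      strand <- as.character(strand(gr))[1]
      key <- paste0("chrS:", strand)
      d <- if (strand == "+") start(gr) else end(gr)
      a <- if (strand == "+") end(gr) else start(gr)
      # known => every site is annotated => could never satisfy NNC
      expect_true(all(d %in% sites$donors[[key]]))
      expect_true(all(a %in% sites$acceptors[[key]]))
    }
    expect_false(any(is.na(td$assigned_gene[td$class_code %in%
      c("known", "ISM", "NIC", "NNC")])))
  }
})

test_that("novel gene assignment equals connected components of the overlap graph", {
  # two overlapping same-strand isoforms share a gene; a third apart does not
  ts <- makeTS(
    list(starts = 1000, ends = 1500, strand = "+", id = "a", gene = "a"),
    list(starts = 1400, ends = 1900, strand = "+", id = "b", gene = "b"),
    list(starts = 5000, ends = 5500, strand = "+", id = "c", gene = "c"),
    list(starts = 1400, ends = 1900, strand = "-", id = "d", gene = "d"))
  td <- txData(ts)
  td$class_code <- "intergenic"
  td$assigned_gene <- NA_character_
  ts@txData <- td
  out <- txData(assignNovelGenes(ts))
  expect_equal(out$assigned_gene[1], out$assigned_gene[2])
  expect_false(out$assigned_gene[1] == out$assigned_gene[3])
  expect_false(out$assigned_gene[1] == out$assigned_gene[4])

  skip_if_not_installed("igraph")
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- 30
      starts <- sample(1000:20000, n)
      ends <- starts + sample(200:2000, n, replace = TRUE)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      args <- lapply(seq_len(n), function(i)
        list(starts = starts[i], ends = ends[i], strand = strands[i],
             id = paste0("t", i), gene = paste0("t", i)))
      ts <- do.call(makeTS, args)
      td <- txData(ts)
      td$class_code <- "intergenic"
      td$assigned_gene <- NA_character_
      ts@txData <- td
      got <- txData(assignNovelGenes(ts))$assigned_gene
      # oracle: connected components of the same-strand overlap graph
      adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
        strands[i] == strands[j] && starts[i] <= ends[j] &&
          starts[j] <= ends[i]))
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      comp <- igraph::components(g)$membership
      expect_equal(length(unique(got)), length(unique(comp)))
      expect_equal(as.integer(factor(got, levels = unique(got))),
                   as.integer(factor(comp, levels = unique(comp))))
    }
  })
})

test_that("collapse merges within the 1000 bp wobble and is idempotent", {
  base <- list(starts = c(1000, 3000, 5000), ends = c(2000, 3500, 6000),
               strand = "+", id = "a", gene = "g")
  shifted <- base; shifted$id <- "b"
  shifted$starts[1] <- 1800; shifted$ends[3] <- 6800   # 800 bp at both ends
  far <- base; far$id <- "c"
  far$starts[1] <- 2200 - 2000   # start shifted by 1200 -> not collapsed
  far$starts[1] <- 1000 - 0
  far2 <- list(starts = c(2200, 3000, 5000), ends = c(2400, 3500, 7200),
               strand = "+", id = "c", gene = "g")
  ts <- makeTS(base, shifted)
  col <- collapseModels(ts)
  expect_equal(length(col$collapsed), 1)
  expect_equal(sort(unique(col$map$representative)), "a")
  # representative takes the most extreme termini
  e <- txExons(col$collapsed)[[1]]
  expect_equal(start(e)[1], 1000)
  expect_equal(end(e)[3], 6800)
  # 1200 bp end shift is beyond the wobble
  far3 <- base; far3$id <- "c"; far3$ends[3] <- 6000 + 1200
  ts2 <- makeTS(base, far3)
  expect_equal(length(collapseModels(ts2)$collapsed), 2)
  # idempotence and identity on singletons
  again <- collapseModels(col$collapsed)
  expect_equal(length(again$collapsed), 1)
  expect_equal(again$map$member, again$map$representative)
  single <- collapseModels(makeTS(base))
  expect_equal(length(single$collapsed), 1)
  expect_equal(single$map$member, single$map$representative)
})

test_that("canonicality audit reads strand-oriented dinucleotides", {
  # + intron 11..20 with GT..AG ; sequence positions 11,12 = GT; 19,20 = AG
  s <- paste0(strrep("A", 10), "GT", strrep("C", 6), "AG", strrep("A", 10))
  g <- genomeFromString(s)
  tsP <- makeTS(list(starts = c(1, 21), ends = c(10, 30), strand = "+",
                     id = "p", gene = "g"))
  aud <- auditCanonical(tsP, g)
  expect_true(aud$isoform[["p"]])
  # - strand: plus-strand bases CT..AC reverse-complement to GT..AG
  s2 <- paste0(strrep("A", 10), "CT", strrep("C", 6), "AC", strrep("A", 10))
  tsM <- makeTS(list(starts = c(1, 21), ends = c(10, 30), strand = "-",
                     id = "m", gene = "g"))
  expect_true(auditCanonical(tsM, genomeFromString(s2))$isoform[["m"]])
  # GT..AC is not in the allowed set
  s3 <- paste0(strrep("A", 10), "GT", strrep("C", 6), "AC", strrep("A", 10))
  expect_false(auditCanonical(tsP, genomeFromString(s3))$isoform[["p"]])
  # GC..AG and AT..AC are canonical
  s4 <- paste0(strrep("A", 10), "GC", strrep("C", 6), "AG", strrep("A", 10))
  expect_true(auditCanonical(tsP, genomeFromString(s4))$isoform[["p"]])
  expect_error(auditCanonical(makeTS(list(starts = c(1, 60), ends = c(10, 70),
    strand = "+", id = "x", gene = "g")), g), "coordinate error")
})

test_that("class summaries reproduce printed-count arithmetic", {
  counts <- c(known = 85697, NIC = 30988, NNC = 79224, antisense = 9457,
              intergenic = 8507)
  genes <- c(antisense = 2466, intergenic = 2773)
  s <- summarizeClasses(counts, genes)
  expect_equal(s$total, 213873)
  pct <- setNames(s$class_table$percent, s$class_table$class)
  expect_equal(pct[["known"]], 40.1)
  expect_equal(pct[["NIC"]], 14.5)
  expect_equal(pct[["NNC"]], 37.0)
  expect_equal(pct[["antisense"]], 4.4)
  expect_equal(pct[["intergenic"]], 4.0)
  expect_equal(s$novel_known_isoforms, 110212)
  expect_equal(s$novel_loci_isoforms, 17964)
  expect_equal(s$novel_genes, 5239)
  avg <- setNames(s$gene_table$mean_isoforms_per_gene,
                  s$gene_table$gene_class)
  expect_equal(avg[["antisense"]], 3.8)
  expect_equal(avg[["intergenic"]], 3.1)
  # one class only -> 100.0%
  s1 <- summarizeClasses(c(known = 17))
  expect_equal(s1$class_table$percent, 100.0)
  # empty input -> empty summary
  s0 <- summarizeClasses(setNames(numeric(), character()))
  expect_equal(s0$total, 0)
})
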