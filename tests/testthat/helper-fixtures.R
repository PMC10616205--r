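# Fixtures and independent oracles used across the suite. Everything is
# built in code; no stored data.

library(GenomicRanges)
library(Biostrings)

# Default-configuration bundles are reused across test files.
.bundleCache <- new.env(parent = emptyenv())
sharedBundle <- function(seed = 7) {
  key <- as.character(seed)
  if (is.null(.bundleCache[[key]]))
    .bundleCache[[key]] <- simulateTruthBundle(simulationConfig(seed = seed))
  .bundleCache[[key]]
}

# A transcript set from a compact spec: list of lists with starts, ends,
# strand, id, gene (1-based closed coordinates on contig "chrS").
makeTS <- function(..., contig = "chrS") {
  txs <- list(...)
  ex <- lapply(txs, function(t)
    GRanges(contig, IRanges(t$starts, t$ends), strand = t$strand))
  td <- S4Vectors::DataFrame(
    transcript_id = vapply(txs, function(t) t$id, ""),
    gene_id = vapply(txs, function(t) t$gene, ""))
  names(ex) <- td$transcript_id
  TranscriptSet(GRangesList(ex), td)
}

genomeFromString <- function(s, name = "chrS") {
  DNAStringSet(setNames(s, name))
}

# Direct, loop-based enumeration of reference donor/acceptor sites
# (independent of ReferenceIndex internals).
bruteSiteSets <- function(reference) {
  intr <- txIntrons(reference)
  ex <- txExons(reference)
  donors <- list(); acceptors <- list()
  for (i in seq_along(intr)) {
    gr <- intr[[i]]
    if (length(gr) == 0) next
    contig <- as.character(seqnames(ex[[i]]))[1]
    strand <- as.character(strand(ex[[i]]))[1]
    key <- paste0(contig, ":", strand)
    for (k in seq_along(gr)) {
      s <- start(gr)[k]; e <- end(gr)[k]
      if (strand == "+") {
        donors[[key]] <- union(donors[[key]], s)
        acceptors[[key]] <- union(acceptors[[key]], e)
      } else {
        donors[[key]] <- union(donors[[key]], e)
        acceptors[[key]] <- union(acceptors[[key]], s)
      }
    }
  }
  list(donors = lapply(donors, sort), acceptors = lapply(acceptors, sort))
}

# Pairwise brute-force AS event oracle: enumerates events between every
# ordered transcript pair of a gene and unions the (type, gene, coords)
# keys. Mirrors the event definitions, not the extraction algorithm.
bruteForceEventKeys <- function(ts) {
  td <- txData(ts); ex <- txExons(ts); intr <- txIntrons(ts)
  ids <- txIds(ts)
  sig <- lapply(seq_along(ids), function(i)
    paste(start(intr[[i]]), end(intr[[i]]), sep = "-"))
  names(sig) <- ids
  keys <- character()
  for (g in unique(as.character(td$gene_id))) {
    gi <- which(td$gene_id == g)
    if (length(gi) < 2) next
    strand <- as.character(strand(ex[[gi[1]]]))[1]
    imat <- lapply(gi, function(i) cbind(start(intr[[i]]), end(intr[[i]])))
    emat <- lapply(gi, function(i) cbind(start(ex[[i]]), end(ex[[i]])))
    names(imat) <- names(emat) <- ids[gi]
    carriers <- function(jxn)
      names(sig)[vapply(sig, function(s) all(jxn %in% s), NA)]
    for (a in ids[gi]) for (b in ids[gi]) {
      if (a == b) next
      iA <- imat[[a]]; iB <- imat[[b]]
      eA <- emat[[a]]; eB <- emat[[b]]
      # SE
      if (nrow(iA) >= 2) for (k in seq_len(nrow(iA) - 1)) {
        if (any(iB[, 1] == iA[k, 1] & iB[, 2] == iA[k + 1, 2]))
          keys <- c(keys, sprintf("SE %s %d:%d:%d:%d", g, iA[k, 1],
                                  iA[k, 2], iA[k + 1, 1], iA[k + 1, 2]))
      }
      # A5 / A3
      for (x in seq_len(nrow(iA))) for (y in seq_len(nrow(iB))) {
        ia <- iA[x, ]; ib <- iB[y, ]
        shareEnd <- ia[2] == ib[2] && ia[1] != ib[1]
        shareStart <- ia[1] == ib[1] && ia[2] != ib[2]
        if (!shareEnd && !shareStart) next
        if ((ia[2] - ia[1]) == (ib[2] - ib[1])) next
        if (any(iA[, 1] == ib[1] & iA[, 2] == ib[2])) next
        if (any(iB[, 1] == ia[1] & iB[, 2] == ia[2])) next
        short <- if ((ia[2] - ia[1]) < (ib[2] - ib[1])) ia else ib
        shortCar <- carriers(sprintf("%d-%d", short[1], short[2]))
        okRegion <- if (shareStart) {
          hi <- max(ia[2], ib[2])
          any(vapply(shortCar, function(t3) {
            em <- emat[[t3]]
            any(em[, 1] == short[2] + 1 & em[, 2] >= hi)
          }, NA))
        } else {
          lo <- min(ia[1], ib[1])
          any(vapply(shortCar, function(t3) {
            em <- emat[[t3]]
            any(em[, 2] == short[1] - 1 & em[, 1] <= lo)
          }, NA))
        }
        if (!okRegion) next
        type <- if (shareEnd) { if (strand == "+") "A5" else "A3" }
                else { if (strand == "+") "A3" else "A5" }
        keys <- c(keys, sprintf("%s %s %d:%d:%d:%d", type, g,
                                min(ia[1], ib[1]), max(ia[1], ib[1]),
                                min(ia[2], ib[2]), max(ia[2], ib[2])))
      }
      # RI
      if (nrow(iA) >= 1) for (k in seq_len(nrow(iA))) {
        s <- iA[k, 1]; e <- iA[k, 2]
        x1 <- eA[k, 1]; x2 <- eA[k + 1, 2]
        if (any(eB[, 1] == x1 & eB[, 2] == x2))
          keys <- c(keys, sprintf("RI %s %d:%d:%d:%d", g, x1, s, e, x2))
      }
      # MX
      if (nrow(eA) >= 3 && nrow(eB) >= 3) {
        for (k in 2:(nrow(eA) - 1)) for (l in 2:(nrow(eB) - 1)) {
          E1 <- eA[k, ]; E2 <- eB[l, ]
          D1 <- iA[k - 1, 1]; A1 <- iA[k, 2]
          D2 <- iB[l - 1, 1]; A2 <- iB[l, 2]
          if (D1 != D2 || A1 != A2) next
          if (E1[1] > E2[1]) { tmp <- E1; E1 <- E2; E2 <- tmp }
          if (E1[2] >= E2[1]) next
          f1 <- c(sprintf("%d-%d", D1, E1[1] - 1),
                  sprintf("%d-%d", E1[2] + 1, A1))
          f2 <- c(sprintf("%d-%d", D1, E2[1] - 1),
                  sprintf("%d-%d", E2[2] + 1, A1))
          c1 <- carriers(f1); c2 <- carriers(f2)
          if (length(c1) == 0 || length(c2) == 0) next
          if (length(intersect(c1, c2))) next
          keys <- c(keys, sprintf("MX %s %d:%d:%d:%d:%d:%d", g, D1, E1[1],
                                  E1[2], E2[1], E2[2], A1))
        }
      }
      # AF / AL
      if (nrow(iA) >= 1 && nrow(iB) >= 1) {
        combos <- list(
          list(side = "first", ea = eA[1, ], eb = eB[1, ],
               ja = iA[1, ], jb = iB[1, ]),
          list(side = "last", ea = eA[nrow(eA), ], eb = eB[nrow(eB), ],
               ja = iA[nrow(iA), ], jb = iB[nrow(iB), ]))
        for (cm in combos) {
          shared <- if (cm$side == "first")
            cm$ja[2] == cm$jb[2] && cm$ja[1] != cm$jb[1]
          else cm$ja[1] == cm$jb[1] && cm$ja[2] != cm$jb[2]
          if (!shared) next
          if (all(cm$ea == cm$eb)) next
          if (cm$ea[1] <= cm$eb[2] && cm$eb[1] <= cm$ea[2]) next
          ja <- sprintf("%d-%d", cm$ja[1], cm$ja[2])
          jb <- sprintf("%d-%d", cm$jb[1], cm$jb[2])
          ca <- carriers(ja); cb <- carriers(jb)
          if (length(setdiff(ca, cb)) == 0 ||
              length(setdiff(cb, ca)) == 0) next
          type <- if (cm$side == "first") {
            if (strand == "+") "AF" else "AL"
          } else { if (strand == "+") "AL" else "AF" }
          keys <- c(keys, sprintf("%s %s %d:%d:%d:%d", type, g,
                                  min(cm$ea[1], cm$eb[1]),
                                  max(cm$ea[1], cm$eb[1]),
                                  min(cm$ea[2], cm$eb[2]),
                                  max(cm$ea[2], cm$eb[2])))
        }
      }
    }
  }
  sort(unique(keys))
}

eventKeysOf <- function(events) {
  sort(unique(paste(events$type, events$gene, events$coordinates)))
}

# Adjusted Rand index between two labelings.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumIJ <- sum(choose(tab, 2))
  sumI <- sum(choose(rowSums(tab), 2))
  sumJ <- sum(choose(colSums(tab), 2))
  expect <- sumI * sumJ / choose(n, 2)
  maxIdx <- (sumI + sumJ) / 2
  (sumIJ - expect) / (maxIdx - expect)
}

# Planted co-expression modules: within-module correlation ~rho, exactly
# uncorrelated module factors (residualized), for module-recovery checks.
plantedModules <- function(n_mod = 3, n_per = 50, n_samples = 30,
                           rho = 0.8, seed = 5) {
  withr::with_seed(seed, {
    f <- matrix(rnorm(n_mod * n_samples), n_mod)
    f[1, ] <- scale(f[1, ])[, 1]
    for (k in seq_len(n_mod)[-1]) {
      r <- resid(lm(f[k, ] ~ t(f[seq_len(k - 1), , drop = FALSE])))
      f[k, ] <- scale(r)[, 1]
    }
    X <- do.call(rbind, lapply(seq_len(n_mod), function(k)
      t(replicate(n_per, sqrt(rho) * f[k, ] +
                    sqrt(1 - rho) * rnorm(n_samples)))))
    rownames(X) <- paste0("g", seq_len(nrow(X)))
    colnames(X) <- paste0("s", seq_len(n_samples))
    list(expr = X, labels = rep(seq_len(n_mod), each = n_per))
  })
}

# Planted 8C trajectory shapes over the six stages (peak-up, shift-up,
# shift-down, peak-down), with per-item Gaussian noise.
plantedTrajectories <- function(n_per = 50, noise = 0.12, seed = 3) {
  shapes <- rbind(c(0, 0, 0, 1, 0, 0), c(0, 0, 0, 1, 1, 1),
                  c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 1, 1))
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(1:4, function(k)
      t(replicate(n_per, shapes[k, ] + rnorm(6, 0, noise)))))
    colnames(X) <- stageLevels()
    rownames(X) <- paste0("iso", seq_len(nrow(X)))
    list(profiles = X, labels = rep(1:4, each = n_per))
  })
}

# All 120 permutations of 1..5, generated independently of the package.
allPerms5 <- function() {
  out <- NULL
  for (a in 1:5) for (b in setdiff(1:5, a)) for (c in setdiff(1:5, c(a, b)))
    for (d in setdiff(1:5, c(a, b, c))) {
      e <- setdiff(1:5, c(a, b, c, d))
      out <- rbind(out, c(a, b, c, d, e))
    }
  out
}
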