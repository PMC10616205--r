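# Alternative-splicing layer: extraction of the seven local AS event types
# from transcript structures, percent-spliced-in (PSI) at event and isoform
# level, permutation tests for differential inclusion between stages, and
# fuzzy c-means clustering of inclusion trajectories.

AS_EVENT_TYPES <- c("SE", "A5", "A3", "RI", "MX", "AF", "AL")

# Junction signature of a transcript: "start-end" strings of its introns.
junctionSignature <- function(intr)
  paste(BiocGenerics::start(intr), BiocGenerics::end(intr), sep = "-")

#' Extract alternative-splicing events
#'
#' Derives the seven local AS event types per gene from exon structures:
#' skipped exon (SE), alternative 5' and 3' splice sites (A5/A3), retained
#' intron (RI), mutually exclusive exons (MX), and alternative first/last
#' exons (AF/AL). Inclusion-form conventions: SE includes the exon; RI
#' retains the intron; A5/A3 include the form whose splice site produces
#' the longer exon; MX includes the form using the 5'-most (transcript
#' orientation) alternative exon; AF/AL include the form whose terminal
#' exon is most distal. `inclusion_transcripts` are the gene's transcripts
#' containing the inclusion form's complete junction signature; `total`
#' adds the exclusion-form carriers. Events are deduplicated by (type,
#' coordinates).
#'
#' @param ts A [TranscriptSet-class] with gene assignments.
#' @return data.frame with `event_id`, `type`, `gene`, `coordinates`,
#'   `inclusion_transcripts`, `total_transcripts` (comma-joined id lists).
#' @export
extractEvents <- function(ts) {
  td <- txData(ts)
  ex <- txExons(ts)
  intr <- txIntrons(ts)
  ids <- txIds(ts)
  events <- list()
  addEvent <- function(type, gene, coords, inc, tot) {
    key <- paste(type, gene, coords)
    if (!is.null(events[[key]])) return(invisible())
    events[[key]] <<- data.frame(event_id = paste0(gene, ";", type, ":",
                                                   coords),
      type = type, gene = gene, coordinates = coords,
      inclusion_transcripts = paste(sort(inc), collapse = ","),
      total_transcripts = paste(sort(tot), collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (g in unique(as.character(td$gene_id))) {
    gi <- which(td$gene_id == g)
    if (length(gi) < 2L) next
    strand <- as.character(BiocGenerics::strand(ex[[gi[1]]]))[1]
    sig <- lapply(gi, function(i) junctionSignature(intr[[i]]))
    names(sig) <- ids[gi]
    carriers <- function(jxn) {   # transcripts containing all junctions
      names(sig)[vapply(sig, function(s) all(jxn %in% s), NA)]
    }
    exonsOf <- lapply(gi, function(i)
      cbind(BiocGenerics::start(ex[[i]]), BiocGenerics::end(ex[[i]])))
    intronsOf <- lapply(gi, function(i)
      cbind(BiocGenerics::start(intr[[i]]), BiocGenerics::end(intr[[i]])))
    names(exonsOf) <- names(intronsOf) <- ids[gi]
    allIntrons <- unique(do.call(rbind, intronsOf))

    # SE: consecutive introns (s1,e1),(s2,e2) in one transcript vs direct
    # junction (s1,e2) in the gene
    for (t1 in names(intronsOf)) {
      im <- intronsOf[[t1]]
      if (nrow(im) < 2L) next
      for (k in seq_len(nrow(im) - 1L)) {
        s1 <- im[k, 1]; e1 <- im[k, 2]; s2 <- im[k + 1L, 1]; e2 <- im[k + 1L, 2]
        skip <- sprintf("%d-%d", s1, e2)
        excl <- carriers(skip)
        if (length(excl) == 0L) next
        incJ <- c(sprintf("%d-%d", s1, e1), sprintf("%d-%d", s2, e2))
        inc <- carriers(incJ)
        addEvent("SE", g, sprintf("%d:%d:%d:%d", s1, e1, s2, e2),
                 inc, union(inc, excl))
      }
    }

    # A5/A3: intron pairs sharing one boundary
    if (nrow(allIntrons) >= 2L) {
      for (a in seq_len(nrow(allIntrons) - 1L))
        for (b in (a + 1L):nrow(allIntrons)) {
          ia <- allIntrons[a, ]; ib <- allIntrons[b, ]
          shareEnd <- ia[2] == ib[2] && ia[1] != ib[1]
          shareStart <- ia[1] == ib[1] && ia[2] != ib[2]
          if (!shareEnd && !shareStart) next
          ja <- sprintf("%d-%d", ia[1], ia[2])
          jb <- sprintf("%d-%d", ib[1], ib[2])
          ca <- setdiff(carriers(ja), carriers(jb))
          cb <- setdiff(carriers(jb), carriers(ja))
          if (length(ca) == 0L || length(cb) == 0L) next
          # the shorter intron leaves the longer flanking exon -> inclusion
          wa <- ia[2] - ia[1]; wb <- ib[2] - ib[1]
          if (wa == wb) next
          # the alternative region must be exonic in the short-intron form
          # (otherwise the pattern is an exon skip, not A5/A3)
          short <- if (wa < wb) ia else ib
          shortCarriers <- carriers(sprintf("%d-%d", short[1], short[2]))
          okRegion <- if (shareStart) {
            hi <- max(ia[2], ib[2])
            any(vapply(shortCarriers, function(t3) {
              em <- exonsOf[[t3]]
              any(em[, 1] == short[2] + 1L & em[, 2] >= hi)
            }, NA))
          } else {
            lo <- min(ia[1], ib[1])
            any(vapply(shortCarriers, function(t3) {
              em <- exonsOf[[t3]]
              any(em[, 2] == short[1] - 1L & em[, 1] <= lo)
            }, NA))
          }
          if (!okRegion) next
          incIntron <- if (wa < wb) ja else jb
          inc <- carriers(incIntron)
          tot <- union(carriers(ja), carriers(jb))
          type <- if (shareEnd) { if (strand == "+") "A5" else "A3" }
                  else { if (strand == "+") "A3" else "A5" }
          coords <- sprintf("%d:%d:%d:%d", min(ia[1], ib[1]),
                            max(ia[1], ib[1]), min(ia[2], ib[2]),
                            max(ia[2], ib[2]))
          addEvent(type, g, coords, inc, tot)
        }
    }

    # RI: transcript exon spanning (x1..x2) an intron (s,e) of another
    # transcript whose flanking exons end at s-1 / start at e+1 with outer
    # boundaries x1, x2
    for (t1 in names(intronsOf)) {
      im <- intronsOf[[t1]]
      em <- exonsOf[[t1]]
      if (nrow(im) == 0L) next
      for (k in seq_len(nrow(im))) {
        s <- im[k, 1]; e <- im[k, 2]
        x1 <- em[k, 1]; x2 <- em[k + 1L, 2]
        for (t2 in names(exonsOf)) {
          if (t2 == t1) next
          e2 <- exonsOf[[t2]]
          if (!any(e2[, 1] == x1 & e2[, 2] == x2)) next
          # inclusion = intron-retaining form: carriers of the spanning exon
          inc <- names(exonsOf)[vapply(names(exonsOf), function(t3)
            any(exonsOf[[t3]][, 1] == x1 & exonsOf[[t3]][, 2] == x2), NA)]
          excl <- carriers(sprintf("%d-%d", s, e))
          addEvent("RI", g, sprintf("%d:%d:%d:%d", x1, s, e, x2),
                   inc, union(inc, excl))
        }
      }
    }

    # MX: two internal exons E1 < E2 with common outer donor/acceptor
    # junction pairs, no transcript carrying both
    internal <- unique(do.call(rbind, lapply(names(exonsOf), function(t1) {
      em <- exonsOf[[t1]]
      if (nrow(em) < 3L) return(NULL)
      em[2:(nrow(em) - 1L), , drop = FALSE]
    })))
    if (!is.null(internal) && nrow(internal) >= 2L) {
      for (a in seq_len(nrow(internal) - 1L)) for (b in (a + 1L):nrow(internal)) {
        e1 <- internal[a, ]; e2 <- internal[b, ]
        if (e1[1] > e2[1]) { tmp <- e1; e1 <- e2; e2 <- tmp }
        if (e1[2] >= e2[1]) next     # must not overlap
        j1in <- NULL; j2in <- NULL
        # junctions into/out of each exon present in the gene
        for (D in unique(allIntrons[allIntrons[, 2] == e1[1] - 1L, 1]))
          for (A in unique(allIntrons[allIntrons[, 1] == e1[2] + 1L, 2])) {
            # form 1: D..e1..A ; form 2 uses same D and A around e2
            f1 <- c(sprintf("%d-%d", D, e1[1] - 1L),
                    sprintf("%d-%d", e1[2] + 1L, A))
            f2 <- c(sprintf("%d-%d", D, e2[1] - 1L),
                    sprintf("%d-%d", e2[2] + 1L, A))
            c1 <- carriers(f1); c2 <- carriers(f2)
            if (length(c1) == 0L || length(c2) == 0L) next
            if (length(intersect(c1, c2))) next
            inc <- if (strand == "+") c1 else c2   # 5'-most alternative exon
            addEvent("MX", g, sprintf("%d:%d:%d:%d:%d:%d", D, e1[1], e1[2],
                                      e2[1], e2[2], A),
                     inc, union(c1, c2))
          }
      }
    }

    # AF/AL: distinct terminal exons spliced to a common internal site
    firstJ <- lapply(names(intronsOf), function(t1) {
      im <- intronsOf[[t1]]
      if (nrow(im) == 0L) return(NULL)
      list(tx = t1, exon = exonsOf[[t1]][1, ], j = im[1, ])
    })
    lastJ <- lapply(names(intronsOf), function(t1) {
      im <- intronsOf[[t1]]
      if (nrow(im) == 0L) return(NULL)
      n <- nrow(exonsOf[[t1]])
      list(tx = t1, exon = exonsOf[[t1]][n, ], j = im[nrow(im), ])
    })
    terminalPairs <- function(lst, side) {
      lst <- Filter(Negate(is.null), lst)
      if (length(lst) < 2L) return(invisible())
      for (a in seq_len(length(lst) - 1L)) for (b in (a + 1L):length(lst)) {
        pa <- lst[[a]]; pb <- lst[[b]]
        shared <- if (side == "first") pa$j[2] == pb$j[2] && pa$j[1] != pb$j[1]
                  else pa$j[1] == pb$j[1] && pa$j[2] != pb$j[2]
        if (!shared) next
        if (all(pa$exon == pb$exon)) next
        # distinct, non-overlapping terminal exons
        if (pa$exon[1] <= pb$exon[2] && pb$exon[1] <= pa$exon[2]) next
        ja <- sprintf("%d-%d", pa$j[1], pa$j[2])
        jb <- sprintf("%d-%d", pb$j[1], pb$j[2])
        ca <- carriers(ja); cb <- carriers(jb)
        if (length(setdiff(ca, cb)) == 0L || length(setdiff(cb, ca)) == 0L)
          next
        # distal = 5'-most (AF) or 3'-most (AL) in transcript orientation
        leftIsA <- pa$exon[1] < pb$exon[1]
        distalA <- if (side == "first") (strand == "+") == leftIsA
                   else (strand == "+") != leftIsA
        inc <- if (distalA) ca else cb
        type <- if (side == "first") { if (strand == "+") "AF" else "AL" }
                else { if (strand == "+") "AL" else "AF" }
        coords <- sprintf("%d:%d:%d:%d", min(pa$exon[1], pb$exon[1]),
                          max(pa$exon[1], pb$exon[1]),
                          min(pa$exon[2], pb$exon[2]),
                          max(pa$exon[2], pb$exon[2]))
        addEvent(type, g, coords, inc, union(ca, cb))
      }
    }
    terminalPairs(firstJ, "first")
    terminalPairs(lastJ, "last")
  }
  if (length(events) == 0L)
    return(data.frame(event_id = character(), type = character(),
                      gene = character(), coordinates = character(),
                      inclusion_transcripts = character(),
                      total_transcripts = character()))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Event-level percent spliced in
#'
#' PSI = sum of inclusion-form TPM over sum of total TPM per sample;
#' missing (NA) where the denominator is 0.
#'
#' @param events Event table from [extractEvents()].
#' @param tpm Isoform x sample TPM matrix.
#' @return Event x sample PSI matrix.
#' @export
eventPsi <- function(events, tpm) {
  out <- matrix(NA_real_, nrow(events), ncol(tpm),
                dimnames = list(events$event_id, colnames(tpm)))
  for (i in seq_len(nrow(events))) {
    inc <- strsplit(events$inclusion_transcripts[i], ",")[[1]]
    tot <- strsplit(events$total_transcripts[i], ",")[[1]]
    missing <- setdiff(tot, rownames(tpm))
    if (length(missing))
      stopf("validation error: transcript(s) %s absent from TPM matrix",
            paste(missing, collapse = ","))
    ti <- colSums(tpm[inc, , drop = FALSE])
    tt <- colSums(tpm[tot, , drop = FALSE])
    psi <- ifelse(tt > 0, ti / tt, NA_real_)
    out[i, ] <- psi
  }
  out
}

#' Isoform-level percent spliced in
#'
#' Isoform PSI = isoform TPM over summed gene TPM; missing where the gene
#' TPM is 0.
#'
#' @param ts A [TranscriptSet-class] with gene assignment.
#' @param tpm Isoform x sample TPM matrix.
#' @return Isoform x sample PSI matrix.
#' @export
isoformPsi <- function(ts, tpm) {
  gene <- setNames(as.character(txData(ts)$gene_id), txIds(ts))
  common <- intersect(rownames(tpm), names(gene))
  m <- tpm[common, , drop = FALSE]
  geneSum <- rowsum(m, gene[common])
  denom <- geneSum[gene[common], , drop = FALSE]
  psi <- m / denom
  psi[denom == 0] <- NA_real_
  psi
}

#' Differential inclusion between two stages
#'
#' Permutation test on PSI values: delta is the difference of stage means
#' over defined values; the p-value is the fraction of sample-label
#' permutations whose absolute delta is at least the observed one, counting
#' the identity permutation. All distinct splits are enumerated exactly
#' when their number is at most `n_permutations`; otherwise Monte Carlo
#' with `seed` (identity included). Significance requires p < `p_threshold`
#' and |delta| > `delta_threshold`.
#'
#' @param psi Feature x sample PSI matrix.
#' @param design data.frame with `sample`, `stage`.
#' @param stage_a,stage_b The two stages (delta = mean(b) - mean(a)).
#' @param n_permutations Permutation budget (default 2000).
#' @param seed RNG seed for the Monte Carlo branch.
#' @param p_threshold,delta_threshold Decision thresholds (defaults 0.05
#'   and 0.1).
#' @return data.frame with `feature`, `delta_psi`, `p_value`, `significant`,
#'   `testable`.
#' @export
diffPsi <- function(psi, design, stage_a, stage_b, n_permutations = 2000L,
                    seed = 1L, p_threshold = 0.05, delta_threshold = 0.1) {
  sa <- design$sample[design$stage == stage_a]
  sb <- design$sample[design$stage == stage_b]
  out <- data.frame(feature = rownames(psi), delta_psi = NA_real_,
                    p_value = NA_real_, significant = FALSE,
                    testable = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(psi))) {
    xa <- psi[i, sa]; xb <- psi[i, sb]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L) next
    res <- permutationDeltaTest(xa, xb, n_permutations, seed + i)
    out$delta_psi[i] <- res$delta
    out$p_value[i] <- res$p
    out$testable[i] <- TRUE
    out$significant[i] <- res$p < p_threshold &&
      abs(res$delta) > delta_threshold
  }
  out
}

# Core two-group permutation test on the difference of means.
permutationDeltaTest <- function(xa, xb, n_permutations, seed) {
  pool <- c(xa, xb)
  na <- length(xa); n <- length(pool)
  obs <- mean(xb) - mean(xa)
  nSplits <- choose(n, na)
  if (nSplits <= n_permutations) {
    idx <- combn(n, na)
    deltas <- apply(idx, 2, function(ii)
      mean(pool[-ii]) - mean(pool[ii]))
    p <- mean(abs(deltas) >= abs(obs) - 1e-12)
  } else {
    deltas <- withSeed(seed, vapply(seq_len(n_permutations - 1L),
      function(k) {
        ii <- sample.int(n, na)
        mean(pool[-ii]) - mean(pool[ii])
      }, 0))
    p <- (1 + sum(abs(deltas) >= abs(obs) - 1e-12)) / n_permutations
  }
  list(delta = obs, p = p)
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means with Euclidean distance on standardized profiles:
#' memberships `u_ij` proportional to `d_ij^(-2/(m-1))`, centers the
#' membership^m-weighted means, iterated until the largest center shift
#' falls below `tol`. The objective `sum u^m d^2` is non-increasing per
#' iteration. Rows with zero distance to a center get membership 1 there.
#'
#' @param profiles Items x conditions numeric matrix (standardize rows
#'   first; see [standardizeRows()]).
#' @param c Number of clusters (>= 2, < number of rows).
#' @param m Fuzzifier (> 1; default 1.25).
#' @param seed Seed for the random initial centers.
#' @param tol Convergence tolerance on the center shift.
#' @param max_iter Iteration cap.
#' @return List of class `FuzzyClusters`: `centers` (c x conditions),
#'   `membership` (items x c, rows summing to 1), `cluster` (argmax
#'   assignment), `objective` (per-iteration values), `m`.
#' @export
fuzzyCMeans <- function(profiles, c, m = 1.25, seed = 1L, tol = 1e-6,
                        max_iter = 200L) {
  X <- as.matrix(profiles)
  n <- nrow(X)
  if (c < 2L) stopf("configuration error: c must be >= 2")
  if (c >= n) stopf("configuration error: c (%d) must be < rows (%d)", c, n)
  if (m <= 1) stopf("configuration error: fuzzifier m must be > 1")
  # k-means initialization of the centers; the fuzzy updates then refine
  centers <- withSeed(seed, {
    km <- suppressWarnings(stats::kmeans(X, centers = c, nstart = 10L,
                                         iter.max = 50L))
    km$centers
  })
  membershipOf <- function(D2) {
    U <- matrix(0, n, c)
    zero <- D2 < 1e-16
    anyZero <- rowSums(zero) > 0L
    pw <- D2^(-1 / (m - 1))
    U[!anyZero, ] <- pw[!anyZero, , drop = FALSE] /
      rowSums(pw[!anyZero, , drop = FALSE])
    if (any(anyZero))
      U[anyZero, ] <- zero[anyZero, , drop = FALSE] /
        rowSums(zero[anyZero, , drop = FALSE])
    U
  }
  dist2 <- function(centers) {
    D2 <- matrix(0, n, c)
    for (k in seq_len(c))
      D2[, k] <- rowSums(sweep(X, 2, centers[k, ])^2)
    D2
  }
  objective <- numeric()
  for (iter in seq_len(max_iter)) {
    D2 <- dist2(centers)
    U <- membershipOf(D2)
    objective <- c(objective, sum(U^m * D2))
    Um <- U^m
    newCenters <- (t(Um) %*% X) / colSums(Um)
    shift <- max(abs(newCenters - centers))
    centers <- newCenters
    if (shift < tol) break
  }
  D2 <- dist2(centers)
  U <- membershipOf(D2)
  objective <- c(objective, sum(U^m * D2))
  rownames(centers) <- paste0("C", seq_len(c))
  dimnames(U) <- list(rownames(X), rownames(centers))
  structure(list(centers = centers, membership = U,
                 cluster = setNames(max.col(U), rownames(X)),
                 objective = objective, m = m), class = "FuzzyClusters")
}

#' Standardize profile rows
#'
#' Per-row mean 0, variance 1; rows with zero variance are dropped.
#' @param x Numeric matrix.
#' @return List with `profiles` (standardized matrix) and `dropped`
#'   (row names with zero variance).
#' @export
standardizeRows <- function(x) {
  sds <- apply(x, 1, sd)
  keep <- !is.na(sds) & sds > 0
  z <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) /
    sds[keep]
  list(profiles = z, dropped = rownames(x)[!keep])
}

#' Cluster switching isoforms by inclusion trajectory
#'
#' Restricts to isoforms with a statistically significant switching event
#' in at least one stage comparison, computes stage-mean PSI profiles,
#' standardizes them and clusters with [fuzzyCMeans()]. Cluster summaries
#' report the direction at the focal stage (more or less included) and the
#' dynamics (transient peak when the final stage returns to the opposite
#' sign of the focal value, sustained shift otherwise).
#'
#' @param diff_results data.frame(s) from [diffPsi()] (rbind over
#'   transitions) with `feature` and `significant`.
#' @param psi Feature x sample PSI matrix.
#' @param design data.frame with `sample`, `stage`.
#' @param c Number of clusters (default 4).
#' @param m Fuzzifier (default 1.25).
#' @param seed,tol,max_iter Passed to [fuzzyCMeans()].
#' @param focal_stage Stage used for direction labels (default `"8C"`).
#' @return A `FuzzyClusters` list with additional `stage_means`, `summary`
#'   (cluster, direction, dynamics) and `dropped`; `NULL` when no isoform
#'   is significant.
#' @export
clusterSwitchingIsoforms <- function(diff_results, psi, design, c = 4L,
                                     m = 1.25, seed = 1L, tol = 1e-6,
                                     max_iter = 200L, focal_stage = "8C") {
  sig <- unique(diff_results$feature[diff_results$significant])
  sig <- intersect(sig, rownames(psi))
  if (length(sig) == 0L) return(NULL)
  stages <- intersect(STAGE_LEVELS, unique(as.character(design$stage)))
  prof <- sapply(stages, function(st) {
    cols <- design$sample[design$stage == st]
    rowMeans(psi[sig, cols, drop = FALSE], na.rm = TRUE)
  })
  prof <- matrix(prof, nrow = length(sig),
                 dimnames = list(sig, stages))
  stz <- standardizeRows(prof)
  fc <- fuzzyCMeans(stz$profiles, c = c, m = m, seed = seed, tol = tol,
                    max_iter = max_iter)
  ctr <- fc$centers
  fi <- match(focal_stage, colnames(ctr))
  dirn <- ifelse(ctr[, fi] > 0, "more_included", "less_included")
  dyn <- ifelse(sign(ctr[, ncol(ctr)]) != sign(ctr[, fi]), "peak", "shift")
  fc$stage_means <- prof
  fc$dropped <- stz$dropped
  fc$summary <- data.frame(cluster = rownames(ctr), direction = dirn,
                           dynamics = dyn, row.names = NULL)
  fc
}
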