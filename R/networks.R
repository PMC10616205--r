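# Expression and network layer: median-ratio normalization, the per-gene
# isoform-novelty statistic, stage detection, signed co-expression
# adjacency and topological overlap, module detection with eigengene
# merging and novelty enrichment, promoter windows, and the
# correlation-filtered TF-target and SF-isoform networks.

#' Median-ratio size factors
#'
#' Per-sample median of count / geometric-mean ratios over genes with a
#' nonzero geometric mean (the median-of-ratios normalization of bulk
#' RNA-seq).
#'
#' @param counts Gene x sample count matrix.
#' @return Named positive numeric per sample.
#' @export
medianRatioSizeFactors <- function(counts) {
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use))
    stopf("normalization error: no gene is positive in all samples")
  sf <- apply(counts[use, , drop = FALSE], 2, function(col)
    exp(median(log(col) - logGeo[use])))
  if (any(!is.finite(sf) | sf <= 0))
    stopf("normalization error: non-positive size factor")
  sf
}

#' Size-factor normalization with log10 transform
#'
#' value = log10(count / factor + 1).
#' @param counts Gene x sample counts.
#' @param factors Size factors from [medianRatioSizeFactors()].
#' @return Normalized matrix.
#' @export
normalizeLog10 <- function(counts, factors) {
  log10(sweep(counts, 2, factors, "/") + 1)
}

#' Per-gene, per-stage isoform novelty percentage
#'
#' For each stage, keeps genes with total gene count strictly greater than
#' `min_count` in every sample of that stage, computes per sample the
#' percentage of the gene's counts attributable to novel isoforms (any
#' class other than `known`), and averages arithmetically over the stage's
#' samples. Also reports, per stage, the fraction of kept genes
#' predominantly transcribed as novel isoforms (stage value > 50).
#'
#' @param isoform_counts Isoform x sample count matrix.
#' @param classes Named character: isoform id -> structural class.
#' @param genes Named character: isoform id -> gene id.
#' @param design data.frame with `sample`, `stage`.
#' @param min_count Gene-count threshold (default 10, strict >).
#' @return List with `per_gene` (gene x stage percentage matrix, NA where
#'   the gene fails the count rule) and `fraction_predominant` (named
#'   numeric per stage).
#' @export
noveltyPercentage <- function(isoform_counts, classes, genes, design,
                              min_count = 10) {
  ids <- rownames(isoform_counts)
  gene <- genes[ids]
  novel <- classes[ids] != "known"
  geneTotals <- rowsum(isoform_counts, gene)
  novelTotals <- rowsum(isoform_counts * novel, gene)
  stages <- intersect(STAGE_LEVELS, unique(as.character(design$stage)))
  out <- matrix(NA_real_, nrow(geneTotals), length(stages),
                dimnames = list(rownames(geneTotals), stages))
  for (st in stages) {
    cols <- design$sample[design$stage == st]
    keep <- apply(geneTotals[, cols, drop = FALSE] > min_count, 1, all)
    pct <- 100 * novelTotals[, cols, drop = FALSE] /
      geneTotals[, cols, drop = FALSE]
    out[keep, st] <- rowMeans(pct[keep, , drop = FALSE])
  }
  fracPredominant <- apply(out, 2, function(v)
    if (all(is.na(v))) NA_real_ else mean(v[!is.na(v)] > 50))
  list(per_gene = out, fraction_predominant = fracPredominant)
}

#' Per-stage detection flags and expression bins
#'
#' Stage mean TPM per isoform; detected iff the mean is at least
#' `threshold`.
#'
#' @param tpm Isoform x sample TPM matrix.
#' @param design data.frame with `sample`, `stage`.
#' @param threshold Detection threshold on the stage mean (default 1).
#' @param bins Numeric breaks for expression bins (left-closed).
#' @return List with `mean` (isoform x stage), `detected` (logical matrix)
#'   and `bin` (character matrix).
#' @export
stageDetection <- function(tpm, design, threshold = 1,
                           bins = c(0, 1, 10, 100, Inf)) {
  stages <- intersect(STAGE_LEVELS, unique(as.character(design$stage)))
  mu <- sapply(stages, function(st)
    rowMeans(tpm[, design$sample[design$stage == st], drop = FALSE]))
  mu <- matrix(mu, nrow = nrow(tpm), dimnames = list(rownames(tpm), stages))
  labels <- paste0("[", head(bins, -1), ",", tail(bins, -1), ")")
  bin <- matrix(labels[findInterval(mu, bins, rightmost.closed = FALSE)],
                nrow = nrow(mu), dimnames = dimnames(mu))
  list(mean = mu, detected = mu >= threshold, bin = bin)
}

#' Signed co-expression adjacency
#'
#' a_ij = ((1 + cor(i,j)) / 2)^beta with unit diagonal; zero-variance genes
#' are excluded with a warning.
#'
#' @param normalized Gene x sample normalized expression.
#' @param beta Soft-threshold power (default 13).
#' @return Gene x gene adjacency matrix in `[0,1]`.
#' @export
signedAdjacency <- function(normalized, beta = 13) {
  v <- apply(normalized, 1, sd)
  if (any(v == 0 | is.na(v))) {
    warnf("excluding %d zero-variance gene(s) from the adjacency",
          sum(v == 0 | is.na(v)))
    normalized <- normalized[v > 0 & !is.na(v), , drop = FALSE]
  }
  r <- cor(t(normalized))
  a <- ((1 + r) / 2)^beta
  diag(a) <- 1
  a
}

#' Signed topological overlap matrix
#'
#' TOM_ij = (sum_k a_ik a_kj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' k_i the connectivity excluding the diagonal; TOM_ii = 1.
#'
#' @param adjacency Symmetric adjacency in `[0,1]` with unit diagonal.
#' @return TOM matrix.
#' @export
topologicalOverlap <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  L <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on 1 - TOM with a static cut at
#' `cut_height`; clusters smaller than `min_module_size` are left
#' unassigned (module 0). Modules are labelled 1..k by decreasing size.
#'
#' @param tom TOM matrix.
#' @param min_module_size Minimum module size (default 30).
#' @param cut_height Static tree-cut height (default 0.99).
#' @return List with `module` (named integer per gene, 0 = unassigned) and
#'   `dendrogram` (the hclust object).
#' @export
detectModules <- function(tom, min_module_size = 30L, cut_height = 0.99) {
  d <- as.dist(1 - tom)
  h <- hclust(d, method = "average")
  raw <- cutree(h, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  module <- integer(length(raw))
  names(module) <- names(raw)
  ord <- keep[order(-sizes[keep], as.integer(keep))]
  for (i in seq_along(ord)) module[raw == as.integer(ord[i])] <- i
  list(module = module, dendrogram = h)
}

#' Module eigengenes
#'
#' First principal component of each module's gene-standardized expression,
#' sign-oriented to correlate positively with the module's mean profile.
#' A single-gene module contributes its standardized profile.
#'
#' @param normalized Gene x sample expression.
#' @param module Named integer assignment from [detectModules()].
#' @return Module x sample matrix (rows `ME<label>`, unassigned genes
#'   excluded).
#' @export
moduleEigengenes <- function(normalized, module) {
  labs <- sort(unique(module[module > 0]))
  if (length(labs) == 0L)
    return(matrix(NA_real_, 0L, ncol(normalized),
                  dimnames = list(character(), colnames(normalized))))
  out <- matrix(NA_real_, length(labs), ncol(normalized),
                dimnames = list(paste0("ME", labs), colnames(normalized)))
  for (i in seq_along(labs)) {
    genes <- names(module)[module == labs[i]]
    X <- normalized[genes, , drop = FALSE]
    Z <- t(scale(t(X)))
    Z[is.na(Z)] <- 0
    if (nrow(Z) == 1L) { eg <- as.numeric(Z) } else {
      sv <- svd(Z, nu = 0, nv = 1)
      eg <- sv$v[, 1]
    }
    meanProf <- colMeans(Z)
    if (sum(eg * meanProf) < 0) eg <- -eg
    out[i, ] <- eg
  }
  out
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively merges the module pair with the highest eigengene Pearson
#' correlation at or above `threshold`, recomputing eigengenes after each
#' merge, until none qualify.
#'
#' @param normalized Gene x sample expression.
#' @param module Named integer assignment.
#' @param threshold Merge threshold (default 0.95).
#' @return List with `module` (relabelled 1..k by decreasing size),
#'   `eigengenes`, and `merge_history` (data.frame of merged label pairs).
#' @export
mergeModules <- function(normalized, module, threshold = 0.95) {
  history <- data.frame(kept = integer(), absorbed = integer())
  repeat {
    labs <- sort(unique(module[module > 0]))
    if (length(labs) < 2L) break
    eg <- moduleEigengenes(normalized, module)
    r <- cor(t(eg))
    diag(r) <- -Inf
    best <- which(r == max(r), arr.ind = TRUE)[1, ]
    if (r[best[1], best[2]] < threshold) break
    a <- labs[best[1]]; b <- labs[best[2]]
    module[module == b] <- a
    history <- rbind(history, data.frame(kept = a, absorbed = b))
  }
  # relabel by decreasing size
  labs <- sort(unique(module[module > 0]))
  sizes <- vapply(labs, function(l) sum(module == l), 0L)
  ord <- labs[order(-sizes, labs)]
  newModule <- integer(length(module))
  names(newModule) <- names(module)
  for (i in seq_along(ord)) newModule[module == ord[i]] <- i
  list(module = newModule,
       eigengenes = moduleEigengenes(normalized, newModule),
       merge_history = history)
}

#' Novel-gene enrichment per module
#'
#' Two-sided Fisher's exact test on the 2x2 table (in module x novel) per
#' module, Benjamini-Hochberg corrected across modules.
#'
#' @param module Named integer assignment.
#' @param novel Named logical: gene -> novel status (every gene labelled).
#' @return data.frame with `module`, `n_genes`, `n_novel`, `odds_ratio`,
#'   `p`, `q`.
#' @export
moduleNovelEnrichment <- function(module, novel) {
  novel <- novel[names(module)]
  if (any(is.na(novel)))
    stopf("every gene must have a novel/known label")
  labs <- sort(unique(module[module > 0]))
  rows <- lapply(labs, function(l) {
    inMod <- module == l
    tab <- matrix(c(sum(inMod & novel), sum(inMod & !novel),
                    sum(!inMod & novel), sum(!inMod & !novel)), 2)
    ft <- fisher.test(tab)
    data.frame(module = l, n_genes = sum(inMod),
               n_novel = sum(inMod & novel),
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out
}

#' Promoter window of a gene's major isoform
#'
#' The major isoform is the gene's isoform with the highest mean TPM across
#' all samples (ties: longest, then lexicographic id); the window spans
#' `upstream` bp upstream to `downstream` bp downstream of its TSS in
#' transcript orientation, clamped to the contig bounds.
#'
#' @param gene Gene id.
#' @param ts A [TranscriptSet-class].
#' @param tpm Isoform x sample TPM matrix (may omit the gene's isoforms, in
#'   which case the longest isoform is used with a warning).
#' @param upstream,downstream Window extents (defaults 3000 and 500).
#' @param contig_length Optional contig length for right clamping.
#' @return A `GRanges` of length 1.
#' @export
promoterWindow <- function(gene, ts, tpm = NULL, upstream = 3000L,
                           downstream = 500L, contig_length = NULL) {
  td <- txData(ts)
  idx <- which(as.character(td$gene_id) == gene)
  if (length(idx) == 0L) stopf("gene %s has no isoforms", gene)
  ids <- txIds(ts)[idx]
  lens <- splicedLength(ts)[ids]
  major <- NULL
  if (!is.null(tpm) && any(ids %in% rownames(tpm))) {
    mu <- rowMeans(tpm[intersect(ids, rownames(tpm)), , drop = FALSE])
    best <- max(mu)
    cand <- names(mu)[mu == best]
    if (length(cand) > 1L) {
      cand <- cand[lens[cand] == max(lens[cand])]
      cand <- sort(cand)
    }
    major <- cand[1]
  } else {
    warnf("gene %s absent from TPM; falling back to longest isoform", gene)
    cand <- ids[lens == max(lens)]
    major <- sort(cand)[1]
  }
  e <- txExons(ts)[[major]]
  strand <- as.character(BiocGenerics::strand(e))[1]
  contig <- as.character(GenomicRanges::seqnames(e))[1]
  if (strand == "+") {
    tss <- BiocGenerics::start(e)[1]
    s <- max(1L, tss - upstream); en <- tss + downstream - 1L
  } else {
    tss <- BiocGenerics::end(e)[length(e)]
    s <- tss - downstream + 1L; en <- tss + upstream
  }
  if (!is.null(contig_length)) en <- min(en, contig_length)
  s <- max(1L, s)
  GenomicRanges::GRanges(contig, IRanges::IRanges(s, en), strand = strand,
                         major_isoform = major)
}

# All permutations of 1..n (n <= 9), one per row.
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    if (pos < n)
      block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                     sub[, pos:(n - 1L), drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# Spearman rho with mid-ranks, and its p-value: exact enumeration over all
# rank permutations when n <= exact_max, else the t approximation.
spearmanTest <- function(x, y, exact_max = 9L) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rx, ry)
  if (n <= exact_max) {
    perms <- allPermutations(n)
    rhos <- apply(perms, 1, function(pp) cor(rx, ry[pp]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Spearman correlations with BH adjustment
#'
#' Spearman rho on pairwise-complete observations for each requested
#' (x row, y row) pair; p-values by exact enumeration over rank
#' permutations when n <= 9, else the t approximation; BH adjustment over
#' all tested pairs. Pairs with fewer than 3 complete observations are
#' untestable (NA).
#'
#' @param x_matrix,y_matrix Feature x sample matrices sharing columns.
#' @param pairs data.frame with columns `x` and `y` (row names into the
#'   matrices).
#' @return data.frame `x`, `y`, `rho`, `n`, `p`, `q`.
#' @export
spearmanBH <- function(x_matrix, y_matrix, pairs) {
  common <- intersect(colnames(x_matrix), colnames(y_matrix))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    xs <- x_matrix[pairs$x[i], common]
    ys <- y_matrix[pairs$y[i], common]
    st <- spearmanTest(xs, ys)
    data.frame(x = pairs$x[i], y = pairs$y[i], rho = st$rho, n = st$n,
               p = st$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bhAdjust(out$p)
  out
}

#' Correlation-filtered TF-target network
#'
#' Keeps a (TF, gene) edge iff the pair is in the bound set (promoter
#' footprinting evidence), the absolute Spearman correlation between the
#' TF's activity and the gene's normalized expression is at least
#' `min_abs_rho`, and the BH-adjusted p-value is below `max_q`.
#'
#' @param bound_pairs data.frame with columns `tf`, `gene`.
#' @param tf_activity TF x sample activity matrix.
#' @param gene_expression Gene x sample normalized expression.
#' @param min_abs_rho Correlation threshold (default 0.3, inclusive).
#' @param max_q Adjusted-p threshold (default 0.05, strict <).
#' @return Edge data.frame `tf`, `gene`, `rho`, `p`, `q`, `kept`.
#' @export
tfTargetNetwork <- function(bound_pairs, tf_activity, gene_expression,
                            min_abs_rho = 0.3, max_q = 0.05) {
  known <- bound_pairs$tf %in% rownames(tf_activity) &
    bound_pairs$gene %in% rownames(gene_expression)
  if (any(!known))
    warnf("dropping %d bound pair(s) with missing TF activity or expression",
          sum(!known))
  bp <- bound_pairs[known, , drop = FALSE]
  if (nrow(bp) == 0L)
    return(data.frame(tf = character(), gene = character(), rho = numeric(),
                      p = numeric(), q = numeric(), kept = logical()))
  res <- spearmanBH(tf_activity, gene_expression,
                    data.frame(x = bp$tf, y = bp$gene))
  data.frame(tf = res$x, gene = res$y, rho = res$rho, p = res$p, q = res$q,
             kept = !is.na(res$rho) & abs(res$rho) >= min_abs_rho &
               !is.na(res$q) & res$q < max_q)
}

#' Correlation- and binding-filtered SF-isoform network
#'
#' Keeps an (SF, isoform) edge iff the absolute Spearman correlation
#' between SF expression and isoform inclusion is strictly greater than
#' `min_abs_rho` and at least one binding peak of that SF overlaps the
#' isoform's genomic span on the same strand.
#'
#' @param sf_expression SF x sample expression matrix.
#' @param inclusion Isoform x sample PSI matrix.
#' @param peaks `GRanges` with a `factor_id` column (eCLIP-style peaks).
#' @param ts The isoform [TranscriptSet-class].
#' @param pairs Optional data.frame `sf`, `isoform`; defaults to all
#'   combinations.
#' @param min_abs_rho Correlation threshold (default 0.75, strict >).
#' @return Edge data.frame `sf`, `isoform`, `rho`, `p`, `q`, `has_peak`,
#'   `kept`.
#' @export
sfIsoformNetwork <- function(sf_expression, inclusion, peaks, ts,
                             pairs = NULL, min_abs_rho = 0.75) {
  if (is.null(pairs))
    pairs <- expand.grid(sf = rownames(sf_expression),
                         isoform = rownames(inclusion),
                         stringsAsFactors = FALSE)
  noPeak <- setdiff(unique(pairs$sf), unique(peaks$factor_id))
  if (length(noPeak))
    warnf("SF(s) without peaks: %s (their edges are dropped)",
          paste(noPeak, collapse = ","))
  res <- spearmanBH(sf_expression, inclusion,
                    data.frame(x = pairs$sf, y = pairs$isoform))
  spans <- txSpans(ts)
  hasPeak <- vapply(seq_len(nrow(res)), function(i) {
    iso <- res$y[i]
    if (!iso %in% names(spans)) return(FALSE)
    pk <- peaks[peaks$factor_id == res$x[i]]
    length(GenomicRanges::findOverlaps(spans[iso], pk,
                                       ignore.strand = FALSE)) > 0L
  }, NA)
  data.frame(sf = res$x, isoform = res$y, rho = res$rho, p = res$p,
             q = res$q, has_peak = hasPeak,
             kept = !is.na(res$rho) & abs(res$rho) > min_abs_rho & hasPeak)
}
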