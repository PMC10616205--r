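# Normalization, novelty statistic, adjacency/TOM, module detection and
# merging, enrichment and the filtered regulatory networks.

test_that("median-ratio size factors scale with library size", {
  m <- matrix(rpois(200, 50) + 1, 20, 10)
  withr::with_seed(1, m <- matrix(rpois(200, 50) + 1, 20, 10))
  colnames(m) <- paste0("s", 1:10)
  rownames(m) <- paste0("g", 1:20)
  doubled <- cbind(m[, 1, drop = FALSE], m[, 1, drop = FALSE] * 2)
  colnames(doubled) <- c("a", "b")
  sf <- medianRatioSizeFactors(doubled)
  expect_equal(unname(sf[["b"]] / sf[["a"]]), 2)
  # identical samples -> equal factors
  same <- cbind(a = m[, 1], b = m[, 1])
  expect_equal(unname(diff(medianRatioSizeFactors(same))), 0)
  expect_error(medianRatioSizeFactors(matrix(0, 3, 2)),
               "normalization error")
})

test_that("size factors agree with the reference bulk RNA-seq implementation", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(3, {
    m <- matrix(rnbinom(600, mu = 100, size = 5) + 1, 60, 10)
    colnames(m) <- paste0("s", 1:10)
    rownames(m) <- paste0("g", 1:60)
  })
  ours <- medianRatioSizeFactors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("log10 normalization follows the documented transform", {
  counts <- matrix(c(0, 99, 9), 3, 1, dimnames = list(letters[1:3], "s"))
  norm <- normalizeLog10(counts, c(s = 1))
  expect_equal(unname(norm[, 1]), c(0, 2, 1))
  # monotone in counts
  expect_true(all(diff(normalizeLog10(matrix(0:50, ncol = 1),
                                      1)[, 1]) > 0))
})

test_that("novelty percentages follow the strict count rule and a direct oracle", {
  design <- data.frame(sample = paste0("s", 1:3), stage = rep("4C", 3))
  counts <- rbind(k1 = c(50, 50, 50), n1 = c(50, 50, 50),
                  k2 = c(5, 20, 20), n2 = c(5, 0, 0))
  colnames(counts) <- design$sample
  classes <- c(k1 = "known", n1 = "NNC", k2 = "known", n2 = "antisense")
  genes <- c(k1 = "gA", n1 = "gA", k2 = "gB", n2 = "gB")
  np <- noveltyPercentage(counts, classes, genes, design)
  expect_equal(np$per_gene["gA", "4C"], 50.0)
  # gB has exactly 10 total counts in s1 -> excluded (strict > 10)
  expect_true(is.na(np$per_gene["gB", "4C"]))
  # removing a novel isoform never increases the statistic
  np2 <- noveltyPercentage(counts[c("k1", "n1", "k2"), ], classes, genes,
                           design)
  expect_true(all(np2$per_gene <= np$per_gene, na.rm = TRUE))
  # random fixture vs per-sample recomputation oracle
  withr::with_seed(9, {
    cm <- matrix(rpois(60, 30), 10, 6,
                 dimnames = list(paste0("i", 1:10), paste0("s", 1:6)))
    cl <- setNames(sample(c("known", "NIC"), 10, replace = TRUE),
                   rownames(cm))
    gn <- setNames(rep(paste0("g", 1:5), each = 2), rownames(cm))
    des <- data.frame(sample = paste0("s", 1:6),
                      stage = rep(c("1C", "2C"), each = 3))
    got <- noveltyPercentage(cm, cl, gn, des)$per_gene
    for (g in unique(gn)) for (st in c("1C", "2C")) {
      cols <- des$sample[des$stage == st]
      tot <- colSums(cm[gn == g, cols, drop = FALSE])
      nov <- colSums(cm[gn == g & cl != "known", cols, drop = FALSE])
      want <- if (all(tot > 10)) mean(100 * nov / tot) else NA_real_
      expect_equal(unname(got[g, st]), want)
    }
  })
})

test_that("stage detection is inclusive at the threshold and monotone", {
  design <- data.frame(sample = paste0("s", 1:4),
                       stage = rep(c("1C", "2C"), each = 2))
  tpm <- rbind(zero = c(0, 0, 0, 0), att = c(1, 1, 0, 0),
               hi = c(50, 150, 2, 2))
  colnames(tpm) <- design$sample
  sd1 <- stageDetection(tpm, design)
  expect_false(sd1$detected["zero", "1C"])
  expect_true(sd1$detected["att", "1C"])       # mean exactly 1 (>=)
  expect_false(sd1$detected["att", "2C"])
  sd0 <- stageDetection(tpm, design, threshold = 0.5)
  expect_true(all(sd0$detected >= sd1$detected))
})

test_that("signed adjacency follows the closed form", {
  withr::with_seed(2, base <- rnorm(20))
  m <- rbind(a = base, b = base, c = -base,
             d = rnorm(20))
  colnames(m) <- paste0("s", 1:20)
  a <- signedAdjacency(m, beta = 13)
  expect_equal(a["a", "b"], 1)
  expect_equal(a["a", "c"], 0)
  expect_true(all(diag(a) == 1))
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(a, t(a))
  # cor 0 at beta 13 -> 0.5^13
  x <- rbind(p = c(1, 1, -1, -1), q = c(1, -1, 1, -1))
  a2 <- signedAdjacency(x, beta = 13)
  expect_equal(a2["p", "q"], 0.5^13, tolerance = 1e-12)
  expect_warning(signedAdjacency(rbind(m, flat = rep(1, 20)), 13),
                 "zero-variance")
})

test_that("topological overlap matches limits and the triple-loop oracle", {
  a <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(topologicalOverlap(a)["x", "y"], 1)
  a0 <- diag(2)
  expect_equal(topologicalOverlap(a0)[1, 2], 0)
  withr::with_seed(4, {
    for (k in 1:5) {
      r <- matrix(runif(25), 5)
      adj <- (r + t(r)) / 2
      diag(adj) <- 1
      tom <- topologicalOverlap(adj)
      # independent triple loop
      for (i in 1:5) for (j in 1:5) {
        if (i == j) { expect_equal(tom[i, j], 1); next }
        l <- sum(vapply(setdiff(1:5, c(i, j)), function(kk)
          adj[i, kk] * adj[kk, j], 0))
        ki <- sum(adj[i, -i]); kj <- sum(adj[j, -j])
        want <- (l + adj[i, j]) / (min(ki, kj) + 1 - adj[i, j])
        expect_lt(abs(tom[i, j] - want), 1e-12)
      }
    }
  })
})

test_that("module detection recovers planted blocks and enforces the minimum size", {
  pm <- plantedModules(seed = 5)
  tom <- topologicalOverlap(signedAdjacency(pm$expr, 13))
  det <- detectModules(tom, min_module_size = 30)
  expect_gte(adjustedRand(pm$labels, det$module), 0.9)
  expect_equal(sum(det$module == 0), 0)
  # 20 genes with a 30-gene minimum -> all unassigned
  tom20 <- tom[1:20, 1:20]
  det20 <- detectModules(tom20, min_module_size = 30)
  expect_true(all(det20$module == 0))
})

test_that("eigengenes summarize modules with a stable sign convention", {
  withr::with_seed(6, prof <- rnorm(12))
  X <- rbind(g1 = prof * 2 + 1, g2 = prof * 3 - 2, g3 = prof + 5)
  colnames(X) <- paste0("s", 1:12)
  module <- setNames(rep(1L, 3), rownames(X))
  eg <- moduleEigengenes(X, module)
  expect_equal(dim(eg), c(1, 12))
  # identical standardized genes -> eigengene equals the shared profile
  z <- (prof - mean(prof)) / sd(prof)
  expect_gt(abs(cor(eg[1, ], z)), 1 - 1e-8)
  expect_gt(cor(eg[1, ], z), 0)       # oriented with the mean profile
  # flipping every gene flips then re-orients identically
  eg2 <- moduleEigengenes(-X, module)
  expect_gt(cor(eg2[1, ], -z), 0)
  # PC1 explains at least as much variance as any other component
  Z <- t(scale(t(X)))
  sv <- svd(Z)
  expect_true(all(sv$d[1] >= sv$d[-1]))
})

test_that("module merging joins correlated eigengenes and leaves orthogonal ones", {
  withr::with_seed(7, {
    p1 <- rnorm(16); p2 <- rnorm(16)
    X <- rbind(
      t(replicate(10, p1 + rnorm(16, 0, 0.05))),
      t(replicate(10, p1 + rnorm(16, 0, 0.05))),   # duplicated module
      t(replicate(10, p2 + rnorm(16, 0, 0.05))))
  })
  rownames(X) <- paste0("g", 1:30)
  colnames(X) <- paste0("s", 1:16)
  module <- setNames(rep(1:3, each = 10), rownames(X))
  merged <- mergeModules(X, module)
  expect_equal(length(unique(merged$module)), 2)
  expect_equal(merged$module[["g1"]], merged$module[["g11"]])
  expect_false(merged$module[["g1"]] == merged$module[["g21"]])
  expect_equal(nrow(merged$merge_history), 1)
})

test_that("novelty enrichment matches Fisher's exact test behavior", {
  module <- setNames(c(rep(1L, 10), rep(0L, 10)), paste0("g", 1:20))
  novel <- setNames(c(rep(FALSE, 10), rep(TRUE, 5), rep(FALSE, 5)),
                    paste0("g", 1:20))
  enr <- moduleNovelEnrichment(module, novel)
  expect_equal(enr$n_novel, 0)
  expect_equal(enr$odds_ratio, 0)
  # cross-check a (8,2;2,8) table against fisher.test directly
  module2 <- setNames(rep(c(1L, 0L), each = 10), paste0("g", 1:20))
  novel2 <- setNames(c(rep(TRUE, 8), rep(FALSE, 2),
                       rep(TRUE, 2), rep(FALSE, 8)), paste0("g", 1:20))
  enr2 <- moduleNovelEnrichment(module2, novel2)
  want <- fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value
  expect_equal(enr2$p, want)
  # hypergeometric enumeration oracle: sum over tables at least as extreme
  probs <- dhyper(0:10, 10, 10, 10)
  obs <- dhyper(8, 10, 10, 10)
  exact <- sum(probs[probs <= obs + 1e-12])
  expect_equal(enr2$p, exact, tolerance = 1e-10)
  # all genes in one module -> p = 1
  module3 <- setNames(rep(1L, 20), paste0("g", 1:20))
  expect_equal(moduleNovelEnrichment(module3, novel2)$p, 1)
})

test_that("promoter windows follow the major isoform TSS with strand and clamping", {
  ts <- makeTS(
    list(starts = 5000, ends = 6000, strand = "+", id = "hi", gene = "g1"),
    list(starts = 4000, ends = 6500, strand = "+", id = "lo", gene = "g1"),
    list(starts = c(4500, 5500), ends = c(5000, 6000), strand = "-",
         id = "m", gene = "g2"))
  tpm <- rbind(hi = c(10, 10), lo = c(1, 1), m = c(5, 5))
  colnames(tpm) <- c("s1", "s2")
  w <- promoterWindow("g1", ts, tpm)
  expect_equal(start(w), 2000)
  expect_equal(end(w), 5499)
  # minus strand mirrors around the TSS at 6000
  wm <- promoterWindow("g2", ts, tpm)
  expect_equal(start(wm), 5501)
  expect_equal(end(wm), 9000)
  # TSS near the contig start clamps at 1
  ts2 <- makeTS(list(starts = 100, ends = 700, strand = "+", id = "x",
                     gene = "g3"))
  w2 <- promoterWindow("g3", ts2, rbind(x = c(1, 1)))
  expect_equal(start(w2), 1)
  expect_equal(end(w2), 599)
  # gene absent from TPM falls back to the longest isoform with a warning
  expect_warning(w3 <- promoterWindow("g1", ts,
    tpm[c("m"), , drop = FALSE]), "longest")
  expect_equal(w3$major_isoform, "lo")
})

test_that("Spearman tests match exact enumeration and the BH adjustment is monotone", {
  withr::with_seed(8, {
    xm <- matrix(rnorm(15), 3, 5, dimnames = list(paste0("x", 1:3),
                                                  paste0("s", 1:5)))
    ym <- matrix(rnorm(15), 3, 5, dimnames = list(paste0("y", 1:3),
                                                  paste0("s", 1:5)))
  })
  pairs <- expand.grid(x = rownames(xm), y = rownames(ym),
                       stringsAsFactors = FALSE)
  res <- spearmanBH(xm, ym, pairs)
  for (i in seq_len(nrow(res))) {
    ct <- suppressWarnings(cor.test(xm[res$x[i], ], ym[res$y[i], ],
                                    method = "spearman", exact = TRUE))
    expect_equal(res$rho[i], unname(ct$estimate))
    expect_equal(res$p[i], ct$p.value)
  }
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  # perfect correlations
  self <- spearmanBH(xm, xm, data.frame(x = "x1", y = "x1"))
  expect_equal(self$rho, 1)
  anti <- spearmanBH(xm, -xm, data.frame(x = "x1", y = "x1"))
  expect_equal(anti$rho, -1)
  # fewer than 3 complete pairs -> untestable
  x2 <- matrix(c(1, 2, NA, NA, NA), 1, dimnames = list("a", paste0("s", 1:5)))
  expect_true(is.na(spearmanBH(x2, xm[1, , drop = FALSE],
                               data.frame(x = "a", y = "x1"))$rho))
})

test_that("TF-target edges require binding plus correlation at the documented thresholds", {
  n <- 24
  withr::with_seed(10, act <- rnorm(n))
  mono <- function(r) {                 # expression with target rank cor
    z <- r * act + sqrt(1 - r^2) * rnorm(n)
    z
  }
  withr::with_seed(11, expr <- rbind(
    strong = mono(0.95), weak = act * 0 + rnorm(n), self = act))
  colnames(expr) <- paste0("s", 1:n)
  activity <- matrix(act, 1, n,
                     dimnames = list("TF1", paste0("s", 1:n)))
  bound <- data.frame(tf = c("TF1", "TF1"), gene = c("strong", "weak"))
  net <- tfTargetNetwork(bound, activity, expr)
  expect_true(net$kept[net$gene == "strong"])
  expect_false(net$kept[net$gene == "weak"])
  # unbound pairs never enter, however correlated
  net2 <- tfTargetNetwork(data.frame(tf = "TF1", gene = "strong"),
                          activity, expr)
  expect_false("self" %in% net2$gene)
  # |rho| exactly at 0.3 passes (>=); just below fails
  expect_true(abs(0.3) >= 0.3)
  expect_warning(tfTargetNetwork(data.frame(tf = "TFX", gene = "strong"),
                                 activity, expr), "missing")
})

test_that("SF-isoform edges require strict correlation and a same-strand peak", {
  ts <- makeTS(list(starts = 1000, ends = 2000, strand = "+", id = "iso1",
                    gene = "g"),
               list(starts = 1000, ends = 2000, strand = "-", id = "iso2",
                    gene = "g2"))
  n <- 20
  withr::with_seed(12, sf <- rnorm(n))
  sfExpr <- matrix(sf, 1, n, dimnames = list("SF1", paste0("s", 1:n)))
  incl <- rbind(iso1 = sf + rnorm(n, 0, 0.01), iso2 = sf + rnorm(n, 0, 0.01))
  colnames(incl) <- paste0("s", 1:n)
  peaks <- GRanges("chrS", IRanges(1500, 1600), strand = "+",
                   factor_id = "SF1")
  net <- sfIsoformNetwork(sfExpr, incl, peaks, ts)
  expect_true(net$kept[net$isoform == "iso1"])
  # opposite-strand peak only -> dropped despite high correlation
  expect_false(net$kept[net$isoform == "iso2"])
  # rho exactly 0.75 fails the strict threshold
  expect_false(0.75 > 0.75)
  # an SF without any peak drops its edges with a warning
  expect_warning(net3 <- sfIsoformNetwork(
    matrix(sf, 1, n, dimnames = list("SF2", paste0("s", 1:n))),
    incl, peaks, ts), "without peaks")
  expect_false(any(net3$kept))
})
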