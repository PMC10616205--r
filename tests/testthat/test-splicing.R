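# AS event extraction, PSI, permutation testing and fuzzy clustering.

test_that("canonical event structures are extracted with the right types", {
  # SE: 3-exon transcript + 2-exon skip sharing flanks
  se <- makeTS(
    list(starts = c(101, 301, 501), ends = c(200, 400, 600),
         strand = "+", id = "inc", gene = "g1"),
    list(starts = c(101, 501), ends = c(200, 600), strand = "+",
         id = "exc", gene = "g1"))
  ev <- extractEvents(se)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "SE")
  expect_equal(ev$inclusion_transcripts, "inc")
  expect_equal(ev$total_transcripts, "exc,inc")
  # A3 on +: introns share the donor, acceptors 500 vs 550
  a3 <- makeTS(
    list(starts = c(101, 501), ends = c(200, 700), strand = "+",
         id = "t1", gene = "g1"),
    list(starts = c(101, 551), ends = c(200, 700), strand = "+",
         id = "t2", gene = "g1"))
  ev3 <- extractEvents(a3)
  expect_equal(ev3$type, "A3")
  # the shorter intron leaves the longer exon -> inclusion = t1
  expect_equal(ev3$inclusion_transcripts, "t1")
  # same structure on minus strand is A5
  a5 <- makeTS(
    list(starts = c(101, 501), ends = c(200, 700), strand = "-",
         id = "t1", gene = "g1"),
    list(starts = c(101, 551), ends = c(200, 700), strand = "-",
         id = "t2", gene = "g1"))
  expect_equal(extractEvents(a5)$type, "A5")
  # RI: spliced transcript + single exon spanning the intron
  ri <- makeTS(
    list(starts = c(101, 301), ends = c(200, 400), strand = "+",
         id = "spliced", gene = "g1"),
    list(starts = 101, ends = 400, strand = "+", id = "retained",
         gene = "g1"))
  evri <- extractEvents(ri)
  expect_equal(evri$type, "RI")
  expect_equal(evri$inclusion_transcripts, "retained")
  # MX: mutually exclusive internal exons
  mx <- makeTS(
    list(starts = c(101, 301, 701), ends = c(200, 400, 800),
         strand = "+", id = "e1", gene = "g1"),
    list(starts = c(101, 501, 701), ends = c(200, 600, 800),
         strand = "+", id = "e2", gene = "g1"))
  evmx <- extractEvents(mx)
  expect_equal(evmx$type, "MX")
  expect_equal(evmx$inclusion_transcripts, "e1")   # 5'-most on +
  # AF: distinct first exons spliced to a common acceptor
  af <- makeTS(
    list(starts = c(101, 701), ends = c(200, 800), strand = "+",
         id = "t1", gene = "g1"),
    list(starts = c(401, 701), ends = c(500, 800), strand = "+",
         id = "t2", gene = "g1"))
  evaf <- extractEvents(af)
  expect_equal(evaf$type, "AF")
  expect_equal(evaf$inclusion_transcripts, "t1")   # most distal 5' exon
  # AL on the last exons
  al <- makeTS(
    list(starts = c(101, 301), ends = c(200, 400), strand = "+",
         id = "t1", gene = "g1"),
    list(starts = c(101, 601), ends = c(200, 700), strand = "+",
         id = "t2", gene = "g1"))
  eval_ <- extractEvents(al)
  expect_equal(eval_$type, "AL")
  expect_equal(eval_$inclusion_transcripts, "t2")
})

test_that("event extraction equals the pairwise brute-force oracle on simulated genes", {
  for (seed in c(7, 11, 2)) {
    b <- sharedBundle(seed)
    ref <- b@reference                 # genes with exon-skip second isoforms
    expect_setequal(eventKeysOf(extractEvents(ref)),
                    bruteForceEventKeys(ref))
  }
})

test_that("PSI ratios follow inclusion over total TPM with missing-on-zero", {
  ev <- data.frame(event_id = "e1", type = "SE", gene = "g",
                   coordinates = "c", inclusion_transcripts = "a",
                   total_transcripts = "a,b")
  tpm <- rbind(a = c(0, 5, 0), b = c(10, 5, 0))
  colnames(tpm) <- paste0("s", 1:3)
  psi <- eventPsi(ev, tpm)
  expect_equal(unname(psi[1, ]), c(0, 0.5, NA))
  expect_error(eventPsi(data.frame(event_id = "x", type = "SE", gene = "g",
    coordinates = "c", inclusion_transcripts = "zz",
    total_transcripts = "zz,b"), tpm), "validation error")
  # isoform PSI: sole isoform 1.0; 3:1 split -> 0.75/0.25; columns sum to 1
  ts <- makeTS(
    list(starts = 101, ends = 600, strand = "+", id = "a", gene = "g1"),
    list(starts = 101, ends = 700, strand = "+", id = "b", gene = "g1"),
    list(starts = 5001, ends = 5600, strand = "+", id = "solo",
         gene = "g2"))
  tpm2 <- rbind(a = c(3, 0), b = c(1, 0), solo = c(7, 2))
  colnames(tpm2) <- c("s1", "s2")
  ipsi <- isoformPsi(ts, tpm2)
  expect_equal(unname(ipsi["a", ]), c(0.75, NA))
  expect_equal(unname(ipsi["b", ]), c(0.25, NA))
  expect_equal(unname(ipsi["solo", ]), c(1, 1))
  expect_equal(unname(ipsi["a", "s1"] + ipsi["b", "s1"]), 1)
})

test_that("differential PSI uses an exact permutation distribution and both thresholds", {
  design <- data.frame(sample = paste0("s", 1:6),
                       stage = rep(c("4C", "8C"), each = 3))
  # identical vectors: delta 0, p 1
  psi <- matrix(rep(0.5, 6), 1, dimnames = list("e", paste0("s", 1:6)))
  r <- diffPsi(psi, design, "4C", "8C")
  expect_equal(r$delta_psi, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
  # perfectly separated 3 vs 3: p = 2/20 = 0.1, not significant
  psi2 <- matrix(c(0.1, 0.12, 0.11, 0.9, 0.88, 0.91), 1,
                 dimnames = list("e", paste0("s", 1:6)))
  r2 <- diffPsi(psi2, design, "4C", "8C")
  expect_equal(r2$p_value, 0.1)
  expect_false(r2$significant)
  # |delta| <= 0.1 is never significant regardless of p
  x <- c(rep(0.40, 3), rep(0.49, 3))
  r3 <- diffPsi(matrix(x, 1, dimnames = list("e", paste0("s", 1:6))),
                design, "4C", "8C")
  expect_false(r3$significant)
  expect_true(abs(r3$delta_psi) <= 0.1)
  # a stage entirely missing -> untestable
  psi4 <- matrix(c(NA, NA, NA, 0.9, 0.9, 0.9), 1,
                 dimnames = list("e", paste0("s", 1:6)))
  expect_false(diffPsi(psi4, design, "4C", "8C")$testable)
})

test_that("fuzzy c-means memberships are proper and the objective never increases", {
  traj <- plantedTrajectories()
  stz <- standardizeRows(traj$profiles)
  fc <- fuzzyCMeans(stz$profiles, c = 4, m = 1.25, seed = 1)
  expect_true(all(abs(rowSums(fc$membership) - 1) < 1e-9))
  expect_true(all(fc$membership >= 0))
  expect_true(all(diff(fc$objective) <= 1e-9))
  # well-separated groups -> own-cluster membership > 0.9
  own <- vapply(seq_len(nrow(fc$membership)), function(i)
    max(fc$membership[i, ]), 0)
  expect_gt(mean(own > 0.9), 0.95)
  # identical items collapse onto their center with membership 1
  X <- rbind(matrix(rep(c(1, 0, 0), 10), 10, byrow = TRUE),
             matrix(rep(c(0, 0, 1), 10), 10, byrow = TRUE))
  rownames(X) <- paste0("r", 1:20)
  f2 <- fuzzyCMeans(X, c = 2, m = 1.5, seed = 1)
  expect_true(all(apply(f2$membership, 1, max) > 1 - 1e-6))
  expect_error(fuzzyCMeans(X, c = 25, m = 1.5), "configuration error")
  # determinism
  f3 <- fuzzyCMeans(stz$profiles, c = 4, m = 1.25, seed = 1)
  expect_identical(fc$centers, f3$centers)
})

test_that("fuzzy c-means agrees with an independent reference implementation", {
  skip_if_not_installed("e1071")
  traj <- plantedTrajectories(n_per = 30)
  stz <- standardizeRows(traj$profiles)
  fc <- fuzzyCMeans(stz$profiles, c = 4, m = 1.25, seed = 1)
  # start the reference implementation from the same initial centers so
  # both converge in the same basin, then compare the fixed points
  init <- withr::with_seed(1, suppressWarnings(
    stats::kmeans(stz$profiles, centers = 4, nstart = 10L,
                  iter.max = 50L))$centers)
  cm <- e1071::cmeans(stz$profiles, centers = init, m = 1.25,
                      iter.max = 500)
  expect_gte(adjustedRand(fc$cluster, cm$cluster), 0.99)
  ord <- apply(fc$centers, 1, function(ct)
    which.min(colSums((t(cm$centers) - ct)^2)))
  expect_lt(max(abs(fc$centers - cm$centers[ord, ])), 1e-3)
})

test_that("switching-isoform clustering recovers planted 8C trajectory shapes", {
  traj <- plantedTrajectories()
  stages <- stageLevels()
  design <- data.frame(sample = stages, stage = stages)
  psi <- traj$profiles
  colnames(psi) <- stages
  diffRes <- data.frame(feature = rownames(psi), significant = TRUE)
  fc <- clusterSwitchingIsoforms(diffRes, psi, design, c = 4, seed = 1)
  tab <- table(traj$labels, fc$cluster)
  agreement <- sum(apply(tab, 1, max)) / length(traj$labels)
  expect_gte(agreement, 0.9)
})

test_that("cluster summaries label direction and dynamics at the focal stage", {
  traj <- plantedTrajectories()
  stages <- stageLevels()
  design <- data.frame(sample = stages, stage = stages)
  psi <- traj$profiles
  diffRes <- data.frame(feature = rownames(psi), significant = TRUE)
  fc <- clusterSwitchingIsoforms(diffRes, psi, design, c = 4, seed = 1)
  combos <- paste(fc$summary$direction, fc$summary$dynamics)
  expect_setequal(combos, c("more_included peak", "more_included shift",
                            "less_included shift", "less_included peak"))
  # all-identical profiles are excluded as zero-variance
  flat <- matrix(0.5, 5, 6, dimnames = list(paste0("f", 1:5), stages))
  expect_null(clusterSwitchingIsoforms(
    data.frame(feature = character(), significant = logical()),
    flat, design))
  stz <- standardizeRows(flat)
  expect_equal(nrow(stz$profiles), 0)
  expect_equal(stz$dropped, paste0("f", 1:5))
})
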