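hitRow <- function(q, s, sstart, ev, bits = 100) {
  data.frame(qseqid = q, sseqid = s, pident = 98, length = 64, mismatch = 1,
             gapopen = 0, qstart = 1, qend = 64, sstart = sstart,
             send = sstart + 63, evalue = ev, bitscore = bits,
             stringsAsFactors = FALSE)
}

testArms <- data.frame(
  arm_id = c("armA", "armB", "armC"), chrom = c("chrA", "chrB", "chrC"),
  start = 1, end = 400, centromere_side = c("low", "low", "high"),
  categories = c("HRTA", "", "AHP"), stringsAsFactors = FALSE)

test_that("top-hit resolution applies the e-value tie rules", {
  hits <- rbind(
    hitRow("m1", "chrA", 10, "1.00e-30"), hitRow("m1", "chrB", 10, "1.00e-12"),
    hitRow("m2", "chrA", 20, "1.00e-25"), hitRow("m2", "chrB", 20, "1.00e-25"),
    hitRow("m3", "chrA", 30, "1.00e-25"), hitRow("m3", "chrB", 30, "1.00e-25"),
    hitRow("m3", "chrC", 30, "1.00e-25"),
    hitRow("m4", "chrX", 40, "1.00e-30"),
    # in-arm tie collapses to a single hit on that arm
    hitRow("m5", "chrA", 50, "1.00e-20", bits = 90),
    hitRow("m5", "chrA", 90, "1.00e-20", bits = 95))
  res <- resolveTopHits(hits, testArms)
  a <- res$assignments
  expect_equal(a$arm[a$marker == "m1"], "armA")        # strictly lowest e
  expect_setequal(a$arm[a$marker == "m2"], c("armA", "armB"))  # 2-arm tie kept
  expect_equal(a$n_arms[a$marker == "m2"], c(2, 2))
  expect_false("m3" %in% a$marker)                     # >= 3 arms dropped
  expect_equal(res$dropped$reason[res$dropped$marker == "m3"], "multi_arm")
  expect_equal(res$dropped$reason[res$dropped$marker == "m4"], "unplaced")
  expect_equal(sum(a$marker == "m5"), 1)               # collapsed within arm
  expect_equal(a$bp[a$marker == "m5"], 90)             # best bitscore kept

  # permutation invariance over input hit order
  set.seed(3)
  for (i in 1:5) {
    shuf <- hits[sample(nrow(hits)), ]
    res2 <- resolveTopHits(shuf, testArms)
    expect_identical(res2$assignments, a)
  }
})

test_that("quarter binning is centromere-aware with half-open bins", {
  asg <- data.frame(marker = c("x", "y", "z"), kind = "map_snp",
                    arm = c("armA", "armC", "armA"), bp = c(350, 350, 100),
                    evalue = "1e-30", n_arms = 1, stringsAsFactors = FALSE)
  q <- binQuarters(asg, testArms)
  expect_equal(q$quarter, c(4, 1, 2))
  # flipping centromere side reverses the histogram exactly
  armsFlip <- testArms
  armsFlip$centromere_side <- ifelse(testArms$centromere_side == "low",
                                     "high", "low")
  set.seed(9)
  # exact quarter boundaries are asymmetric under the half-open convention,
  # so sample off-boundary positions for the mirror check
  bpPool <- setdiff(1:400, c(seq(100, 400, 100), seq(1, 301, 100)))
  asg2 <- data.frame(marker = sprintf("r%d", 1:200), kind = "map_snp",
                     arm = "armA", bp = sample(bpPool, 200, TRUE),
                     evalue = "1e-30", n_arms = 1, stringsAsFactors = FALSE)
  h1 <- base::table(factor(binQuarters(asg2, testArms)$quarter, 1:4))
  h2 <- base::table(factor(binQuarters(asg2, armsFlip)$quarter, 1:4))
  expect_equal(as.integer(h1), rev(as.integer(h2)))
  expect_equal(sum(h1), nrow(asg2))
  expect_error(binQuarters(transform(asg, bp = 900), testArms),
               "outside its arm")
})

test_that("contingency machinery matches the stats oracle exactly", {
  set.seed(13)
  for (i in 1:200) {
    m <- matrix(sample(5:200, 4), 2)
    ours <- contingencyChisq(m)
    oracle <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(ours$chi2, unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(ours$p, oracle$p.value, tolerance = 1e-9)
    yates <- contingencyChisq(m, correct = TRUE)
    oracleY <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    expect_equal(yates$chi2, unname(oracleY$statistic), tolerance = 1e-9)
  }
})

test_that("category contingency reproduces the published family's tests", {
  counts <- topHitHrtaCounts()
  m <- as.matrix(counts[, c("hrta", "other")])
  rownames(m) <- counts$kind
  res <- contingencyChisq(m)
  expect_lt(res$p, 1e-4)
  expect_equal(round(100 * m["psv", "hrta"] / sum(m["psv", ]), 1), 40.9)
  # equal proportions: chi2 exactly 0
  expect_equal(contingencyChisq(matrix(c(10, 20, 30, 60), 2))$chi2, 0)
  # TE 2x2: p consistent with the printed 0.0009
  te <- teCategoryCounts()
  tem <- as.matrix(te[, c("no_te", "te")])
  expect_lt(contingencyChisq(tem)$p, 0.001)
  # the printed 0.0009 matches the Yates-corrected p at 4 decimals
  expect_equal(round(contingencyChisq(tem, correct = TRUE)$p, 4), 0.0009)
})

test_that("quarter distribution tests detect constructed enrichment", {
  asg <- rbind(
    data.frame(marker = sprintf("s%d", 1:80), kind = "map_snp",
               quarter = rep(1:4, 20), stringsAsFactors = FALSE),
    data.frame(marker = sprintf("p%d", 1:30), kind = "psv",
               quarter = 4, stringsAsFactors = FALSE))
  res <- quarterDistributionTest(asg)
  expect_equal(res$df, 3)
  expect_lt(res$p, 1e-6)
  expect_equal(res$counts["psv", "q4"], 30)
  expect_lt(res$gof$psv$p, 1e-6)
  # identical profiles: chi2 = 0
  same <- rbind(
    data.frame(marker = sprintf("s%d", 1:40), kind = "map_snp",
               quarter = rep(1:4, 10), stringsAsFactors = FALSE),
    data.frame(marker = sprintf("p%d", 1:40), kind = "psv",
               quarter = rep(1:4, 10), stringsAsFactors = FALSE))
  expect_equal(quarterDistributionTest(same)$chi2, 0)
})

test_that("telomere-biased PSV simulation recovers q4 enrichment", {
  hit <- vapply(1:10, function(s) {
    fam <- simFixture(seed = 400 + s, nLg = 2, markersPerLg = 8,
                      spacingCM = 5, nProgeny = 20,
                      homeologPairs = list(c("LG01", "LG02")),
                      psvFraction = 0.5)
    ht <- emitHitTables(fam$model, fam$truth, fam$cfg)
    arms <- cbind(fam$model@arms, categories = "")
    kinds <- setNames(rep("psv", length(fam$truth@psvMarkers)),
                      fam$truth@psvMarkers)
    res <- resolveTopHits(ht$hits, arms, markerKinds = kinds)
    q <- binQuarters(res$assignments, arms)
    psvQ4 <- mean(q$quarter[q$kind == "psv"] == 4)
    mapQ4 <- mean(q$quarter[q$kind == "map_snp"] == 4)
    psvQ4 > mapQ4
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("TE proportions and category tests follow the marker sets", {
  te <- data.frame(qseqid = c("a1", "a2", "b1", "zz"),
                   stringsAsFactors = FALSE)
  sets <- list(hrta = c("a1", "a2", "a3", "a4"),
               other = c("b1", "b2", "b3", "b4", "b5"))
  res <- teProportions(sets, te)
  expect_equal(unname(res$proportions), c(0.5, 0.2))
  expect_equal(res$ignored, "zz")
  empty <- teProportions(sets, te[0, , drop = FALSE])
  expect_equal(unname(empty$proportions), c(0, 0))
})

test_that("linkage-group composition calls follow block support", {
  mk <- sprintf("m%02d", 1:35)
  asg <- data.frame(marker = mk, kind = "map_snp",
                    arm = c(rep("Ssa05q", 20), rep("Ssa02p", 15)),
                    bp = 1, evalue = "1e-30", n_arms = 1,
                    stringsAsFactors = FALSE)
  res <- classifyLgComposition(mk, asg)
  expect_equal(res$class, "compound")
  expect_setequal(res$arms, c("Ssa05q", "Ssa02p"))

  one <- transform(asg, arm = "Ssa05q")
  expect_equal(classifyLgComposition(mk, one)$class, "simple")

  stray <- asg
  stray$arm <- c(rep("Ssa05q", 33), "Ssa02p", "Ssa09qa")
  expect_equal(classifyLgComposition(mk, stray)$class, "simple")

  expect_equal(classifyLgComposition(mk[1:2], asg[1:2, ])$class,
               "unclassified")
})

test_that("duplicate-tag detection applies both thresholds and classes", {
  set.seed(6)  # aperiodic tag, so shifted alignments cannot outscore
  base <- paste(sample(c("A", "C", "G", "T"), 64, TRUE), collapse = "")
  flip <- function(s, pos) {  # substitute with a guaranteed different base
    v <- strsplit(s, "")[[1]]
    v[pos] <- chartr("ACGT", "CGTA", v[pos])
    paste(v, collapse = "")
  }
  seqs <- c(t1 = base,
            t2 = flip(flip(base, 20), 40),                   # 2 mismatches
            t3 = flip(flip(flip(flip(base, 10), 25), 40), 55),
            t4 = base)                                       # exact duplicate
  dup <- findDuplicateTags(seqs)
  key <- paste(dup$marker_a, dup$marker_b)
  expect_true("t1 t2" %in% key)
  expect_false(any(grepl("t3", key)))                        # 93.75% identity
  expect_true("t1 t4" %in% key)
  d12 <- dup[dup$marker_a == "t1" & dup$marker_b == "t2", ]
  expect_gte(d12$identity, 62 / 64 - 1e-9)
  expect_gte(d12$overlap, 0.95)

  # classification by map position
  mp <- data.frame(marker = c("t1", "t2", "t4"),
                   lg = c("LG1", "LG2", "LG1"), rank = c(1, 5, 2),
                   stringsAsFactors = FALSE)
  dup2 <- findDuplicateTags(seqs[c("t1", "t2", "t4")], mapPositions = mp)
  k2 <- paste(dup2$marker_a, dup2$marker_b)
  expect_equal(dup2$class[k2 == "t1 t2"], "inter_lg")
  expect_equal(dup2$class[k2 == "t1 t4"], "tandem")

  expect_error(findDuplicateTags(c(bad = "ACGN")), "non-ACGT")
})

test_that("exact-duplicate detection equals the hashing oracle", {
  set.seed(21)
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 64, TRUE), collapse = ""),
    character(1))
  seqs[c(5, 12)] <- seqs[2]
  seqs[25] <- seqs[7]
  names(seqs) <- sprintf("t%02d", seq_along(seqs))
  dup <- findDuplicateTags(seqs, minIdentity = 1.0, minOverlap = 1.0)
  got <- sort(paste(dup$marker_a, dup$marker_b))
  # oracle: all pairs with identical strings (forward or reverse complement)
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  want <- character()
  for (i in 1:29) for (j in (i + 1):30)
    if (seqs[i] == seqs[j] || seqs[i] == rc(seqs[j]))
      want <- c(want, paste(names(seqs)[i], names(seqs)[j]))
  expect_setequal(got, sort(want))
})
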