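test_that("genome model layout follows the requested spacing", {
  m <- buildGenomeModel(nLg = 2, markersPerLg = 10, spacingCM = 5,
                        homeologPairs = list(c("LG01", "LG02")))
  expect_equal(nrow(m@markers), 20)
  expect_equal(max(m@markers$pos_cM), 45)
  expect_equal(m@homeologPairs,
               data.frame(lg_a = "LG01", lg_b = "LG02",
                          stringsAsFactors = FALSE))
  # bp monotone within each arm
  for (lg in unique(m@markers$lg))
    expect_false(is.unsorted(m@markers$bp[m@markers$lg == lg]))
  expect_error(buildGenomeModel(nLg = 0), "configuration error")
  expect_error(buildGenomeModel(spacingCM = 0), "configuration error")
})

test_that("identical configs reproduce identical families and hit tables", {
  run <- function() {
    fam <- simFixture(seed = 42, nLg = 2, homeologPairs = list(c("LG01", "LG02")),
                      psvFraction = 0.1, missingRate = 0.05, errorRate = 0.01,
                      multivalentProb = 0.3)
    ht <- emitHitTables(fam$model, fam$truth, fam$cfg)
    list(g = progenyGenotypes(fam$table), ph = fam$truth@phases,
         hits = ht$hits, te = ht$te)
  }
  a <- run(); b <- run()
  expect_identical(a, b)
})

test_that("recombination fraction matches the interval length", {
  model <- buildGenomeModel(nLg = 1, markersPerLg = 2, spacingCM = 10)
  cfg <- simConfig(interference = "haldane", seed = 5)
  set.seed(99)
  rec <- vapply(seq_len(10000), function(i) {
    ph <- simulateMeiosis(model, cfg)$phases
    ph[1] != ph[2]
  }, logical(1))
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(mean(rec) - 0.1), 3 * se)
})

test_that("a zero-cM interval is always co-inherited", {
  model <- buildGenomeModel(nLg = 1, markersPerLg = 2, spacingCM = 10)
  model@markers$pos_cM <- c(0, 0)
  cfg <- simConfig(seed = 1)
  set.seed(7)
  for (i in 1:50) {
    ph <- simulateMeiosis(model, cfg)$phases
    expect_identical(ph[[1]], ph[[2]])
  }
})

test_that("without multivalents homeolog pairs segregate independently", {
  fam <- simFixture(seed = 3, nLg = 2, markersPerLg = 6, spacingCM = 10,
                    nProgeny = 600, homeologPairs = list(c("LG01", "LG02")),
                    multivalentProb = 0)
  expect_equal(nrow(fam$truth@tetrasomyEvents), 0)
  ph <- fam$truth@phases$female
  a <- ph["LG01_M06", ]; b <- ph["LG02_M06", ]
  r <- mean(a != b)
  expect_lt(abs(r - 0.5), 4 * sqrt(0.25 / 600))
})

test_that("family output honours error, missingness and PSV construction", {
  fam <- simFixture(seed = 8, markersPerLg = 10, nProgeny = 85,
                    psvFraction = 0.2)
  # error 0 / missing 0: Mendelian consistency and fully-het PSVs
  cl <- classifyMarkers(fam$table)
  expect_equal(sum(cl$mendel_inconsistent), 0)
  psv <- fam$truth@psvMarkers
  expect_gt(length(psv), 0)
  g <- progenyGenotypes(fam$table)[psv, , drop = FALSE]
  expect_true(all(substr(g, 1, 1) != substr(g, 2, 2)))

  fam2 <- simFixture(seed = 9, markersPerLg = 30, nProgeny = 85,
                     missingRate = 0.2)
  miss <- mean(progenyGenotypes(fam2$table) == "--")
  n <- length(progenyGenotypes(fam2$table))
  expect_lt(abs(miss - 0.2), 4 * sqrt(0.2 * 0.8 / n))
})

test_that("recombination-fraction recovery holds across seeds", {
  hits <- vapply(1:20, function(s) {
    fam <- simFixture(seed = s, markersPerLg = 2, spacingCM = 10,
                      nProgeny = 85, interference = "haldane")
    ph <- fam$truth@phases$female
    r <- mean(ph[1, ] != ph[2, ])
    abs(r - 0.1) < 4 * sqrt(0.1 * 0.9 / 85)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a 3:1 distorted locus is caught by the G-test with high power", {
  model <- buildGenomeModel(nLg = 1, markersPerLg = 2, spacingCM = 10)
  flagged <- vapply(1:200, function(s) {
    cfg <- simConfig(nProgeny = 85, crossTypeProbs = c(1, 0, 0), seed = s,
                     distortionLoci = data.frame(marker = "LG01_M01",
                                                 ratio = 3))
    fam <- simulateFamily(model, cfg)
    cl <- classifyMarkers(fam$table)
    grepl("distorted", cl$flags[cl$marker == "LG01_M01"])
  }, logical(1))
  expect_gt(mean(flagged), 0.9)
})

test_that("multivalent phase coupling has the expected sign per mode", {
  phaseCounts <- function(mode) {
    fam <- simFixture(seed = 21, nLg = 2, markersPerLg = 10, spacingCM = 5,
                      nProgeny = 1500,
                      homeologPairs = list(c("LG01", "LG02")),
                      multivalentProb = 0.5, disjunctionMode = mode)
    pt <- phaseTable("LG01_M10", "LG02_M10", fam$table, "female")
    ori <- fam$truth@alleles
    o <- setNames(ori$allele0[ori$parent == "female"],
                  ori$marker[ori$parent == "female"])
    a0 <- o[["LG01_M10"]]; b0 <- o[["LG02_M10"]]
    a1 <- setdiff(pt$alleles_a, a0); b1 <- setdiff(pt$alleles_b, b0)
    par <- pt$counts[[paste(a0, b0, sep = "/")]] +
      pt$counts[[paste(a1, b1, sep = "/")]]
    c(parental = par, nonparental = pt$n_total - par,
      chi2 = chisq1111(pt)$chi2)
  }
  rnd <- phaseCounts("random")
  prf <- phaseCounts("preferential")
  expect_gt(rnd[["parental"]], rnd[["nonparental"]])
  expect_gt(prf[["nonparental"]], prf[["parental"]])
  expect_gt(rnd[["chi2"]], qchisq(0.99, 3))
  expect_gt(prf[["chi2"]], qchisq(0.99, 3))
})

test_that("hit tables encode truth: top hits, PSV double hits, TE rows", {
  fam <- simFixture(seed = 30, nLg = 2, markersPerLg = 8, spacingCM = 5,
                    nProgeny = 20, homeologPairs = list(c("LG01", "LG02")),
                    psvFraction = 0.25, pDouble = 1)
  ht <- emitHitTables(fam$model, fam$truth, fam$cfg)
  arms <- data.frame(arm_id = fam$model@arms$arm_id,
                     chrom = fam$model@arms$chrom,
                     start = fam$model@arms$start, end = fam$model@arms$end,
                     centromere_side = fam$model@arms$centromere_side,
                     categories = "", stringsAsFactors = FALSE)
  kinds <- setNames(
    ifelse(c(fam$truth@trueMap$marker, fam$truth@psvMarkers) %in%
             fam$truth@psvMarkers, "psv", "map_snp"),
    c(fam$truth@trueMap$marker, fam$truth@psvMarkers))
  res <- resolveTopHits(ht$hits, arms, markerKinds = kinds)
  asg <- res$assignments
  # noise 0: mapped markers placed at their true bp
  mapped <- asg[asg$kind == "map_snp", ]
  truth <- fam$truth@trueMap
  expect_equal(mapped$bp[match(truth$marker, mapped$marker)], truth$bp)
  # pDouble = 1: every PSV hits exactly two arms
  psvArms <- base::table(asg$marker[asg$kind == "psv"])
  expect_true(all(psvArms == 2))
  # telomeric placement: every PSV hit bins into quarter 4
  q <- binQuarters(asg, arms)
  expect_true(all(q$quarter[q$kind == "psv"] == 4))
  # TE table references known markers
  expect_true(all(ht$te$qseqid %in% names(kinds)))
})

test_that("genotype and hit tables round-trip through their TSV layouts", {
  fam <- simFixture(seed = 12, markersPerLg = 5, nProgeny = 10,
                    missingRate = 0.1)
  tf <- tempfile(fileext = ".tsv")
  writeGenotypeTable(fam$table, tf)
  back <- readGenotypeTable(tf)
  expect_identical(progenyGenotypes(back), progenyGenotypes(fam$table))
  expect_identical(parentGenotypes(back, "male"),
                   parentGenotypes(fam$table, "male"))
  ht <- emitHitTables(fam$model, fam$truth, fam$cfg)
  hf <- tempfile(fileext = ".tsv")
  writeHitTable(ht$hits, hf)
  back2 <- readHitTable(hf)
  expect_equal(back2$sstart, ht$hits$sstart)
  expect_identical(back2$evalue, ht$hits$evalue)
  td <- tempfile()
  writeTruthSet(fam$truth, td)
  expect_true(all(file.exists(file.path(td,
    c("true_map.tsv", "phases_female.tsv", "psv_markers.tsv")))))
})
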