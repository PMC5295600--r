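test_that("two-point estimates match their closed forms", {
  # identical inheritance vectors: r = 0, LOD = N log10 2
  ph <- makePhase(a = rep(0:1, 10), b = rep(0:1, 10))
  tp <- charrmap:::.twoPointFromPhases(ph["a", ], ph["b", ])
  expect_equal(tp$r_hat, 0)
  expect_equal(tp$lod, 20 * log10(2), tolerance = 1e-12)
  expect_equal(round(tp$lod, 3), 6.021)

  # N = 10, k = 8 same-phase: r = 0.2, LOD ~ 0.837
  pa <- c(rep(0L, 8), 1L, 1L)
  pb <- rep(0L, 10)
  tp <- charrmap:::.twoPointFromPhases(pa, pb)
  expect_equal(tp$r_hat, 0.2)
  expect_equal(round(tp$lod, 3), 0.837)
  expect_equal(tp$phase, "coupling")

  # independence: r near 0.5, LOD near 0
  set.seed(2)
  pa <- sample(0:1, 2000, TRUE); pb <- sample(0:1, 2000, TRUE)
  tp <- charrmap:::.twoPointFromPhases(pa, pb)
  expect_gt(tp$r_hat, 0.45)
  expect_lt(tp$lod, 1)

  # no informative progeny: undefined record
  tp <- charrmap:::.twoPointFromPhases(c(NA, NA, 0L), c(1L, 0L, NA))
  expect_equal(tp$n_informative, 0)
  expect_true(is.na(tp$lod))
})

test_that("two-point is symmetric and phase-flip invariant", {
  tab <- makeTable(list(
    a = c("AG", "AA", "AG", "AA", "AG", "AG", "AA", "AA", "AG", "AA"),
    b = c("CT", "CC", "CT", "CC", "CT", "CT", "CC", "CT", "CT", "CC")))
  ab <- twoPoint("a", "b", "female", tab)
  ba <- twoPoint("b", "a", "female", tab)
  expect_equal(ab[c("r_hat", "lod", "n_informative", "n_recombinant")],
               ba[c("r_hat", "lod", "n_informative", "n_recombinant")])
  # relabel marker b's alleles: swap C and T in progeny and parents alike
  g <- progenyGenotypes(tab)
  g["b", ] <- chartr("CT", "TC", g["b", ])
  pm <- parentGenotypes(tab, "male")
  pm[["b"]] <- chartr("CT", "TC", pm[["b"]])
  tab2 <- GenotypeTable(g, parentGenotypes(tab, "female"), pm)
  ab2 <- twoPoint("a", "b", "female", tab2)
  expect_equal(ab2$r_hat, ab$r_hat)
  expect_equal(ab2$lod, ab$lod)
  expect_false(identical(ab2$phase, ab$phase))
})

test_that("the closed-form LOD is never beaten by a likelihood scan", {
  grid <- seq(0.001, 0.5, by = 0.001)
  lodAt <- function(r, R, N) R * log10(r) + (N - R) * log10(1 - r) +
    N * log10(2)
  set.seed(11)
  for (i in 1:200) {
    N <- sample(10:85, 1)
    R <- sample(0:floor(N / 2), 1)
    closed <- if (R == 0) N * log10(2) else lodAt(R / N, R, N)
    expect_gte(closed + 1e-9, max(lodAt(grid, R, N)))
  }
})

test_that("grouping is a transitive closure with deterministic labels", {
  pairs <- data.frame(
    marker_a = c("A", "B", "A", "C", "D"),
    marker_b = c("B", "C", "C", "D", "E"),
    lod = c(12, 11, 2, 1, 0.5), stringsAsFactors = FALSE)
  g <- groupMarkers(pairs, 10, markers = c("A", "B", "C", "D", "E"))
  expect_equal(g$groups, list(A = c("A", "B", "C")))
  expect_setequal(g$unassigned, c("D", "E"))
  # all below threshold: everything unassigned
  g2 <- groupMarkers(pairs, 20, markers = c("A", "B", "C", "D", "E"))
  expect_equal(length(g2$groups), 0)
  expect_equal(length(g2$unassigned), 5)
})

test_that("raising the LOD threshold only refines the partition", {
  fam <- simFixture(seed = 5, nLg = 3, markersPerLg = 8, spacingCM = 8,
                    nProgeny = 85)
  cl <- classifyMarkers(fam$table)
  inf <- cl$marker[cl$cross_type == "maternal_informative"]
  pairs <- twoPointAll(fam$table, "female", markers = inf)
  lo <- groupMarkers(pairs, 6, markers = inf)
  hi <- groupMarkers(pairs, 12, markers = inf)
  # each high-threshold group is contained in one low-threshold group
  for (g in hi$groups) {
    container <- unique(lo$membership[g])
    expect_equal(length(container), 1)
    expect_false(any(is.na(container)))
  }
})

test_that("grouping at LOD 10 recovers the simulated partition exactly", {
  skip_if_not_installed("mclust")
  fam <- simFixture(seed = 19, nLg = 5, markersPerLg = 12, spacingCM = 2.5,
                    nProgeny = 85)
  cl <- classifyMarkers(fam$table)
  inf <- cl$marker[cl$cross_type == "maternal_informative"]
  pairs <- twoPointAll(fam$table, "female", markers = inf)
  g <- groupMarkers(pairs, 10, markers = inf)
  expect_equal(length(g$unassigned), 0)
  truthLg <- setNames(fam$truth@trueMap$lg, fam$truth@trueMap$marker)
  ari <- mclust::adjustedRandIndex(g$membership[inf], truthLg[inf])
  expect_equal(ari, 1.0)
})

test_that("descending-LOD assignment attaches singletons and gates merges", {
  pairs <- data.frame(
    marker_a = c("A", "B", "C", "X", "X", "A", "Y", "Y"),
    marker_b = c("B", "C", "D", "A", "C", "D", "B", "D"),
    lod = c(12, 12, 12, 5.2, 4.8, 11, 4.5, 4.4), stringsAsFactors = FALSE)
  base <- groupMarkers(pairs, 10, markers = c("A", "B", "C", "D", "X", "Y"))
  expect_equal(names(base$groups), "A")
  # X joins the single group at step 5; Y joins at step 4
  merged <- descendingLodMerge(base, pairs, schedule = c(6, 5, 4, 3))
  expect_equal(merged$membership[["X"]], "A")
  expect_equal(merged$membership[["Y"]], "A")
  expect_true(all(c("X", "Y") %in% merged$joinLog$a))

  # two groups linked at LOD 3.4 merge only via the whitelist
  pairs2 <- data.frame(
    marker_a = c("A", "C", "B"),
    marker_b = c("B", "D", "C"),
    lod = c(12, 12, 3.4), stringsAsFactors = FALSE)
  base2 <- groupMarkers(pairs2, 10, markers = c("A", "B", "C", "D"))
  expect_equal(length(base2$groups), 2)
  noWl <- descendingLodMerge(base2, pairs2, whitelist = NULL)
  expect_equal(length(noWl$groups), 2)
  wl <- data.frame(a = "A", b = "C", stringsAsFactors = FALSE)
  yesWl <- descendingLodMerge(base2, pairs2, whitelist = wl)
  expect_equal(length(yesWl$groups), 1)
  mlog <- yesWl$joinLog[yesWl$joinLog$type == "merge", ]
  expect_true(all(mlog$whitelist_used))

  # marker tied to two groups at one step stays unassigned, logged ambiguous
  pairs3 <- rbind(pairs2,
                  data.frame(marker_a = c("Z", "Z"), marker_b = c("A", "C"),
                             lod = c(5.5, 5.1), stringsAsFactors = FALSE))
  base3 <- groupMarkers(pairs3, 10, markers = c("A", "B", "C", "D", "Z"))
  amb <- descendingLodMerge(base3, pairs3, schedule = c(5))
  expect_true(is.na(amb$membership[["Z"]]))
  expect_true("ambiguous" %in% amb$joinLog$type)
})

test_that("DH markers are group-assigned by best LOD but never ordered", {
  pairs <- data.frame(
    marker_a = c("A", "DH1", "DH1", "DH2"),
    marker_b = c("B", "A", "B", "B"),
    lod = c(12, 11, 9, 4), stringsAsFactors = FALSE)
  g <- groupMarkers(pairs[1, ], 10, markers = c("A", "B"))
  asg <- assignDhMarkers(g, pairs, c("DH1", "DH2"), lodThreshold = 10)
  expect_equal(asg$group[asg$marker == "DH1"], "A")
  expect_true(is.na(asg$group[asg$marker == "DH2"]))
})

test_that("simulated DH markers are assigned to their true group", {
  fam <- simFixture(seed = 23, nLg = 3, markersPerLg = 12, spacingCM = 4,
                    nProgeny = 85, crossTypeProbs = c(0.7, 0, 0.3))
  cl <- classifyMarkers(fam$table)
  inf <- cl$marker[cl$cross_type == "maternal_informative"]
  dh <- cl$marker[cl$cross_type == "double_het"]
  skip_if(length(dh) == 0)
  pairsInf <- twoPointAll(fam$table, "female", markers = inf)
  g <- groupMarkers(pairsInf, 10, markers = inf)
  pairsAll <- twoPointAll(fam$table, "female", markers = sort(c(inf, dh)))
  # DH markers are phase-resolvable in only ~half the progeny, so their
  # pairwise LOD ceiling is ~(n/2) log10 2; assign at a matching threshold
  asg <- assignDhMarkers(g, pairsAll, dh, lodThreshold = 5)
  truthLg <- setNames(fam$truth@trueMap$lg, fam$truth@trueMap$marker)
  ids <- majorityGroupIds(g, truthLg)
  hit <- !is.na(asg$group)
  # every assignment lands on the true group
  expect_true(all(ids[asg$group[hit]] == truthLg[asg$marker[hit]]))
  # DH markers adjacent to a *grouped* informative marker are always assigned
  tm <- fam$truth@trueMap
  pos <- setNames(tm$pos_cM, tm$marker)
  grouped <- inf[!is.na(g$membership[inf])]
  near <- vapply(dh, function(m) {
    cand <- intersect(tm$marker[tm$lg == truthLg[[m]]], grouped)
    length(cand) > 0 && min(abs(pos[cand] - pos[[m]])) <= 4.1
  }, logical(1))
  expect_true(any(near))
  # assignment follows the single max-LOD partner, which can itself be an
  # ungrouped marker, so near-grouped DH markers are assigned in the large
  # majority of cases rather than universally
  expect_gte(mean(hit[match(dh[near], asg$marker)]), 0.8)
})
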