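# Shared fixtures built in code.

# GenotypeTable from a compact spec: list(marker = c(pf, pm, progeny...))
makeTable <- function(rows) {
  ids <- names(rows)
  pf <- vapply(rows, `[`, "", 1)
  pm <- vapply(rows, `[`, "", 2)
  g <- t(vapply(rows, function(r) r[-(1:2)], character(length(rows[[1]]) - 2)))
  rownames(g) <- ids
  GenotypeTable(g, pf, pm)
}

# phase matrix straight from 0/1/NA rows
makePhase <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- sprintf("progeny_%d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

# a small simulated all-maternal-informative family plus its truth
simFixture <- function(seed, nLg = 1, markersPerLg = 8, spacingCM = 10,
                       nProgeny = 200, homeologPairs = NULL,
                       crossTypeProbs = c(1, 0, 0), ...) {
  model <- buildGenomeModel(nLg = nLg, markersPerLg = markersPerLg,
                            spacingCM = spacingCM,
                            homeologPairs = homeologPairs)
  cfg <- simConfig(nProgeny = nProgeny, crossTypeProbs = crossTypeProbs,
                   seed = seed, ...)
  fam <- simulateFamily(model, cfg)
  fam$model <- model
  fam$cfg <- cfg
  fam
}

# minimum-COUNT over all orders of <= 8 markers, via the pairwise
# recombinant-count matrix (complete data)
exhaustiveMinCount <- function(phase) {
  D <- charrmap:::.recombCountMatrix(phase)
  n <- nrow(phase)
  perms <- charrmap:::.permutations(n)
  costs <- rowSums(matrix(D[cbind(as.vector(perms[, -n]),
                                  as.vector(perms[, -1]))], nrow(perms)))
  min(costs)
}
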