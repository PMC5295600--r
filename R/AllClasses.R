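#' @import methods
NULL

.VALID_GENO <- "^([ACGT]{2}|--)$"

#' GenotypeTable: biallelic genotypes for an outcrossed F1 family
#'
#' Holds the genotypes of two parents and N full-sib progeny at a set of
#' markers. Genotypes are unordered two-character allele strings over
#' \code{A,C,G,T} (stored with alleles sorted), with \code{"--"} for missing.
#'
#' @slot genotypes character matrix, markers x progeny; rownames are marker
#'   ids, colnames progeny ids.
#' @slot parentFemale named character vector of maternal genotypes per marker.
#' @slot parentMale named character vector of paternal genotypes per marker.
#' @export
setClass("GenotypeTable",
  representation(
    genotypes    = "matrix",
    parentFemale = "character",
    parentMale   = "character"
  )
)

setValidity("GenotypeTable", function(object) {
  g <- object@genotypes
  msgs <- character()
  if (!is.character(g)) msgs <- c(msgs, "genotypes must be a character matrix")
  if (is.null(rownames(g)) || anyDuplicated(rownames(g)))
    msgs <- c(msgs, "marker ids (rownames) must be present and unique")
  if (ncol(g) < 1L) msgs <- c(msgs, "at least one progeny required")
  if (length(object@parentFemale) != nrow(g) ||
      length(object@parentMale) != nrow(g))
    msgs <- c(msgs, "parent genotype vectors must match marker count")
  bad <- c(g, object@parentFemale, object@parentMale)
  bad <- bad[!grepl(.VALID_GENO, bad)]
  if (length(bad))
    msgs <- c(msgs, sprintf("invalid genotype string(s), e.g. '%s'", bad[[1L]]))
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeTable
#'
#' @param genotypes character matrix of progeny genotypes (markers x progeny).
#' @param parentFemale,parentMale character vectors of parental genotypes,
#'   one per marker (recycled names from \code{rownames(genotypes)}).
#' @return A \linkS4class{GenotypeTable}.
#' @export
GenotypeTable <- function(genotypes, parentFemale, parentMale) {
  genotypes[] <- vapply(genotypes, .normGeno, character(1))
  parentFemale <- vapply(parentFemale, .normGeno, character(1))
  parentMale <- vapply(parentMale, .normGeno, character(1))
  names(parentFemale) <- rownames(genotypes)
  names(parentMale) <- rownames(genotypes)
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- sprintf("progeny_%d", seq_len(ncol(genotypes)))
  new("GenotypeTable", genotypes = genotypes,
      parentFemale = parentFemale, parentMale = parentMale)
}

#' @describeIn GenotypeTable Marker identifiers.
#' @param x A GenotypeTable.
#' @export
markerIds <- function(x) rownames(x@genotypes)

#' @describeIn GenotypeTable Number of progeny.
#' @export
nProgeny <- function(x) ncol(x@genotypes)

#' @describeIn GenotypeTable Progeny genotype matrix.
#' @export
progenyGenotypes <- function(x) x@genotypes

#' @describeIn GenotypeTable Parental genotypes for one parent.
#' @param parent \code{"female"} or \code{"male"}.
#' @export
parentGenotypes <- function(x, parent = c("female", "male")) {
  parent <- match.arg(parent)
  if (parent == "female") x@parentFemale else x@parentMale
}

setMethod("show", "GenotypeTable", function(object) {
  cat(sprintf("GenotypeTable: %d markers x %d progeny (+2 parents)\n",
              nrow(object@genotypes), ncol(object@genotypes)))
  miss <- mean(object@genotypes == "--")
  cat(sprintf("  progeny missingness: %.1f%%\n", 100 * miss))
})

#' Subset a GenotypeTable by marker id
#' @param x GenotypeTable; @param i marker ids or indices; @param j,...,drop ignored.
#' @export
setMethod("[", "GenotypeTable", function(x, i, j, ..., drop = FALSE) {
  new("GenotypeTable", genotypes = x@genotypes[i, , drop = FALSE],
      parentFemale = x@parentFemale[i], parentMale = x@parentMale[i])
})

#' SimConfig: parameters of the synthetic F1-family simulator
#'
#' The defaults encode the family design the analysis assumes: an 85-progeny
#' pseudo-testcross panel, optional genotyping noise, fixed-heterozygote PSV
#' loci, and residual tetrasomy between homeologous arms with telomere-biased
#' homeologous exchange.
#'
#' @slot nProgeny number of full-sib progeny (default 85).
#' @slot missingRate,errorRate per-genotype missingness / replacement-error
#'   probabilities.
#' @slot psvFraction number of PSV loci emitted, as a fraction of the mapped
#'   marker count.
#' @slot distortionLoci data.frame (marker, ratio) of transmission-distorted
#'   loci; ratio r means allele-0 is transmitted with probability r/(1+r).
#' @slot multivalentProb probability per homeolog pair per meiosis that a
#'   multivalent forms.
#' @slot disjunctionMode \code{"preferential"} (alternate disjunction;
#'   nonparental-phase excess) or \code{"random"} (parental-phase excess).
#' @slot telomereBias distal fraction of the arm in which homeologous
#'   exchange points fall (default 0.25).
#' @slot interference \code{"dco_suppression"} (a crossover in interval i
#'   suppresses interval i+1; default) or \code{"haldane"} (no interference).
#' @slot psvPlacement \code{"telomeric"} (PSVs in the distal quarter;
#'   default) or \code{"uniform"}.
#' @slot pDouble probability a PSV hits both homeolog arms in the emitted
#'   hit table.
#' @slot teFraction fraction of markers given rows in the TE hit table.
#' @slot hitNoiseBp sd (bp) of Gaussian noise on emitted hit coordinates.
#' @slot log10EvalueMean,log10EvalueSd parameters of the simulated
#'   log10(e-value) distribution.
#' @slot crossTypeProbs length-3 numeric (female, male, dh): sampling
#'   weights of maternal-informative, paternal-informative and
#'   double-heterozygote cross types per marker.
#' @slot seed RNG seed; identical configs give identical output.
#' @export
setClass("SimConfig",
  representation(
    nProgeny = "integer", missingRate = "numeric", errorRate = "numeric",
    crossTypeProbs = "numeric",
    psvFraction = "numeric", distortionLoci = "data.frame",
    multivalentProb = "numeric", disjunctionMode = "character",
    telomereBias = "numeric", interference = "character",
    psvPlacement = "character", pDouble = "numeric", teFraction = "numeric",
    hitNoiseBp = "numeric", log10EvalueMean = "numeric",
    log10EvalueSd = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  pr <- c(missingRate = object@missingRate, errorRate = object@errorRate,
          psvFraction = object@psvFraction,
          multivalentProb = object@multivalentProb,
          telomereBias = object@telomereBias, pDouble = object@pDouble,
          teFraction = object@teFraction)
  bad <- pr < 0 | pr > 1
  if (any(bad))
    msgs <- c(msgs, sprintf("probabilities out of [0,1]: %s",
                            paste(names(pr)[bad], collapse = ", ")))
  if (object@nProgeny < 1L) msgs <- c(msgs, "nProgeny must be >= 1")
  if (length(object@crossTypeProbs) != 3L ||
      any(object@crossTypeProbs < 0) || sum(object@crossTypeProbs) <= 0)
    msgs <- c(msgs, "crossTypeProbs must be 3 non-negative weights")
  if (!object@disjunctionMode %in% c("preferential", "random"))
    msgs <- c(msgs, "disjunctionMode must be 'preferential' or 'random'")
  if (!object@interference %in% c("dco_suppression", "haldane"))
    msgs <- c(msgs, "interference must be 'dco_suppression' or 'haldane'")
  if (!object@psvPlacement %in% c("telomeric", "uniform"))
    msgs <- c(msgs, "psvPlacement must be 'telomeric' or 'uniform'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimConfig
#'
#' @param nProgeny,missingRate,errorRate,psvFraction,distortionLoci
#'   see \linkS4class{SimConfig}.
#' @param multivalentProb,disjunctionMode,telomereBias,interference
#'   residual-tetrasomy model parameters.
#' @param psvPlacement,pDouble,teFraction,hitNoiseBp,log10EvalueMean,log10EvalueSd
#'   hit-table emission parameters.
#' @param seed integer RNG seed.
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(nProgeny = 85L, missingRate = 0, errorRate = 0,
                      crossTypeProbs = c(female = 0.4, male = 0.4, dh = 0.2),
                      psvFraction = 0,
                      distortionLoci = data.frame(marker = character(),
                                                  ratio = numeric()),
                      multivalentProb = 0,
                      disjunctionMode = c("preferential", "random"),
                      telomereBias = 0.25,
                      interference = c("dco_suppression", "haldane"),
                      psvPlacement = c("telomeric", "uniform"),
                      pDouble = 1, teFraction = 0.35, hitNoiseBp = 0,
                      log10EvalueMean = -30, log10EvalueSd = 4, seed = 1L) {
  new("SimConfig", nProgeny = as.integer(nProgeny),
      missingRate = missingRate, errorRate = errorRate,
      crossTypeProbs = crossTypeProbs,
      psvFraction = psvFraction, distortionLoci = distortionLoci,
      multivalentProb = multivalentProb,
      disjunctionMode = match.arg(disjunctionMode),
      telomereBias = telomereBias, interference = match.arg(interference),
      psvPlacement = match.arg(psvPlacement), pDouble = pDouble,
      teFraction = teFraction, hitNoiseBp = hitNoiseBp,
      log10EvalueMean = log10EvalueMean, log10EvalueSd = log10EvalueSd,
      seed = as.integer(seed))
}

#' GenomeModel: marker layout of the simulated genome
#'
#' @slot markers data.frame (lg, marker, pos_cM, arm, bp); cM positions are
#'   nondecreasing within a linkage group and bp positions monotone within
#'   an arm.
#' @slot homeologPairs data.frame (lg_a, lg_b) of homeologous linkage-group
#'   pairs; paired groups carry equal marker counts at matching positions so
#'   a homeologous exchange has a well-defined positional counterpart.
#' @slot arms data.frame (arm_id, chrom, start, end, centromere_side).
#' @export
setClass("GenomeModel",
  representation(markers = "data.frame", homeologPairs = "data.frame",
                 arms = "data.frame")
)

setValidity("GenomeModel", function(object) {
  msgs <- character()
  mk <- object@markers
  if (anyDuplicated(mk$marker)) msgs <- c(msgs, "duplicate marker ids")
  for (lg in unique(mk$lg)) {
    p <- mk$pos_cM[mk$lg == lg]
    if (is.unsorted(p) || any(p < 0))
      msgs <- c(msgs, sprintf("positions in %s must be nondecreasing, >= 0", lg))
  }
  a <- object@arms
  if (any(a$end - a$start + 1 <= 0)) msgs <- c(msgs, "arm lengths must be > 0")
  hp <- object@homeologPairs
  if (nrow(hp)) {
    if (!all(unlist(hp) %in% mk$lg))
      msgs <- c(msgs, "homeolog pairs must reference existing linkage groups")
    nA <- table(mk$lg)[hp$lg_a]
    nB <- table(mk$lg)[hp$lg_b]
    if (any(nA != nB))
      msgs <- c(msgs, "paired homeolog groups must have equal marker counts")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel: %d markers on %d linkage groups, %d homeolog pair(s)\n",
              nrow(object@markers), length(unique(object@markers$lg)),
              nrow(object@homeologPairs)))
})

#' TruthSet: simulator ground truth
#'
#' @slot trueMap data.frame mirror of the model's marker table (true order
#'   and cM positions per linkage group).
#' @slot phases list with elements \code{female} and \code{male}: integer
#'   0/1 matrices (mapped markers x progeny) of transmitted parental phases.
#' @slot psvMarkers character vector of PSV marker ids (these carry no map
#'   position, by construction).
#' @slot distortedMarkers character vector of transmission-distorted markers.
#' @slot tetrasomyEvents data.frame (progeny, parent, lg_a, lg_b,
#'   exchange_rel) of multivalent exchange events; exchange_rel is the
#'   relative arm position of the exchange point.
#' @slot alleles data.frame (marker, parent, allele0, allele1) giving the
#'   allele carried by phase-0 and phase-1 chromosomes of each parent.
#' @slot psvTruth data.frame (marker, arm_a, bp_a, arm_b, bp_b) of true PSV
#'   homeolog placements.
#' @export
setClass("TruthSet",
  representation(trueMap = "data.frame", phases = "list",
                 psvMarkers = "character", distortedMarkers = "character",
                 tetrasomyEvents = "data.frame", alleles = "data.frame",
                 psvTruth = "data.frame")
)

setValidity("TruthSet", function(object) {
  if (length(intersect(object@psvMarkers, object@trueMap$marker)))
    "PSV markers must not appear in the ordered true map" else TRUE
})

setMethod("show", "TruthSet", function(object) {
  cat(sprintf("TruthSet: %d mapped markers, %d PSVs, %d tetrasomy events\n",
              nrow(object@trueMap), length(object@psvMarkers),
              nrow(object@tetrasomyEvents)))
})
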