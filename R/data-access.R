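# Accessors for the curated Arctic charr / Atlantic salmon reference data
# shipped with the package.

.extdata <- function(f) {
  p <- system.file("extdata", f, package = "charrmap")
  if (p == "") stop("packaged data file not found: ", f)
  p
}

#' Curated Arctic charr homeolog pairs
#'
#' Reference table of homeologous linkage-group / chromosome-arm pairs in
#' Arctic charr (descendants of common pre-duplication ancestors), used as
#' the default whitelist for descending-LOD group joins and pseudolinkage
#' scanning.
#'
#' @return data.frame (homeolog_1, homeolog_2).
#' @export
charrHomeologPairs <- function() {
  utils::read.delim(.extdata("homeolog_pairs_arctic_charr.tsv"),
                    stringsAsFactors = FALSE)
}

#' Atlantic salmon chromosome-arm categories
#'
#' Reference classification of Atlantic salmon chromosome arms into
#' high-residual-tetrasomy arms (HRTA) and acrocentric homeolog pairs
#' (AHP), with their Arctic charr homologs.
#'
#' @return data.frame (ssa_arm, charr_lg, category).
#' @export
salmonArmCategories <- function() {
  df <- utils::read.delim(.extdata("atlantic_salmon_arm_categories.tsv"),
                          stringsAsFactors = FALSE)
  df$category[is.na(df$category)] <- ""
  df
}

#' Published-family pseudolinkage phase-class counts
#'
#' The four phase-class counts for the six marker pairs of the mapping
#' family's two pseudolinked homeolog pairs (AC01q/21 and AC13q/34), with
#' parental and recombinant class labels.
#'
#' @return data.frame with marker ids, class labels and counts.
#' @export
pseudolinkagePhaseCounts <- function() {
  utils::read.delim(.extdata("pseudolinkage_phase_counts.tsv"),
                    stringsAsFactors = FALSE)
}

#' Mapping-family top-hit counts by HRTA category
#'
#' Counts of linkage-map SNP and PSV top hits on HRTA vs other Atlantic
#' salmon chromosome arms in the mapping family.
#'
#' @return data.frame (kind, hrta, other).
#' @export
topHitHrtaCounts <- function() {
  utils::read.delim(.extdata("tophit_hrta_counts.tsv"),
                    stringsAsFactors = FALSE)
}

#' Mapping-family TE-hit counts by linkage-group category
#'
#' Counts of SNPs with and without significant TE hits, split by whether
#' their linkage group contains an HRTA.
#'
#' @return data.frame (group_category, no_te, te).
#' @export
teCategoryCounts <- function() {
  utils::read.delim(.extdata("te_category_counts.tsv"),
                    stringsAsFactors = FALSE)
}
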