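# Reference-genome comparative analyses: top-hit resolution, chromosome-arm
# quarter binning, category contingency tests, TE proportions, linkage-group
# composition and duplicate-tag detection.

#' Read a chromosome-arm definition table
#'
#' TSV with header: arm_id, chrom, start, end, centromere_side (low/high),
#' and optionally categories (comma-separated labels such as HRTA or AHP).
#'
#' @param path file path.
#' @return data.frame of arm definitions.
#' @export
readArmTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("arm_id", "chrom", "start", "end", "centromere_side")
  if (!all(need %in% names(df)))
    stop("arm table must have columns: ", paste(need, collapse = ", "))
  if (!"categories" %in% names(df)) df$categories <- ""
  if (any(df$start > df$end)) stop("arm start must be <= end")
  df
}

.armOfHit <- function(chrom, pos, arms) {
  hit <- which(arms$chrom == chrom & arms$start <= pos & arms$end >= pos)
  if (length(hit) == 1L) hit else NA_integer_
}

#' Resolve marker top hits to chromosome arms
#'
#' Keeps, per marker, every hit tied at the lowest e-value (ties are exact
#' matches of the printed e-value string, the aligner's own dialect;
#' \code{tieTol} enables a relative numeric tolerance instead). Tied hits
#' within one arm are collapsed to a single best hit per arm. Markers whose
#' tied top hits span one or two distinct arms are retained (two-arm
#' markers are duplicate-locus candidates); markers with three or more tied
#' arms, with no hits, or with hits outside every defined arm are dropped
#' and logged.
#'
#' @param hits data.frame from \code{\link{readHitTable}} /
#'   \code{\link{emitHitTables}}.
#' @param arms arm-definition data.frame (see \code{\link{readArmTable}}).
#' @param markerKinds optional named character vector (\code{"map_snp"} /
#'   \code{"psv"}) per marker; defaults to \code{"map_snp"}.
#' @param tieTol relative e-value tolerance for tie detection (default 0:
#'   exact string equality).
#' @return list with \code{assignments} (marker, kind, arm, bp, evalue,
#'   n_arms) and \code{dropped} (marker, reason).
#' @export
resolveTopHits <- function(hits, arms, markerKinds = NULL, tieTol = 0) {
  if (!"evalue_num" %in% names(hits))
    hits$evalue_num <- as.numeric(hits$evalue)
  # deterministic processing order: results are invariant to input order
  hits <- hits[order(hits$qseqid, hits$evalue_num, hits$evalue,
                     hits$sseqid, hits$sstart), ]
  armIdx <- mapply(.armOfHit, hits$sseqid, hits$sstart,
                   MoreArgs = list(arms = arms))
  assignments <- list(); droppedRows <- list()
  drop <- function(m, why) droppedRows[[length(droppedRows) + 1L]] <<-
    data.frame(marker = m, reason = why, stringsAsFactors = FALSE)
  for (m in unique(hits$qseqid)) {
    idx <- which(hits$qseqid == m)
    placed <- idx[!is.na(armIdx[idx])]
    if (!length(placed)) {
      drop(m, if (length(idx)) "unplaced" else "no_hit")
      next
    }
    sub <- hits[placed, ]
    subArm <- arms$arm_id[armIdx[placed]]
    minE <- min(sub$evalue_num)
    if (tieTol > 0) {
      top <- sub$evalue_num <= minE * (1 + tieTol)
    } else {
      topStr <- min(sub$evalue[sub$evalue_num == minE])
      top <- sub$evalue == topStr
    }
    topArms <- unique(subArm[top])
    if (length(topArms) >= 3L) {
      drop(m, "multi_arm")
      next
    }
    kind <- if (!is.null(markerKinds) && m %in% names(markerKinds) &&
                  !is.na(markerKinds[[m]])) markerKinds[[m]] else "map_snp"
    for (a in sort(topArms)) {
      w <- which(top & subArm == a)
      best <- w[order(-sub$bitscore[w], sub$sstart[w])][1L]
      assignments[[length(assignments) + 1L]] <- data.frame(
        marker = m, kind = kind, arm = a, bp = sub$sstart[best],
        evalue = sub$evalue[best], n_arms = length(topArms),
        stringsAsFactors = FALSE)
    }
  }
  list(assignments = if (length(assignments)) do.call(rbind, assignments)
       else data.frame(marker = character(), kind = character(),
                       arm = character(), bp = numeric(),
                       evalue = character(), n_arms = integer(),
                       stringsAsFactors = FALSE),
       dropped = if (length(droppedRows)) do.call(rbind, droppedRows)
       else data.frame(marker = character(), reason = character(),
                       stringsAsFactors = FALSE))
}

#' Bin arm assignments into chromosome-arm quarters
#'
#' Each arm is divided into four equal quarters; quarter 1 is
#' centromere-proximal and quarter 4 telomeric, per the arm's
#' \code{centromere_side}. Bins are half-open with the last bin closed:
#' quarter = min(4, 1 + floor(4 * offset / length)) with offset the 1-based
#' distance from the centromeric end.
#'
#' @param assignments data.frame from \code{\link{resolveTopHits}}.
#' @param arms arm-definition data.frame.
#' @return \code{assignments} with a \code{quarter} column.
#' @export
binQuarters <- function(assignments, arms) {
  i <- match(assignments$arm, arms$arm_id)
  if (anyNA(i)) stop("assignment references unknown arm")
  len <- arms$end[i] - arms$start[i] + 1
  off <- ifelse(arms$centromere_side[i] == "low",
                assignments$bp - arms$start[i] + 1,
                arms$end[i] - assignments$bp + 1)
  if (any(off < 1 | off > len)) stop("hit position outside its arm")
  assignments$quarter <- pmin(4L, 1L + floor(4 * off / len))
  assignments
}

#' Pearson chi-square for a contingency table
#'
#' Expected counts from the margins; no continuity correction by default
#' (set \code{correct = TRUE} for Yates on 2x2 tables). A warning is
#' attached when any expected cell is below 1.
#'
#' @param m a counts matrix.
#' @param correct apply the Yates correction (2x2 only).
#' @return list with \code{chi2}, \code{df}, \code{p}, \code{expected}.
#' @export
contingencyChisq <- function(m, correct = FALSE) {
  m <- as.matrix(m)
  n <- sum(m)
  if (n == 0) stop("empty contingency table")
  e <- outer(rowSums(m), colSums(m)) / n
  if (any(e < 1)) warning("expected cell count below 1")
  dev <- abs(m - e)
  if (correct && all(dim(m) == 2L)) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / e)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE), expected = e)
}

.armsInCategory <- function(arms, category) {
  hit <- vapply(strsplit(arms$categories, ","), function(x)
    category %in% trimws(x), logical(1))
  arms$arm_id[hit]
}

#' Contingency test of marker-kind counts on a chromosome-arm category
#'
#' Compares the number of linkage-map and PSV top hits on arms of the given
#' category (HRTA: high-residual-tetrasomy arms; AHP: acrocentric homeolog
#' pairs) with the number on all other arms: a 2x2 Pearson chi-square
#' (rows map_snp / psv, columns in-category / other).
#'
#' @param assignments data.frame with \code{kind} and \code{arm} columns.
#' @param arms arm table with a \code{categories} column.
#' @param category \code{"HRTA"} or \code{"AHP"}.
#' @param correct Yates correction (default off).
#' @return list with \code{counts} (2x2), \code{chi2}, \code{df}, \code{p},
#'   \code{proportions} (in-category share per kind).
#' @export
categoryContingency <- function(assignments, arms,
                                category = c("HRTA", "AHP"),
                                correct = FALSE) {
  category <- match.arg(category)
  inCat <- assignments$arm %in% .armsInCategory(arms, category)
  kind <- factor(assignments$kind, levels = c("map_snp", "psv"))
  counts <- base::table(kind, factor(ifelse(inCat, "in_category", "other"),
                                     levels = c("in_category", "other")))
  counts <- matrix(as.integer(counts), 2, 2,
                   dimnames = list(c("map_snp", "psv"),
                                   c("in_category", "other")))
  res <- contingencyChisq(counts, correct = correct)
  res$counts <- counts
  res$proportions <- counts[, 1] / rowSums(counts)
  res
}

#' Quarter-distribution test for map SNPs vs PSVs
#'
#' Pools quarter-binned top hits across all arms and tests whether the
#' frequency of linkage-map SNPs and PSVs varies across chromosome-arm
#' quarters: a 2x4 contingency chi-square (3 df), plus per-kind
#' goodness-of-fit tests against a uniform quarter distribution as a
#' secondary output.
#'
#' @param assignments quarter-annotated data.frame from
#'   \code{\link{binQuarters}}.
#' @return list with \code{counts} (2x4), \code{chi2}, \code{df}, \code{p},
#'   and \code{gof} (per-kind uniform goodness-of-fit).
#' @export
quarterDistributionTest <- function(assignments) {
  kind <- factor(assignments$kind, levels = c("map_snp", "psv"))
  q <- factor(assignments$quarter, levels = 1:4)
  counts <- base::table(kind, q)
  counts <- matrix(as.integer(counts), 2, 4,
                   dimnames = list(c("map_snp", "psv"), paste0("q", 1:4)))
  res <- contingencyChisq(counts)
  res$counts <- counts
  res$gof <- lapply(rownames(counts), function(k) {
    x <- counts[k, ]
    n <- sum(x)
    if (n == 0) return(list(chi2 = NA, df = 3L, p = NA))
    chi2 <- sum((x - n / 4)^2 / (n / 4))
    list(chi2 = chi2, df = 3L,
         p = stats::pchisq(chi2, 3L, lower.tail = FALSE))
  })
  names(res$gof) <- rownames(counts)
  res
}

#' TE-hit proportions per marker category
#'
#' A marker is TE-positive when it has any row in the TE hit table. Returns
#' the TE-positive proportion per category and the contingency chi-square
#' across categories (no-TE vs TE counts).
#'
#' @param markerSets named list of character vectors, one per category
#'   (e.g. markers on HRTA-containing linkage groups vs the rest).
#' @param teTable TE hit data.frame with a \code{qseqid} column.
#' @return list with \code{table} (category x no_te/te), \code{proportions},
#'   \code{chi2}, \code{df}, \code{p}, \code{ignored} (TE-table markers in
#'   no category).
#' @export
teProportions <- function(markerSets, teTable) {
  tePos <- unique(teTable$qseqid)
  counts <- t(vapply(markerSets, function(mk) {
    te <- sum(mk %in% tePos)
    c(no_te = length(mk) - te, te = te)
  }, numeric(2)))
  ignored <- setdiff(tePos, unlist(markerSets))
  res <- if (all(rowSums(counts) > 0) && nrow(counts) > 1 && sum(counts) > 0
             && all(colSums(counts) > 0))
    contingencyChisq(counts) else list(chi2 = NA, df = NA, p = NA)
  list(table = counts,
       proportions = counts[, "te"] / pmax(rowSums(counts), 1),
       chi2 = res$chi2, df = res$df, p = res$p, ignored = ignored)
}

#' Classify linkage-group arm composition
#'
#' Walks the arm assignments of a group's markers in map order, compacts
#' them into majority blocks, and calls the group \code{"compound"} when
#' two or more ancestral arms are each supported by at least
#' \code{minBlock} markers (single stray hits are TE/paralog noise);
#' otherwise \code{"simple"}. Groups with fewer than 3 assigned markers are
#' \code{"unclassified"}. Metacentric vs tandem-fused-acrocentric structure
#' cannot be distinguished without karyotype input; an optional
#' \code{karyotype} annotation (named vector group -> label) is passed
#' through when present.
#'
#' @param orderedMarkers marker ids in map order.
#' @param assignments data.frame from \code{\link{resolveTopHits}}
#'   (single-arm rows are used).
#' @param minBlock minimum markers supporting an arm (default 3).
#' @param karyotype optional named character vector of group labels.
#' @param lg optional group id used for the karyotype lookup.
#' @return list with \code{class}, \code{arms} (supporting arms), and
#'   \code{blocks} (run-length summary along the map).
#' @export
classifyLgComposition <- function(orderedMarkers, assignments, minBlock = 3,
                                  karyotype = NULL, lg = NULL) {
  a <- assignments[assignments$n_arms == 1 &
                     assignments$marker %in% orderedMarkers, ]
  armOf <- stats::setNames(a$arm, a$marker)
  seqArms <- armOf[orderedMarkers]
  seqArms <- seqArms[!is.na(seqArms)]
  if (length(seqArms) < 3L)
    return(list(class = "unclassified", arms = character(),
                blocks = data.frame(arm = character(), n = integer())))
  rl <- rle(as.vector(seqArms))
  blocks <- data.frame(arm = rl$values, n = rl$lengths,
                       stringsAsFactors = FALSE)
  support <- tapply(rep(1L, length(seqArms)), seqArms, sum)
  arms <- names(support)[support >= minBlock]
  cls <- if (length(arms) >= 2L) "compound" else "simple"
  if (cls == "compound" && !is.null(karyotype) && !is.null(lg) &&
      lg %in% names(karyotype))
    cls <- karyotype[[lg]]
  list(class = cls, arms = sort(arms), blocks = blocks)
}

#' Find duplicated tag sequences
#'
#' All-vs-all comparison of short (<= 64 bp) tag sequences: candidate pairs
#' share at least one exact k-mer (forward or reverse complement), then are
#' aligned with BLASTn-like scoring (match 2, mismatch -3, gap open 5, gap
#' extend 2; ends-free overlap alignment, both strands). Pairs whose
#' aligned identity and mutual length overlap both reach the thresholds are
#' duplicates — reciprocal near-identical copies, the signature of
#' retained post-duplication paralogs — and are classified by map position:
#' \code{inter_lg} (different groups, potential homeologs), \code{tandem}
#' (same group, adjacent map ranks) or \code{intra_lg} (same group,
#' regional duplicates).
#'
#' @param tagSequences named character vector of A/C/G/T sequences.
#' @param minIdentity minimum aligned identity (default 0.95).
#' @param minOverlap minimum aligned fraction of the shorter sequence
#'   (default 0.95).
#' @param mapPositions optional data.frame (marker, lg, rank) for
#'   classification.
#' @param k prefilter k-mer size (default 16).
#' @return data.frame: marker_a, marker_b, identity, overlap, strand, class.
#' @export
findDuplicateTags <- function(tagSequences, minIdentity = 0.95,
                              minOverlap = 0.95, mapPositions = NULL,
                              k = 16L) {
  bad <- grepl("[^ACGT]", tagSequences)
  if (any(bad))
    stop("sequence with non-ACGT characters rejected: ",
         names(tagSequences)[bad][1])
  ids <- names(tagSequences)
  n <- length(ids)
  kmers <- function(s) {
    L <- nchar(s)
    if (L < k) return(s)
    substring(s, 1:(L - k + 1L), k:L)
  }
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (km in unique(c(kmers(tagSequences[i]), kmers(rc(tagSequences[i]))))) {
      idx[[km]] <- c(idx[[km]], i)
    }
  }
  cand <- unique(do.call(rbind, lapply(ls(idx), function(km) {
    v <- sort(unique(idx[[km]]))
    if (length(v) < 2L) return(NULL)
    t(utils::combn(v, 2L))
  })))
  if (is.null(cand) || !nrow(cand))
    return(data.frame(marker_a = character(), marker_b = character(),
                      identity = numeric(), overlap = numeric(),
                      strand = character(), class = character(),
                      stringsAsFactors = FALSE))
  subMat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3,
                                                     baseOnly = TRUE)
  alignPair <- function(s1, s2) {
    aln <- Biostrings::pairwiseAlignment(s1, s2, type = "overlap",
                                         substitutionMatrix = subMat,
                                         gapOpening = 5, gapExtension = 2)
    cols <- nchar(as.character(Biostrings::pattern(aln)))
    if (cols == 0) return(c(identity = 0, overlap = 0))
    c(identity = Biostrings::nmatch(aln) / cols,
      overlap = min(1, cols / min(nchar(s1), nchar(s2))))
  }
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    fwd <- alignPair(tagSequences[i], tagSequences[j])
    rev <- alignPair(tagSequences[i], rc(tagSequences[j]))
    use <- if (fwd["identity"] * fwd["overlap"] >=
                 rev["identity"] * rev["overlap"]) list(fwd, "+") else
                   list(rev, "-")
    v <- use[[1]]
    if (v["identity"] >= minIdentity && v["overlap"] >= minOverlap) {
      cls <- "unplaced"
      if (!is.null(mapPositions)) {
        pa <- mapPositions[mapPositions$marker == ids[i], ]
        pb <- mapPositions[mapPositions$marker == ids[j], ]
        if (nrow(pa) && nrow(pb)) {
          cls <- if (pa$lg[1] != pb$lg[1]) "inter_lg"
            else if (abs(pa$rank[1] - pb$rank[1]) <= 1L) "tandem"
            else "intra_lg"
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        marker_a = ids[i], marker_b = ids[j],
        identity = unname(v["identity"]), overlap = unname(v["overlap"]),
        strand = use[[2]], class = cls, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(marker_a = character(), marker_b = character(),
               identity = numeric(), overlap = numeric(),
               strand = character(), class = character(),
               stringsAsFactors = FALSE)
}
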