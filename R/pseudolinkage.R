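# Weak pseudolinkage between homeologous linkage groups: phase tables,
# 1:1:1:1 tests, and LOD-window detection.

#' Four-class phase table for a marker pair
#'
#' Counts the four transmitted-allele combinations (alleles of marker A x
#' alleles of marker B, for the given parent) over progeny that are doubly
#' called and phase-resolvable at both markers. For DH markers only
#' homozygous progeny are resolvable, so roughly half the progeny drop out.
#'
#' @param markerA,markerB marker ids.
#' @param table a \linkS4class{GenotypeTable}.
#' @param parent \code{"female"} or \code{"male"}.
#' @return list of class \code{"PhaseTable"}: \code{classes} (labels like
#'   \code{"G/A"}), \code{counts} (4 integers, zeros allowed),
#'   \code{n_total}, \code{alleles_a}, \code{alleles_b}, marker ids and
#'   parent; all-zero tables carry \code{flag = "no_informative_progeny"}.
#' @export
phaseTable <- function(markerA, markerB, table, parent) {
  al <- .alleleMatrix(table, parent, c(markerA, markerB))
  aA <- sort(strsplit(parentGenotypes(table, parent)[[markerA]], "")[[1]])
  aB <- sort(strsplit(parentGenotypes(table, parent)[[markerB]], "")[[1]])
  ok <- !is.na(al[1, ]) & !is.na(al[2, ])
  classes <- as.vector(outer(aA, aB, paste, sep = "/"))
  counts <- stats::setNames(integer(4), classes)
  if (any(ok)) {
    obs <- paste(al[1, ok], al[2, ok], sep = "/")
    counts[] <- tabulate(factor(obs, levels = classes), nbins = 4L)
  }
  structure(list(marker_a = markerA, marker_b = markerB,
                 alleles_a = aA, alleles_b = aB, classes = classes,
                 counts = counts, n_total = sum(counts), parent = parent,
                 flag = if (sum(counts) == 0) "no_informative_progeny" else
                   NULL),
            class = "PhaseTable")
}

#' Chi-square test against a 1:1:1:1 phase-class distribution
#'
#' Pearson goodness-of-fit with expected n/4 per class, 3 df. Equal
#' transmission of the four allele combinations is the null under
#' independent disomic segregation of the two markers.
#'
#' @param x a \code{"PhaseTable"} or a numeric vector of 4 class counts.
#' @return list with \code{chi2}, \code{df = 3}, \code{p}.
#' @examples
#' chisq1111(c(32, 25, 23, 5))$chi2  # 18.67
#' @export
chisq1111 <- function(x) {
  counts <- if (inherits(x, "PhaseTable")) x$counts else x
  if (length(counts) != 4L) stop("need exactly 4 class counts")
  n <- sum(counts)
  if (n == 0) stop("empty phase table: chi-square undefined")
  e <- n / 4
  chi2 <- sum((counts - e)^2 / e)
  list(chi2 = chi2, df = 3L, p = stats::pchisq(chi2, 3L, lower.tail = FALSE))
}

#' Detect weak pseudolinkage between homeologous groups
#'
#' For every whitelisted homeolog pair whose members sit in different
#' linkage groups, the maximum cross-group two-point LOD is computed. Pairs
#' whose maximum falls inside the LOD window (default [3, 5], both ends
#' inclusive) yield calls: the linking (argmax) marker pair's phase table
#' is tabulated and tested against 1:1:1:1, and the direction of excess is
#' classified as \code{parental_excess} or \code{nonparental_excess}.
#' Cross-group maxima above the window are reported as anomalies
#' (\code{accepted = FALSE}) — possible group misassembly — not calls.
#'
#' Direction needs an allele orientation: \code{orientation} maps each
#' marker to the allele carried by its phase-0 chromosome (data.frame
#' marker, allele0), as provided by the simulator truth or by prior
#' knowledge of the homeolog coupling. The parental classes are
#' (allele0_A/allele0_B, allele1_A/allele1_B); swapping one marker's allele
#' labels flips the direction label while the chi-square is unchanged.
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param parent \code{"female"} or \code{"male"}.
#' @param grouping a \code{"GroupingResult"}.
#' @param pairs data.frame from \code{\link{twoPointAll}}.
#' @param whitelist 2-column data.frame of homeolog id pairs.
#' @param groupIds optional named vector translating group labels to
#'   whitelist ids.
#' @param lodWindow acceptance window (default \code{c(3, 5)}).
#' @param orientation optional data.frame (marker, allele0).
#' @return data.frame: group_a, group_b, marker_a, marker_b, n1..n4 (class
#'   counts), n_total, chi2, p, direction, lod, accepted.
#' @export
detectPseudolinkage <- function(table, parent, grouping, pairs, whitelist,
                                groupIds = NULL, lodWindow = c(3, 5),
                                orientation = NULL) {
  stopifnot(length(lodWindow) == 2L, lodWindow[1] <= lodWindow[2])
  labs <- names(grouping$groups)
  ids <- if (is.null(groupIds))
    stats::setNames(labs, labs) else groupIds[labs]
  out <- list()
  for (w in seq_len(nrow(whitelist))) {
    pa <- whitelist[w, 1]; pb <- whitelist[w, 2]
    ga <- labs[which(ids == pa)]; gb <- labs[which(ids == pb)]
    if (length(ga) != 1L || length(gb) != 1L || ga == gb) next
    memA <- grouping$groups[[ga]]; memB <- grouping$groups[[gb]]
    cross <- pairs[(pairs$marker_a %in% memA & pairs$marker_b %in% memB) |
                   (pairs$marker_a %in% memB & pairs$marker_b %in% memA), ]
    cross <- cross[!is.na(cross$lod), ]
    if (!nrow(cross)) next
    cross <- cross[order(-cross$lod, cross$marker_a, cross$marker_b), ]
    best <- cross[1L, ]
    if (best$lod < lodWindow[1]) next
    accepted <- best$lod <= lodWindow[2]
    mA <- best$marker_a; mB <- best$marker_b
    pt <- phaseTable(mA, mB, table, parent)
    ts <- chisq1111(pt)
    direction <- NA_character_
    if (!is.null(orientation)) {
      o <- stats::setNames(orientation$allele0, orientation$marker)
      a0 <- o[[mA]]; b0 <- o[[mB]]
      if (!is.null(a0) && !is.null(b0)) {
        a1 <- setdiff(pt$alleles_a, a0)
        b1 <- setdiff(pt$alleles_b, b0)
        par <- pt$counts[[paste(a0, b0, sep = "/")]] +
          pt$counts[[paste(a1, b1, sep = "/")]]
        nonpar <- pt$n_total - par
        direction <- if (par > nonpar) "parental_excess"
          else if (nonpar > par) "nonparental_excess" else NA_character_
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      group_a = ga, group_b = gb, marker_a = mA, marker_b = mB,
      n1 = pt$counts[1], n2 = pt$counts[2], n3 = pt$counts[3],
      n4 = pt$counts[4], n_total = pt$n_total, chi2 = ts$chi2, p = ts$p,
      direction = direction, lod = best$lod, accepted = accepted,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(group_a = character(), group_b = character(),
               marker_a = character(), marker_b = character(),
               n1 = integer(), n2 = integer(), n3 = integer(),
               n4 = integer(), n_total = integer(), chi2 = numeric(),
               p = numeric(), direction = character(), lod = numeric(),
               accepted = logical(), stringsAsFactors = FALSE)
}
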