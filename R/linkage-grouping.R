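#' Two-point linkage analysis for one marker pair
#'
#' Over the N progeny with resolvable phases at both markers in the given
#' parent, k counts the progeny whose two phases agree. The recombination
#' fraction estimate is r = min(k, N-k)/N (the phase label — coupling or
#' repulsion — is chosen so that r <= 0.5) and the LOD score is
#' R log10(r) + (N-R) log10(1-r) + N log10(2) with R = min(k, N-k); at
#' r = 0 the limit N log10(2) is used. Double-heterozygote markers
#' contribute only progeny homozygous at the DH marker (the phase of
#' heterozygous progeny cannot be ascertained).
#'
#' @param markerA,markerB marker ids.
#' @param parent \code{"female"} or \code{"male"}.
#' @param table a \linkS4class{GenotypeTable}.
#' @return list with \code{r_hat}, \code{lod}, \code{phase},
#'   \code{n_informative}, \code{n_recombinant}; \code{n_informative = 0}
#'   yields an undefined record (NA estimates) that grouping excludes.
#' @export
twoPoint <- function(markerA, markerB, parent, table) {
  ph <- .phaseMatrix(table, parent, c(markerA, markerB))
  .twoPointFromPhases(ph[1, ], ph[2, ])
}

.lodAt <- function(R, N) {
  r <- R / N
  if (R == 0) return(N * log10(2))
  R * log10(r) + (N - R) * log10(1 - r) + N * log10(2)
}

.twoPointFromPhases <- function(pa, pb) {
  ok <- !is.na(pa) & !is.na(pb)
  N <- sum(ok)
  if (N == 0)
    return(list(r_hat = NA_real_, lod = NA_real_, phase = NA_character_,
                n_informative = 0L, n_recombinant = NA_integer_))
  k <- sum(pa[ok] == pb[ok])
  R <- min(k, N - k)
  list(r_hat = R / N, lod = .lodAt(R, N),
       phase = if (k >= N - k) "coupling" else "repulsion",
       n_informative = N, n_recombinant = R)
}

#' All pairwise two-point results for one parent
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param parent \code{"female"} or \code{"male"}.
#' @param markers markers to include; defaults to every marker informative
#'   in \code{parent} (single-parent-informative plus DH) according to
#'   \code{classes}.
#' @param classes optional precomputed \code{\link{classifyMarkers}} output.
#' @return data.frame (marker_a, marker_b, parent, n, k, R, r_hat, lod,
#'   phase), one row per unordered pair with \code{marker_a < marker_b}.
#' @export
twoPointAll <- function(table, parent, markers = NULL, classes = NULL) {
  if (is.null(markers)) {
    if (is.null(classes)) classes <- classifyMarkers(table)
    want <- if (parent == "female") "maternal_informative" else
      "paternal_informative"
    markers <- classes$marker[classes$cross_type %in% c(want, "double_het")]
  }
  markers <- sort(markers)
  ph <- .phaseMatrix(table, parent, markers)
  called <- !is.na(ph)
  A <- (ph == 1L) & called; A[is.na(A)] <- FALSE
  B <- (ph == 0L) & called; B[is.na(B)] <- FALSE
  N <- tcrossprod(called * 1)
  K <- tcrossprod(A * 1) + tcrossprod(B * 1)
  ut <- which(upper.tri(N), arr.ind = TRUE)
  n <- N[ut]; k <- K[ut]
  R <- pmin(k, n - k)
  r <- ifelse(n > 0, R / n, NA_real_)
  lod <- ifelse(n == 0, NA_real_,
                ifelse(R == 0, n * log10(2),
                       R * log10(pmax(r, .Machine$double.eps)) +
                         (n - R) * log10(1 - r) + n * log10(2)))
  data.frame(marker_a = markers[ut[, 1]], marker_b = markers[ut[, 2]],
             parent = parent, n = n, k = k, R = R, r_hat = r, lod = lod,
             phase = ifelse(n == 0, NA_character_,
                            ifelse(k >= n - k, "coupling", "repulsion")),
             stringsAsFactors = FALSE)
}

#' Partition markers into linkage groups at a LOD threshold
#'
#' Single-linkage transitive closure over marker pairs with LOD at or above
#' the threshold (LOD 10 is the published standard for group assessment).
#' Group labels are the lexicographically smallest member, so labels are
#' deterministic. Markers in no qualifying pair are listed as unassigned.
#'
#' @param pairs data.frame from \code{\link{twoPointAll}}.
#' @param lodThreshold minimum LOD for an edge (default 10).
#' @param markers optional full marker universe (so isolated markers are
#'   reported as unassigned).
#' @return list of class \code{"GroupingResult"}: \code{groups} (named list
#'   of marker vectors), \code{membership} (named character), \code{unassigned},
#'   \code{assignmentLod} (per-marker best within-group LOD) and
#'   \code{joinLog}.
#' @export
groupMarkers <- function(pairs, lodThreshold = 10, markers = NULL) {
  if (is.null(markers))
    markers <- sort(unique(c(pairs$marker_a, pairs$marker_b)))
  keep <- !is.na(pairs$lod) & pairs$lod >= lodThreshold
  edges <- pairs[keep, c("marker_a", "marker_b", "lod")]
  membership <- stats::setNames(rep(NA_character_, length(markers)), markers)
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                       vertices = data.frame(name = markers))
    comp <- igraph::components(g)
    for (cid in seq_len(comp$no)) {
      mem <- names(comp$membership)[comp$membership == cid]
      if (length(mem) > 1L) membership[mem] <- min(mem)
    }
  }
  groups <- split(names(membership)[!is.na(membership)],
                  membership[!is.na(membership)])
  groups <- lapply(groups, sort)
  bestLod <- stats::setNames(rep(NA_real_, length(markers)), markers)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$marker_a[i]; b <- edges$marker_b[i]; l <- edges$lod[i]
      bestLod[a] <- max(bestLod[a], l, na.rm = TRUE)
      bestLod[b] <- max(bestLod[b], l, na.rm = TRUE)
    }
  }
  structure(list(groups = groups, membership = membership,
                 unassigned = names(membership)[is.na(membership)],
                 assignmentLod = bestLod,
                 joinLog = data.frame(step = numeric(), type = character(),
                                      a = character(), b = character(),
                                      lod = numeric(),
                                      whitelist_used = logical(),
                                      accepted = logical(),
                                      stringsAsFactors = FALSE),
                 lodThreshold = lodThreshold),
            class = "GroupingResult")
}

.pairLodToGroups <- function(marker, groups, pairs) {
  # best LOD from `marker` to each group
  rel <- pairs[pairs$marker_a == marker | pairs$marker_b == marker, ]
  if (!nrow(rel)) return(stats::setNames(numeric(0), character(0)))
  other <- ifelse(rel$marker_a == marker, rel$marker_b, rel$marker_a)
  vapply(groups, function(mem) {
    l <- rel$lod[other %in% mem]
    if (length(l)) max(l, na.rm = TRUE) else -Inf
  }, numeric(1))
}

#' Descending-LOD marker assignment with homeolog-gated merges
#'
#' Re-examines unassigned markers at a descending LOD schedule (default
#' 6, 5, 4, 3). At each step a marker linking to exactly one existing group
#' at or above the step's LOD is assigned to it; a marker linking to two or
#' more groups is left unassigned and logged as ambiguous. Additions that
#' would join two existing groups are accepted only when the pair of groups
#' is on the homeolog whitelist (joinings of groups known to be homeologous
#' to one another); every decision is logged.
#'
#' @param grouping a \code{"GroupingResult"} from \code{\link{groupMarkers}}.
#' @param pairs data.frame from \code{\link{twoPointAll}}.
#' @param whitelist 2-column data.frame of id pairs allowed to merge;
#'   entries are matched against group labels, or against
#'   \code{groupIds[label]} when \code{groupIds} is given.
#' @param schedule descending LOD steps (default \code{c(6, 5, 4, 3)}).
#' @param groupIds optional named character vector translating group labels
#'   to the external (e.g. chromosome-arm) ids used by the whitelist.
#' @return An updated \code{"GroupingResult"} with an audit \code{joinLog}.
#' @export
descendingLodMerge <- function(grouping, pairs, whitelist = NULL,
                               schedule = c(6, 5, 4, 3), groupIds = NULL) {
  groups <- grouping$groups
  membership <- grouping$membership
  assignmentLod <- grouping$assignmentLod
  log <- grouping$joinLog
  wl <- if (is.null(whitelist) || !nrow(whitelist)) NULL else {
    t(apply(as.matrix(whitelist[, 1:2]), 1, sort))
  }
  onWhitelist <- function(la, lb) {
    if (is.null(wl)) return(FALSE)
    ida <- if (is.null(groupIds)) la else groupIds[[la]]
    idb <- if (is.null(groupIds)) lb else groupIds[[lb]]
    if (is.null(ida) || is.null(idb) || is.na(ida) || is.na(idb)) return(FALSE)
    p <- sort(c(ida, idb))
    any(wl[, 1] == p[1] & wl[, 2] == p[2])
  }
  for (step in sort(schedule, decreasing = TRUE)) {
    # singleton attachment, evaluated against the groups at step start
    snapshot <- groups
    unass <- sort(names(membership)[is.na(membership)])
    for (m in unass) {
      lods <- .pairLodToGroups(m, snapshot, pairs)
      hit <- names(lods)[is.finite(lods) & lods >= step]
      if (length(hit) == 1L) {
        groups[[hit]] <- sort(c(groups[[hit]], m))
        membership[m] <- hit
        assignmentLod[m] <- lods[[hit]]
        log <- rbind(log, data.frame(step = step, type = "attach", a = m,
                                     b = hit, lod = lods[[hit]],
                                     whitelist_used = FALSE, accepted = TRUE,
                                     stringsAsFactors = FALSE))
      } else if (length(hit) > 1L) {
        log <- rbind(log, data.frame(step = step, type = "ambiguous", a = m,
                                     b = paste(hit, collapse = "+"),
                                     lod = max(lods[hit]),
                                     whitelist_used = FALSE, accepted = FALSE,
                                     stringsAsFactors = FALSE))
      }
    }
    # group-group merges, whitelist-gated
    labs <- names(groups)
    if (length(labs) > 1L) {
      for (i in seq_along(labs)[-length(labs)]) {
        for (j in seq((i + 1L), length(labs))) {
          la <- labs[i]; lb <- labs[j]
          if (!la %in% names(groups) || !lb %in% names(groups)) next
          memA <- groups[[la]]; memB <- groups[[lb]]
          cross <- pairs[(pairs$marker_a %in% memA & pairs$marker_b %in% memB) |
                         (pairs$marker_a %in% memB & pairs$marker_b %in% memA), ]
          if (!nrow(cross)) next
          best <- suppressWarnings(max(cross$lod, na.rm = TRUE))
          if (!is.finite(best) || best < step) next
          ok <- onWhitelist(la, lb)
          log <- rbind(log, data.frame(step = step, type = "merge", a = la,
                                       b = lb, lod = best,
                                       whitelist_used = ok, accepted = ok,
                                       stringsAsFactors = FALSE))
          if (ok) {
            newLab <- min(c(memA, memB))
            merged <- sort(c(memA, memB))
            groups[[la]] <- NULL; groups[[lb]] <- NULL
            groups[[newLab]] <- merged
            membership[merged] <- newLab
          }
        }
      }
      groups <- groups[order(names(groups))]
    }
  }
  structure(list(groups = groups, membership = membership,
                 unassigned = names(membership)[is.na(membership)],
                 assignmentLod = assignmentLod, joinLog = log,
                 lodThreshold = grouping$lodThreshold),
            class = "GroupingResult")
}

#' Label linkage groups by the majority of an external marker label
#'
#' Maps each group to the most frequent label among its members (ties to
#' the lexicographically smallest label) — e.g. to translate data-driven
#' group labels into linkage-group or chromosome-arm ids for whitelist
#' matching.
#'
#' @param grouping a \code{"GroupingResult"}.
#' @param markerLabels named character vector (marker -> label).
#' @return named character vector (group label -> majority label).
#' @export
majorityGroupIds <- function(grouping, markerLabels) {
  vapply(grouping$groups, function(mem) {
    lab <- markerLabels[mem]
    lab <- lab[!is.na(lab)]
    if (!length(lab)) return(NA_character_)
    tab <- sort(base::table(lab), decreasing = TRUE)
    names(tab)[1]
  }, character(1))
}

#' Assign double-heterozygote markers to linkage groups
#'
#' DH markers are assigned to the group of their best-LOD partner when that
#' LOD reaches the threshold; they are never given map positions (their
#' phase is unresolvable in half the progeny, so ordering them is not
#' supported).
#'
#' @param grouping a \code{"GroupingResult"}.
#' @param pairs two-point results including the DH markers (e.g.
#'   \code{twoPointAll} run over informative + DH markers).
#' @param dhMarkers character vector of DH marker ids.
#' @param lodThreshold minimum LOD for assignment (default 10).
#' @return data.frame (marker, group, lod); unassigned markers have NA group.
#' @export
assignDhMarkers <- function(grouping, pairs, dhMarkers, lodThreshold = 10) {
  rows <- lapply(sort(dhMarkers), function(m) {
    rel <- pairs[(pairs$marker_a == m & !pairs$marker_b %in% dhMarkers) |
                 (pairs$marker_b == m & !pairs$marker_a %in% dhMarkers), ]
    rel <- rel[!is.na(rel$lod), ]
    if (!nrow(rel))
      return(data.frame(marker = m, group = NA_character_, lod = NA_real_,
                        stringsAsFactors = FALSE))
    best <- rel[which.max(rel$lod), ]
    partner <- if (best$marker_a == m) best$marker_b else best$marker_a
    grp <- grouping$membership[[partner]]
    if (is.na(grp) || best$lod < lodThreshold)
      data.frame(marker = m, group = NA_character_, lod = best$lod,
                 stringsAsFactors = FALSE)
    else
      data.frame(marker = m, group = grp, lod = best$lod,
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
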