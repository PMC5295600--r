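# Marker ordering by recombination-count minimisation, adjacent-DCO
# refinement, and map-distance estimation with DCO masking.

# COUNT objective: total recombination events summed over progeny, counted
# between consecutive *called* markers in the candidate order.
.countObjective <- function(phase, ord) {
  M <- phase[ord, , drop = FALSE]
  if (!anyNA(M)) {
    d <- M[-1L, , drop = FALSE] != M[-nrow(M), , drop = FALSE]
    return(sum(d))
  }
  sum(apply(M, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) 0L else sum(v[-1L] != v[-length(v)])
  }))
}

# pairwise recombinant-count matrix over shared-called progeny
.recombCountMatrix <- function(phase) {
  called <- !is.na(phase)
  A <- (phase == 1L) & called; A[is.na(A)] <- FALSE
  B <- (phase == 0L) & called; B[is.na(B)] <- FALSE
  N <- tcrossprod(called * 1)
  same <- tcrossprod(A * 1) + tcrossprod(B * 1)
  N - same
}

# collapse markers with identical phase vectors into bins; returns
# representative phase matrix plus bin membership (sorted lexicographically,
# so co-segregating markers are ordered arbitrarily but stably)
.collapseBins <- function(phase) {
  key <- apply(phase, 1L, function(v) paste(ifelse(is.na(v), "N", v),
                                            collapse = ""))
  bins <- split(rownames(phase), key)
  bins <- lapply(bins, sort)
  reps <- vapply(bins, `[`, "", 1L)
  names(bins) <- reps
  list(phase = phase[reps, , drop = FALSE], bins = bins)
}

.expandBins <- function(repOrder, bins) unlist(bins[repOrder], use.names = FALSE)

#' Order markers by recombination-count minimisation (RECORD-style)
#'
#' Greedy sequential insertion: markers are added one at a time, each at the
#' position minimising COUNT, the total number of recombination events
#' between adjacent called markers summed over progeny. The best of
#' \code{restarts} randomised insertion orders is kept; ties between final
#' orderings are broken by the lexicographically smaller canonical (order
#' vs. its reversal) marker sequence, so results are deterministic for a
#' given seed. Markers with identical inheritance vectors are collapsed
#' into a zero-recombination bin and listed stably in marker-id order.
#'
#' @param markers marker ids to order (>= 2).
#' @param table a \linkS4class{GenotypeTable}.
#' @param parent \code{"female"} or \code{"male"}.
#' @param restarts randomised insertion orders to try (default 20).
#' @param seed RNG seed.
#' @param phase optional precomputed phase matrix (markers x progeny).
#' @return list of class \code{"Ordering"}: \code{markers} (ordered ids),
#'   \code{count}, \code{adjacent_dco}, \code{parent}, \code{bins}.
#' @export
orderRecord <- function(markers, table = NULL, parent = NULL, restarts = 20,
                        seed = 1L, phase = NULL) {
  if (is.null(phase)) phase <- .phaseMatrix(table, parent, markers)
  phase <- phase[markers, , drop = FALSE]
  if (nrow(phase) < 2L) stop("need >= 2 markers to order")
  cb <- .collapseBins(phase)
  reps <- rownames(cb$phase)
  m <- length(reps)
  set.seed(seed)
  complete <- !anyNA(cb$phase)
  D <- if (complete) .recombCountMatrix(cb$phase) else NULL
  evalOrd <- function(idx) {
    if (complete) sum(D[cbind(idx[-length(idx)], idx[-1L])])
    else .countObjective(cb$phase, idx)
  }
  best <- NULL; bestCount <- Inf; bestKey <- NULL
  for (r in seq_len(max(1L, restarts))) {
    insOrder <- if (m > 1L) sample.int(m) else 1L
    ord <- insOrder[1L]
    for (x in insOrder[-1L]) {
      cand <- lapply(seq_len(length(ord) + 1L), function(p) append(ord, x, p - 1L))
      costs <- vapply(cand, evalOrd, numeric(1))
      ord <- cand[[which.min(costs)]]
    }
    cnt <- evalOrd(ord)
    ids <- .canonicalOrder(reps[ord])
    key <- paste(ids, collapse = "\r")
    if (cnt < bestCount || (cnt == bestCount && key < bestKey)) {
      bestCount <- cnt; best <- ids; bestKey <- key
    }
  }
  full <- .expandBins(best, cb$bins)
  structure(list(markers = full, count = .countObjective(phase, full),
                 adjacent_dco = countAdjacentDco(full, phase = phase),
                 parent = parent, bins = cb$bins), class = "Ordering")
}

#' Count adjacent double crossovers under an ordering
#'
#' For each progeny the phase sequence over its called markers is scanned
#' for interior runs of length one: a single marker whose phase differs
#' from both flanking called markers while those flanks agree. Such
#' singletons imply two crossovers in adjacent intervals — biologically
#' implausible under strong interference, and the signature of a
#' genotyping error. Terminal flips are single crossovers, not DCOs.
#'
#' @param ordering an \code{"Ordering"} or a character vector of marker ids.
#' @param table,parent source of phases when \code{phase} is not given.
#' @param phase optional phase matrix (markers x progeny).
#' @return total count across progeny.
#' @export
countAdjacentDco <- function(ordering, table = NULL, parent = NULL,
                             phase = NULL) {
  ids <- if (inherits(ordering, "Ordering")) ordering$markers else ordering
  if (is.null(phase)) phase <- .phaseMatrix(table, parent, ids)
  M <- phase[ids, , drop = FALSE]
  sum(vapply(seq_len(ncol(M)), function(j) {
    v <- M[, j]; v <- v[!is.na(v)]
    n <- length(v)
    if (n < 3L) return(0L)
    mid <- 2:(n - 1L)
    sum(v[mid] != v[mid - 1L] & v[mid] != v[mid + 1L] &
          v[mid - 1L] == v[mid + 1L])
  }, integer(1)))
}

# positions (marker, progeny) of adjacent-DCO singleton genotypes
.dcoSingletons <- function(M) {
  out <- matrix(FALSE, nrow(M), ncol(M), dimnames = dimnames(M))
  for (j in seq_len(ncol(M))) {
    idx <- which(!is.na(M[, j]))
    if (length(idx) < 3L) next
    v <- M[idx, j]
    mid <- 2:(length(v) - 1L)
    hit <- mid[v[mid] != v[mid - 1L] & v[mid] != v[mid + 1L] &
                 v[mid - 1L] == v[mid + 1L]]
    out[idx[hit], j] <- TRUE
  }
  out
}

#' Refine an ordering by windowed permutation (ripple)
#'
#' Slides a window across the order and tries every permutation within it,
#' accepting the first that strictly reduces the pair
#' (adjacent DCO count, COUNT) in lexicographic order. When a full window
#' pass stalls, a relocation pass removes each marker in turn and tries
#' reinserting it at every position — the move that repairs a marker
#' misplaced beyond the window's reach, whose wrong placement is what
#' manufactures adjacent DCOs in the first place. Passes alternate until a
#' fixed point. The returned ordering is never worse than the input, and
#' with \code{window} equal to the number of markers the window search is
#' exhaustive.
#'
#' @param ordering an \code{"Ordering"} (or character vector of marker ids).
#' @param table,parent,phase phase source as in \code{\link{orderRecord}}.
#' @param window window width (default 5).
#' @return refined \code{"Ordering"}.
#' @export
rippleRefine <- function(ordering, table = NULL, parent = NULL, window = 5,
                         phase = NULL) {
  ids <- if (inherits(ordering, "Ordering")) ordering$markers else ordering
  if (is.null(phase)) phase <- .phaseMatrix(table, parent, ids)
  m <- length(ids)
  w <- min(window, m)
  perms <- .permutations(w)
  obj <- function(o) c(countAdjacentDco(o, phase = phase),
                       .countObjective(phase, o))
  cur <- ids
  curObj <- obj(cur)
  better <- function(co) co[1] < curObj[1] ||
    (co[1] == curObj[1] && co[2] < curObj[2])
  windowPass <- function() {
    for (s in seq_len(m - w + 1L)) {
      for (p in seq_len(nrow(perms))[-1L]) {
        cand <- cur
        cand[s:(s + w - 1L)] <- cur[s - 1L + perms[p, ]]
        co <- obj(cand)
        if (better(co)) {
          cur <<- cand; curObj <<- co
          return(TRUE)
        }
      }
    }
    FALSE
  }
  insertPass <- function() {
    for (i in seq_len(m)) {
      rest <- cur[-i]
      for (p in seq_len(m)) {
        if (p == i) next
        cand <- append(rest, cur[i], after = p - 1L)
        co <- obj(cand)
        if (better(co)) {
          cur <<- cand; curObj <<- co
          return(TRUE)
        }
      }
    }
    FALSE
  }
  repeat {
    if (!windowPass() && !insertPass()) break
  }
  structure(list(markers = cur, count = curObj[2], adjacent_dco = curObj[1],
                 parent = if (inherits(ordering, "Ordering"))
                   ordering$parent else parent,
                 bins = if (inherits(ordering, "Ordering"))
                   ordering$bins else NULL),
            class = "Ordering")
}

#' Compute map distances for an ordered linkage group
#'
#' Interval recombination fractions are recombinants over informative
#' (doubly called) progeny. With \code{excludeAdjacentDco} (the default)
#' each adjacent-DCO singleton genotype is masked — treated as missing —
#' before interval counting, so a suspected genotyping error contributes no
#' recombination to either flanking interval. Distances are 100 r
#' (\code{"morgan"}, the default: DCO exclusion already imposes
#' near-complete interference) or the Haldane / Kosambi transforms.
#'
#' @param ordering an \code{"Ordering"} or character vector of marker ids.
#' @param table,parent,phase phase source as in \code{\link{orderRecord}}.
#' @param excludeAdjacentDco mask singleton DCO genotypes (default TRUE).
#' @param mapFunction \code{"morgan"}, \code{"haldane"} or \code{"kosambi"}.
#' @return data.frame of class \code{"GeneticMap"}: rank, marker,
#'   interval_cM, cumulative_cM, r_hat, n_informative; total length in
#'   \code{attr(, "length_cM")}.
#' @export
computeMap <- function(ordering, table = NULL, parent = NULL,
                       excludeAdjacentDco = TRUE,
                       mapFunction = c("morgan", "haldane", "kosambi"),
                       phase = NULL) {
  mapFunction <- match.arg(mapFunction)
  ids <- if (inherits(ordering, "Ordering")) ordering$markers else ordering
  if (is.null(phase)) phase <- .phaseMatrix(table, parent, ids)
  M <- phase[ids, , drop = FALSE]
  if (excludeAdjacentDco) M[.dcoSingletons(M)] <- NA_integer_
  m <- length(ids)
  r <- nInf <- numeric(max(m - 1L, 0L))
  for (i in seq_len(m - 1L)) {
    ok <- !is.na(M[i, ]) & !is.na(M[i + 1L, ])
    nInf[i] <- sum(ok)
    if (nInf[i] == 0L) {
      warning(sprintf("interval %s-%s has no informative meioses; distance 0",
                      ids[i], ids[i + 1L]))
      r[i] <- 0
    } else r[i] <- sum(M[i, ok] != M[i + 1L, ok]) / nInf[i]
  }
  d <- switch(mapFunction,
              morgan = 100 * r,
              haldane = ifelse(r >= 0.5, Inf, -50 * log(1 - 2 * r)),
              kosambi = ifelse(r >= 0.5, Inf,
                               25 * log((1 + 2 * r) / (1 - 2 * r))))
  out <- data.frame(rank = seq_len(m), marker = ids,
                    interval_cM = c(0, d), cumulative_cM = cumsum(c(0, d)),
                    r_hat = c(NA, r), n_informative = c(NA, nInf),
                    stringsAsFactors = FALSE)
  attr(out, "length_cM") <- sum(d)
  attr(out, "map_function") <- mapFunction
  class(out) <- c("GeneticMap", "data.frame")
  out
}
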