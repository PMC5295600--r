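#' QC configuration for marker filtering
#'
#' @param minCalledFraction minimum fraction of progeny with called
#'   genotypes (default 75/85, the panel's published cutoff).
#' @param gThreshold G-statistic cutoff for segregation distortion
#'   (default 6.693, P < 0.01 at 1 df).
#' @param requireParents drop markers with a missing parental genotype
#'   (default TRUE).
#' @param psvStrictness fraction of called progeny that must be
#'   heterozygous for a double-het marker to be called a PSV (default 1:
#'   all of them).
#' @return A validated list of class \code{"QCConfig"}.
#' @export
qcConfig <- function(minCalledFraction = 75 / 85, gThreshold = 6.693,
                     requireParents = TRUE, psvStrictness = 1.0) {
  stopifnot(minCalledFraction > 0, minCalledFraction <= 1,
            gThreshold > 0, psvStrictness > 0, psvStrictness <= 1)
  structure(list(minCalledFraction = minCalledFraction,
                 gThreshold = gThreshold, requireParents = requireParents,
                 psvStrictness = psvStrictness), class = "QCConfig")
}

#' G-test for 1:1 segregation
#'
#' Likelihood-ratio (G) statistic for the transmitted allele counts of an
#' informative parent against the Mendelian 1:1 expectation:
#' G = 2[a ln(2a/(a+b)) + b ln(2b/(a+b))], with 0 ln 0 = 0; 1 df.
#'
#' @param countA,countB transmitted counts of the two parental alleles.
#' @return The G statistic (numeric).
#' @examples
#' gTestSegregation(40, 40)  # 0
#' gTestSegregation(60, 25)  # ~14.85, past the 6.693 cutoff
#' @export
gTestSegregation <- function(countA, countB) {
  if (countA < 0 || countB < 0) stop("counts must be non-negative")
  n <- countA + countB
  if (n == 0) stop("countA + countB must be > 0")
  term <- function(x) if (x == 0) 0 else x * log(2 * x / n)
  2 * (term(countA) + term(countB))
}

# informative allele counts for the distortion test:
#  - single-het markers: transmitted-allele counts among called progeny
#  - DH markers: counts of the two homozygote classes (the phase-resolvable
#    progeny); identical for both parents
#  - PSV / uninformative: no 1:1 expectation, NA
.segCounts <- function(pf, pm, progeny) {
  hetF <- .isHet(pf); hetM <- .isHet(pm)
  called <- progeny[!.isMissing(progeny)]
  if (hetF && hetM) {
    al <- strsplit(pf, "")[[1]]
    hom <- called[substr(called, 1, 1) == substr(called, 2, 2)]
    c(sum(substr(hom, 1, 1) == al[1]), sum(substr(hom, 1, 1) == al[2]))
  } else if (xor(hetF, hetM)) {
    het <- if (hetF) pf else pm
    oth <- if (hetF) pm else pf
    al <- strsplit(het, "")[[1]]
    tr <- vapply(called, .transmitted, character(1),
                 hetAlleles = al, otherGeno = oth)
    c(sum(tr == al[1], na.rm = TRUE), sum(tr == al[2], na.rm = TRUE))
  } else c(NA_integer_, NA_integer_)
}

#' Classify a marker's cross type
#'
#' A marker heterozygous in exactly one parent is maternal- or
#' paternal-informative; heterozygous in both parents it is a
#' double-heterozygote (DH), unless at least \code{psvStrictness} of the
#' called progeny are also heterozygous, in which case it is a PSV (a
#' collapsed duplicated locus appearing heterozygous in every individual);
#' homozygous in both parents it is uninformative.
#'
#' @param parentF,parentM parental genotype strings.
#' @param progeny character vector of progeny genotypes.
#' @param cfg a \code{\link{qcConfig}}.
#' @return list with \code{cross_type}, \code{g_stat}, \code{n_called},
#'   \code{counts} (informative allele counts), \code{mendel_inconsistent}
#'   (count of progeny carrying an allele absent from both parents) and
#'   \code{flags}.
#' @export
classifyMarker <- function(parentF, parentM, progeny, cfg = qcConfig()) {
  parentF <- .normGeno(parentF); parentM <- .normGeno(parentM)
  progeny <- vapply(progeny, .normGeno, character(1))
  flags <- character()
  if (.isMissing(parentF) || .isMissing(parentM)) flags <- c(flags, "parent_missing")
  called <- progeny[!.isMissing(progeny)]
  nCalled <- length(called)
  hetF <- .isHet(parentF); hetM <- .isHet(parentM)
  parAl <- unique(c(strsplit(parentF, "")[[1]], strsplit(parentM, "")[[1]]))
  parAl <- setdiff(parAl, "-")
  mendel <- sum(vapply(called, function(g)
    !all(strsplit(g, "")[[1]] %in% parAl), logical(1)))
  if (mendel > 0) flags <- c(flags, "mendel_inconsistent")
  crossType <-
    if (.isMissing(parentF) || .isMissing(parentM)) "uninformative"
    else if (hetF && !hetM) "maternal_informative"
    else if (!hetF && hetM) "paternal_informative"
    else if (hetF && hetM) {
      hetFrac <- if (nCalled) mean(.isHet(called)) else 0
      if (nCalled > 0 && hetFrac >= cfg$psvStrictness) "psv" else "double_het"
    } else "uninformative"
  counts <- if (crossType %in% c("maternal_informative",
                                 "paternal_informative", "double_het"))
    .segCounts(parentF, parentM, progeny) else c(NA_integer_, NA_integer_)
  g <- if (!any(is.na(counts)) && sum(counts) > 0)
    gTestSegregation(counts[1], counts[2]) else NA_real_
  if (!is.na(g) && g > cfg$gThreshold) flags <- c(flags, "distorted")
  list(cross_type = crossType, g_stat = g, n_called = nCalled,
       counts = counts, mendel_inconsistent = mendel, flags = flags)
}

#' Classify every marker in a table
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param cfg a \code{\link{qcConfig}}.
#' @return data.frame with one row per marker: marker, cross_type, g_stat,
#'   n_called, count_a, count_b, mendel_inconsistent, flags
#'   (comma-separated).
#' @export
classifyMarkers <- function(table, cfg = qcConfig()) {
  ids <- markerIds(table)
  g <- progenyGenotypes(table)
  pf <- parentGenotypes(table, "female")
  pm <- parentGenotypes(table, "male")
  rows <- lapply(seq_along(ids), function(i) {
    cl <- classifyMarker(pf[i], pm[i], g[i, ], cfg)
    data.frame(marker = ids[i], cross_type = cl$cross_type,
               g_stat = cl$g_stat, n_called = cl$n_called,
               count_a = cl$counts[1], count_b = cl$counts[2],
               mendel_inconsistent = cl$mendel_inconsistent,
               flags = paste(cl$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter markers by call rate, parental completeness and distortion
#'
#' Filters are applied in a fixed order — progeny call fraction, then
#' parental genotypes, then segregation distortion — and each marker is
#' attributed to the first filter it fails. Filtering is idempotent.
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param cfg a \code{\link{qcConfig}}.
#' @param classes optional precomputed \code{\link{classifyMarkers}} output.
#' @return list with \code{table} (retained \linkS4class{GenotypeTable}),
#'   \code{report} (per-marker data.frame with \code{dropped} and
#'   \code{reason}) and \code{counts} (drops per filter).
#' @export
filterMarkers <- function(table, cfg = qcConfig(), classes = NULL) {
  if (is.null(classes)) classes <- classifyMarkers(table, cfg)
  n <- nProgeny(table)
  lowCall <- classes$n_called / n < cfg$minCalledFraction
  parentMissing <- grepl("parent_missing", classes$flags) & cfg$requireParents
  distorted <- grepl("distorted", classes$flags)
  reason <- rep("", nrow(classes))
  reason[distorted] <- "distorted"
  reason[parentMissing] <- "parent_missing"
  reason[lowCall] <- "low_call"           # order: calls -> parents -> distortion
  dropped <- reason != ""
  report <- cbind(classes, dropped = dropped, reason = reason,
                  stringsAsFactors = FALSE)
  keep <- classes$marker[!dropped]
  if (!length(keep)) warning("all markers removed by QC filters")
  list(table = table[keep], report = report,
       counts = c(low_call = sum(reason == "low_call"),
                  parent_missing = sum(reason == "parent_missing"),
                  distorted = sum(reason == "distorted"),
                  retained = length(keep)))
}
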