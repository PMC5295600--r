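#' Build a simulated genome model
#'
#' Lays out evenly spaced markers on a set of linkage groups, each anchored
#' to one reference chromosome arm with base-pair positions proportional to
#' the genetic position. Homeologous group pairs (descendants of a common
#' pre-duplication ancestor) are declared here; paired groups share the same
#' marker layout so a homeologous exchange has a positional counterpart on
#' the partner arm.
#'
#' @param nLg number of linkage groups (>= 1).
#' @param markersPerLg markers per group (>= 1).
#' @param spacingCM genetic spacing between adjacent markers (> 0); marker i
#'   sits at (i-1) * spacingCM.
#' @param armLengthBp physical length of each reference arm in bp.
#' @param homeologPairs list of length-2 character vectors of lg ids (e.g.
#'   \code{list(c("LG01","LG02"))}), or NULL.
#' @param seed kept for interface symmetry; the layout is deterministic.
#' @return A \linkS4class{GenomeModel}.
#' @examples
#' m <- buildGenomeModel(nLg = 2, markersPerLg = 10, spacingCM = 5)
#' max(m@markers$pos_cM)  # 45
#' @export
buildGenomeModel <- function(nLg = 2L, markersPerLg = 10L, spacingCM = 5,
                             armLengthBp = 5e7, homeologPairs = NULL,
                             seed = 1L) {
  if (nLg < 1L || markersPerLg < 1L)
    stop("configuration error: need >= 1 linkage group and >= 1 marker")
  if (spacingCM <= 0) stop("configuration error: marker spacing must be > 0")
  lgs <- sprintf("LG%02d", seq_len(nLg))
  arms <- data.frame(arm_id = sprintf("ARM%02d", seq_len(nLg)),
                     chrom = sprintf("chr%02d", seq_len(nLg)),
                     start = 1, end = armLengthBp,
                     centromere_side = "low", stringsAsFactors = FALSE)
  pos <- (seq_len(markersPerLg) - 1L) * spacingCM
  maxPos <- max(pos)
  # keep a 64 bp tag footprint inside the arm at the telomeric end
  bp <- if (maxPos > 0) 1 + round(pos / maxPos * (armLengthBp - 64)) else
    rep(round(armLengthBp / 2), markersPerLg)
  markers <- do.call(rbind, lapply(seq_len(nLg), function(i) {
    data.frame(lg = lgs[i],
               marker = sprintf("%s_M%02d", lgs[i], seq_len(markersPerLg)),
               pos_cM = pos, arm = arms$arm_id[i], bp = bp,
               stringsAsFactors = FALSE)
  }))
  hp <- if (is.null(homeologPairs))
    data.frame(lg_a = character(), lg_b = character(),
               stringsAsFactors = FALSE)
  else
    data.frame(lg_a = vapply(homeologPairs, `[`, "", 1),
               lg_b = vapply(homeologPairs, `[`, "", 2),
               stringsAsFactors = FALSE)
  new("GenomeModel", markers = markers, homeologPairs = hp, arms = arms)
}

#' Simulate one meiosis
#'
#' Draws the transmitted phase (0/1) at every marker for a single gamete.
#' Within a linkage group, recombination between adjacent markers occurs
#' with probability equal to the interval length in Morgans; under the
#' default \code{"dco_suppression"} interference model a crossover in
#' interval i forbids one in interval i+1 (adjacent double crossovers are
#' biologically implausible under the strong chromatid interference of
#' salmonid meiosis). With probability \code{multivalentProb} per homeolog
#' pair, a multivalent forms: an exchange point is drawn uniformly in the
#' distal \code{telomereBias} fraction of the arm and the phases of markers
#' distal to it become coupled between the partner groups. Only balanced
#' disjunction products are assumed to yield viable gametes, so
#' \code{"preferential"} (alternate) disjunction anti-couples the distal
#' phases (nonparental excess) while \code{"random"} pairing couples them
#' (parental excess).
#'
#' @param model a \linkS4class{GenomeModel}.
#' @param cfg a \linkS4class{SimConfig} (only the meiosis-model fields are
#'   used; the caller controls the RNG state).
#' @return list with \code{phases} (named integer 0/1 vector over markers),
#'   \code{crossovers} (data.frame lg, interval) and \code{events}
#'   (data.frame lg_a, lg_b, exchange_rel).
#' @export
simulateMeiosis <- function(model, cfg) {
  mk <- model@markers
  phases <- integer(nrow(mk))
  names(phases) <- mk$marker
  xo <- list()
  for (lg in unique(mk$lg)) {
    idx <- which(mk$lg == lg)
    pos <- mk$pos_cM[idx]
    n <- length(idx)
    ph <- integer(n)
    ph[1] <- sample(0:1, 1L)
    suppressed <- FALSE
    for (j in seq_len(n - 1L)) {
      r <- min((pos[j + 1L] - pos[j]) / 100, 0.5)
      if (cfg@interference == "dco_suppression" && suppressed) {
        co <- FALSE
        suppressed <- FALSE
      } else {
        co <- stats::runif(1) < r
        if (co && cfg@interference == "dco_suppression") suppressed <- TRUE
      }
      if (co) xo[[length(xo) + 1L]] <- data.frame(lg = lg, interval = j)
      ph[j + 1L] <- if (co) 1L - ph[j] else ph[j]
    }
    phases[idx] <- ph
  }
  events <- data.frame(lg_a = character(), lg_b = character(),
                       exchange_rel = numeric(), stringsAsFactors = FALSE)
  hp <- model@homeologPairs
  arms <- model@arms
  for (p in seq_len(nrow(hp))) {
    if (cfg@multivalentProb <= 0 || stats::runif(1) >= cfg@multivalentProb)
      next
    u <- stats::runif(1, 1 - cfg@telomereBias, 1)
    ia <- which(mk$lg == hp$lg_a[p])
    ib <- which(mk$lg == hp$lg_b[p])
    armA <- arms[match(mk$arm[ia[1]], arms$arm_id), ]
    len <- armA$end - armA$start + 1
    rel <- (mk$bp[ia] - armA$start + 1) / len
    if (armA$centromere_side == "high") rel <- 1 - rel + 1 / len
    aff <- which(rel > u)
    if (length(aff)) {
      if (cfg@disjunctionMode == "preferential")
        phases[ib[aff]] <- 1L - phases[ia[aff]]
      else
        phases[ib[aff]] <- phases[ia[aff]]
    }
    events <- rbind(events, data.frame(lg_a = hp$lg_a[p], lg_b = hp$lg_b[p],
                                       exchange_rel = u,
                                       stringsAsFactors = FALSE))
  }
  crossovers <- if (length(xo)) do.call(rbind, xo) else
    data.frame(lg = character(), interval = integer())
  list(phases = phases, crossovers = crossovers, events = events)
}

#' Simulate a full F1 family with ground truth
#'
#' Generates parental and progeny genotypes for all mapped markers plus a
#' configurable number of PSV loci (collapsed duplicated loci, heterozygous
#' in both parents and every progeny). Cross types are drawn per marker
#' (maternal-informative, paternal-informative, or double-heterozygote, in
#' the configured proportions); genotyping error is applied as random genotype
#' replacement, missingness as masking, and transmission distortion by
#' resampling the informative parent's transmitted allele at the configured
#' ratio.
#'
#' @param model a \linkS4class{GenomeModel}.
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with \code{table} (a \linkS4class{GenotypeTable}) and
#'   \code{truth} (a \linkS4class{TruthSet}).
#' @export
simulateFamily <- function(model, cfg) {
  set.seed(cfg@seed)
  mk <- model@markers
  nM <- nrow(mk)
  nP <- cfg@nProgeny
  progIds <- sprintf("progeny_%d", seq_len(nP))

  crossType <- sample(c("female", "male", "dh"), nM, replace = TRUE,
                      prob = cfg@crossTypeProbs)
  alleles <- t(vapply(seq_len(nM), function(i)
    sample(c("A", "C", "G", "T"), 2L), character(2)))
  pf <- pm <- character(nM)
  for (i in seq_len(nM)) {
    het <- paste(sort(alleles[i, ]), collapse = "")
    hom <- function() paste(rep(sample(alleles[i, ], 1L), 2), collapse = "")
    if (crossType[i] == "female") { pf[i] <- het; pm[i] <- hom() }
    else if (crossType[i] == "male") { pf[i] <- hom(); pm[i] <- het }
    else { pf[i] <- het; pm[i] <- het }
  }
  # phase-0/1 allele mapping per parent: phase k carries sorted allele k+1
  # for het parents; hom parents transmit their single allele regardless.
  sortedAl <- t(apply(alleles, 1, sort))

  phF <- matrix(0L, nM, nP, dimnames = list(mk$marker, progIds))
  phM <- matrix(0L, nM, nP, dimnames = list(mk$marker, progIds))
  events <- list()
  for (j in seq_len(nP)) {
    gf <- simulateMeiosis(model, cfg)
    gm <- simulateMeiosis(model, cfg)
    phF[, j] <- gf$phases
    phM[, j] <- gm$phases
    for (e in list(c(gf$events, parent = "female"),
                   c(gm$events, parent = "male"))) {
      ev <- as.data.frame(e[c("lg_a", "lg_b", "exchange_rel")])
      if (nrow(ev)) {
        ev$parent <- e$parent
        ev$progeny <- progIds[j]
        events[[length(events) + 1L]] <- ev
      }
    }
  }
  tetra <- if (length(events)) do.call(rbind, events) else
    data.frame(lg_a = character(), lg_b = character(),
               exchange_rel = numeric(), parent = character(),
               progeny = character(), stringsAsFactors = FALSE)

  # transmission distortion: resample the informative parent's phase
  distorted <- character()
  dl <- cfg@distortionLoci
  for (d in seq_len(nrow(dl))) {
    i <- match(dl$marker[d], mk$marker)
    if (is.na(i)) next
    p0 <- dl$ratio[d] / (1 + dl$ratio[d])
    draw <- function() as.integer(stats::runif(nP) >= p0)
    if (crossType[i] %in% c("female", "dh")) phF[i, ] <- draw()
    if (crossType[i] %in% c("male", "dh")) phM[i, ] <- draw()
    distorted <- c(distorted, dl$marker[d])
  }

  transmit <- function(i, phase, parent) {
    geno <- if (parent == "female") pf[i] else pm[i]
    al <- strsplit(geno, "")[[1]]
    if (al[1] == al[2]) rep(al[1], length(phase)) else
      sort(al)[phase + 1L]
  }
  geno <- matrix("--", nM, nP, dimnames = list(mk$marker, progIds))
  for (i in seq_len(nM)) {
    a <- transmit(i, phF[i, ], "female")
    b <- transmit(i, phM[i, ], "male")
    geno[i, ] <- ifelse(a <= b, paste0(a, b), paste0(b, a))
  }

  # PSV loci: fixed heterozygotes placed on homeolog pairs (or single arms)
  nPsv <- round(cfg@psvFraction * nM)
  psvIds <- character(0)
  psvTruth <- data.frame(marker = character(), arm_a = character(),
                         bp_a = numeric(), arm_b = character(),
                         bp_b = numeric(), stringsAsFactors = FALSE)
  if (nPsv > 0) {
    psvIds <- sprintf("PSV%03d", seq_len(nPsv))
    hp <- model@homeologPairs
    arms <- model@arms
    lgArm <- tapply(mk$arm, mk$lg, function(x) x[1])
    for (k in seq_len(nPsv)) {
      if (nrow(hp)) {
        p <- ((k - 1L) %% nrow(hp)) + 1L
        armA <- lgArm[[hp$lg_a[p]]]
        armB <- lgArm[[hp$lg_b[p]]]
      } else {
        armA <- arms$arm_id[((k - 1L) %% nrow(arms)) + 1L]
        armB <- NA_character_
      }
      aDef <- arms[match(armA, arms$arm_id), ]
      len <- aDef$end - aDef$start + 1
      rel <- if (cfg@psvPlacement == "telomeric")
        stats::runif(1, 0.75, 1) else stats::runif(1)
      # ceiling keeps the hit at or beyond the drawn relative position so
      # telomeric draws stay in the distal quarter; cap fits the 64 bp tag
      off <- min(ceiling(rel * len), len - 63)
      bp <- aDef$start + off - 1
      psvTruth <- rbind(psvTruth, data.frame(
        marker = psvIds[k], arm_a = armA, bp_a = bp,
        arm_b = armB, bp_b = bp, stringsAsFactors = FALSE))
    }
    psvAl <- t(vapply(seq_len(nPsv), function(i)
      sort(sample(c("A", "C", "G", "T"), 2L)), character(2)))
    psvGeno <- paste0(psvAl[, 1], psvAl[, 2])
    geno <- rbind(geno, matrix(rep(psvGeno, nP), nPsv, nP,
                               dimnames = list(psvIds, progIds)))
    pf <- c(pf, psvGeno)
    pm <- c(pm, psvGeno)
  }

  # genotyping error: replace with a uniform draw from the genotypes the
  # cross can produce
  if (cfg@errorRate > 0) {
    possible <- lapply(seq_len(nrow(geno)), function(i) {
      af <- strsplit(pf[i], "")[[1]]
      am <- strsplit(pm[i], "")[[1]]
      unique(vapply(1:2, function(x) vapply(1:2, function(y) {
        a <- sort(c(af[x], am[y])); paste(a, collapse = "")
      }, character(1)), character(2)))
    })
    err <- matrix(stats::runif(length(geno)) < cfg@errorRate, nrow(geno))
    for (i in seq_len(nrow(geno))) {
      w <- which(err[i, ])
      if (length(w))
        geno[i, w] <- sample(possible[[i]], length(w), replace = TRUE)
    }
  }
  if (cfg@missingRate > 0) {
    miss <- matrix(stats::runif(length(geno)) < cfg@missingRate, nrow(geno))
    geno[miss] <- "--"
  }

  table <- GenotypeTable(geno, pf, pm)
  alDf <- rbind(
    data.frame(marker = mk$marker, parent = "female",
               allele0 = sortedAl[, 1], allele1 = sortedAl[, 2],
               stringsAsFactors = FALSE),
    data.frame(marker = mk$marker, parent = "male",
               allele0 = sortedAl[, 1], allele1 = sortedAl[, 2],
               stringsAsFactors = FALSE))
  truth <- new("TruthSet", trueMap = mk,
               phases = list(female = phF, male = phM),
               psvMarkers = psvIds, distortedMarkers = distorted,
               tetrasomyEvents = tetra, alleles = alDf, psvTruth = psvTruth)
  list(table = table, truth = truth)
}

.fmtEvalue <- function(x) formatC(x, format = "e", digits = 2)

#' Emit reference-genome and TE hit tables for a simulated family
#'
#' Produces the 12-column tabular alignment layout (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore; 1-based inclusive coordinates). Every
#' mapped marker receives one top hit at its true arm and position (plus
#' optional Gaussian bp noise); each PSV receives hits on both arms of its
#' homeolog pair with exactly tied e-value strings with probability
#' \code{pDouble}. A \code{teFraction} of markers also receive TE-table rows.
#'
#' @param model a \linkS4class{GenomeModel}.
#' @param truth the \linkS4class{TruthSet} from \code{\link{simulateFamily}}.
#' @param cfg the \linkS4class{SimConfig} used for the family.
#' @return list with \code{hits} and \code{te} data.frames (e-values kept as
#'   printed strings in column \code{evalue}).
#' @export
emitHitTables <- function(model, truth, cfg) {
  set.seed(cfg@seed + 104729L)  # independent stream from the family draw
  arms <- model@arms
  mk <- truth@trueMap
  mkArm <- arms[match(mk$arm, arms$arm_id), ]
  row1 <- function(q, armRow, bp, ev) {
    pid <- round(stats::runif(1, 96, 100), 2)
    sstart <- max(armRow$start,
                  min(armRow$end - 63, round(bp +
                    if (cfg@hitNoiseBp > 0) stats::rnorm(1, 0, cfg@hitNoiseBp)
                    else 0)))
    data.frame(qseqid = q, sseqid = armRow$chrom, pident = pid, length = 64L,
               mismatch = round((100 - pid) * 64 / 100), gapopen = 0L,
               qstart = 1L, qend = 64L, sstart = sstart, send = sstart + 63L,
               evalue = ev, bitscore = round(stats::runif(1, 80, 120), 1),
               stringsAsFactors = FALSE)
  }
  hits <- vector("list", nrow(mk))
  for (i in seq_len(nrow(mk))) {
    ev <- .fmtEvalue(10^stats::rnorm(1, cfg@log10EvalueMean,
                                     cfg@log10EvalueSd))
    hits[[i]] <- row1(mk$marker[i], mkArm[i, ], mk$bp[i], ev)
  }
  pt <- truth@psvTruth
  for (i in seq_len(nrow(pt))) {
    ev <- .fmtEvalue(10^stats::rnorm(1, cfg@log10EvalueMean,
                                     cfg@log10EvalueSd))
    armA <- arms[match(pt$arm_a[i], arms$arm_id), ]
    hits[[length(hits) + 1L]] <- row1(pt$marker[i], armA, pt$bp_a[i], ev)
    if (!is.na(pt$arm_b[i]) && stats::runif(1) < cfg@pDouble) {
      armB <- arms[match(pt$arm_b[i], arms$arm_id), ]
      # tie created by duplicating the printed e-value exactly
      hits[[length(hits) + 1L]] <- row1(pt$marker[i], armB, pt$bp_b[i], ev)
    }
  }
  hits <- do.call(rbind, hits)

  allIds <- c(mk$marker, pt$marker)
  teIds <- allIds[stats::runif(length(allIds)) < cfg@teFraction]
  teFams <- c("DNA-TcMar-Tc1", "LINE-L2", "LTR-Gypsy", "SINE-tRNA",
              "DNA-hAT-Charlie")
  te <- if (length(teIds)) do.call(rbind, lapply(teIds, function(q) {
    pid <- round(stats::runif(1, 85, 100), 2)
    len <- sample(30:64, 1L)
    data.frame(qseqid = q, sseqid = sample(teFams, 1L), pident = pid,
               length = len, mismatch = round((100 - pid) * len / 100),
               gapopen = 0L, qstart = 1L, qend = len,
               sstart = 1L, send = len,
               evalue = .fmtEvalue(10^stats::rnorm(1, -12, 3)),
               bitscore = round(stats::runif(1, 40, 90), 1),
               stringsAsFactors = FALSE)
  })) else hits[0, ]
  list(hits = hits, te = te)
}

#' Read / write family genotype tables
#'
#' TSV layout: header row with columns \code{marker_id}, \code{parent_female},
#' \code{parent_male}, then one column per progeny; genotypes as two-character
#' allele strings, \code{"--"} for missing. Ragged rows, duplicate marker ids
#' and half-missing genotypes (e.g. \code{"A-"}) are parse errors naming the
#' offending line or id.
#'
#' @param path file path.
#' @return \code{readGenotypeTable}: a \linkS4class{GenotypeTable}.
#' @export
readGenotypeTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty genotype file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 4L ||
      !identical(header[1:3], c("marker_id", "parent_female", "parent_male")))
    stop("genotype table header must start with ",
         "marker_id, parent_female, parent_male")
  nc <- length(header)
  body <- fields[-1]
  lens <- lengths(body)
  if (any(lens != nc))
    stop(sprintf("ragged row at line %d (%d fields, expected %d)",
                 which(lens != nc)[1] + 1L, lens[lens != nc][1], nc))
  m <- do.call(rbind, body)
  ids <- m[, 1]
  if (anyDuplicated(ids))
    stop("duplicate marker ID: ", ids[duplicated(ids)][1])
  genos <- m[, -(1:3), drop = FALSE]
  all <- cbind(m[, 2:3, drop = FALSE], genos)
  bad <- matrix(!grepl(.VALID_GENO, all), nrow = nrow(all))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("malformed genotype '%s' at line %d", all[bad][1],
                 w[[1]] + 1L))
  }
  rownames(genos) <- ids
  colnames(genos) <- header[-(1:3)]
  GenotypeTable(genos, m[, 2], m[, 3])
}

#' @rdname readGenotypeTable
#' @param x a \linkS4class{GenotypeTable}.
#' @export
writeGenotypeTable <- function(x, path) {
  df <- data.frame(marker_id = markerIds(x),
                   parent_female = parentGenotypes(x, "female"),
                   parent_male = parentGenotypes(x, "male"),
                   progenyGenotypes(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write 12-column tabular alignment hit tables
#'
#' The layout is query, subject, percent identity, alignment length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore,
#' tab-separated without a header, coordinates 1-based inclusive. The
#' e-value is kept as its printed string (tie resolution compares strings
#' exactly) alongside a numeric copy.
#'
#' @param path file path.
#' @return \code{readHitTable}: data.frame with the 12 columns plus
#'   \code{evalue_num}.
#' @export
readHitTable <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          col.names = cols, stringsAsFactors = FALSE)
  for (nm in c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
               "sstart", "send", "bitscore"))
    df[[nm]] <- as.numeric(df[[nm]])
  df$evalue_num <- as.numeric(df$evalue)
  df
}

#' @rdname readHitTable
#' @param x a hit-table data.frame (as from \code{\link{emitHitTables}}).
#' @export
writeHitTable <- function(x, path) {
  x$evalue_num <- NULL
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write simulator ground truth as plain-text TSV files
#'
#' Writes \code{true_map.tsv}, \code{phases_female.tsv},
#' \code{phases_male.tsv}, \code{psv_markers.tsv} and
#' \code{tetrasomy_events.tsv} into \code{dir}.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param dir output directory (created if absent).
#' @export
writeTruthSet <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                         quote = FALSE, row.names = FALSE)
  w(truth@trueMap, "true_map.tsv")
  w(data.frame(marker = rownames(truth@phases$female),
               truth@phases$female, check.names = FALSE),
    "phases_female.tsv")
  w(data.frame(marker = rownames(truth@phases$male),
               truth@phases$male, check.names = FALSE), "phases_male.tsv")
  w(data.frame(marker = truth@psvMarkers), "psv_markers.tsv")
  w(truth@tetrasomyEvents, "tetrasomy_events.tsv")
  invisible(dir)
}
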