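# End-to-end orchestration: qc -> group -> order -> map -> pseudolink ->
# homeology, with a structured config, fixed seeds and a summary report.

.pipelineDefaults <- function() list(
  genotypes = NULL, hits = NULL, te = NULL, arms = NULL,
  whitelist = NULL, orientation = NULL,
  min_called_fraction = 75 / 85, g_threshold = 6.693,
  require_parents = TRUE, psv_strictness = 1.0,
  lod_threshold = 10, schedule = c(6, 5, 4, 3),
  ripple_window = 5, restarts = 20, map_function = "morgan",
  exclude_adjacent_dco = TRUE, lod_window = c(3, 5),
  tie_tol = 0, min_block = 3, seed = 1L, out_dir = NULL)

#' Validate a pipeline configuration
#'
#' Accepts a named list or the path of a YAML file; unknown keys are
#' rejected before any stage runs.
#'
#' @param config named list or YAML path.
#' @return validated config list with defaults filled in.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defs <- .pipelineDefaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defs, config)
  stopifnot(out$lod_threshold > 0, length(out$lod_window) == 2L)
  if (length(out$schedule) < 2L)
    warning("initial grouping uses the LOD threshold (",
            out$lod_threshold, ") regardless of the descent schedule")
  out
}

.writeStage <- function(df, outDir, name) {
  if (is.null(outDir)) return(invisible(NULL))
  utils::write.table(df, file.path(outDir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full mapping and diploidization pipeline
#'
#' Stages run in a fixed order: marker QC and classification; per-parent
#' two-point analysis, LOD-threshold grouping, descending-LOD assignment
#' with homeolog-gated merges, and DH-marker group assignment; RECORD
#' ordering, ripple refinement and DCO-masked map distances per group;
#' pseudolinkage scanning in the accepted LOD window; and, when hit tables
#' are supplied, top-hit resolution, quarter binning, category and quarter
#' tests, TE proportions and linkage-group composition calls. Each stage's
#' table is written to \code{out_dir} (when set) together with a run log
#' recording parameters and counts; identical configs give byte-identical
#' outputs.
#'
#' @param config a \code{\link{pipelineConfig}} list (or YAML path).
#'   Inputs may be objects (\linkS4class{GenotypeTable}, data.frames) or
#'   file paths.
#' @return report list (invisibly when writing to disk): per-stage tables
#'   plus a per-group summary with marker counts and cM lengths per parent,
#'   and the marker conservation accounting retained = ordered +
#'   group-assigned DH + PSV + unlinked.
#' @export
runPipeline <- function(config = list()) {
  cfg <- pipelineConfig(config)
  outDir <- cfg$out_dir
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  fail <- function(stage, msg) stop(sprintf("[%s] %s", stage, msg),
                                    call. = FALSE)
  log <- c(sprintf("seed\t%d", cfg$seed))
  note <- function(...) log <<- c(log, sprintf(...))

  # --- qc ---------------------------------------------------------------
  table <- cfg$genotypes
  if (is.character(table)) table <- readGenotypeTable(table)
  if (!methods::is(table, "GenotypeTable"))
    fail("qc", "config$genotypes must be a GenotypeTable or TSV path")
  qcc <- qcConfig(cfg$min_called_fraction, cfg$g_threshold,
                  cfg$require_parents, cfg$psv_strictness)
  classes <- classifyMarkers(table, qcc)
  flt <- filterMarkers(table, qcc, classes)
  table <- flt$table
  classes <- flt$report[!flt$report$dropped, ]
  note("qc\tretained\t%d", length(markerIds(table)))
  note("qc\tdropped_low_call\t%d", flt$counts[["low_call"]])
  note("qc\tdropped_parent_missing\t%d", flt$counts[["parent_missing"]])
  note("qc\tdropped_distorted\t%d", flt$counts[["distorted"]])
  .writeStage(flt$report, outDir, "qc_report.tsv")

  psv <- classes$marker[classes$cross_type == "psv"]
  dh <- classes$marker[classes$cross_type == "double_het"]
  report <- list(qc = flt$report, groups = list(), maps = list(),
                 pseudolinkage = list(), homeology = NULL)

  # --- per-parent grouping / ordering / mapping -------------------------
  perLg <- list()
  orderedCount <- 0L; dhAssigned <- character()
  for (parent in c("female", "male")) {
    want <- if (parent == "female") "maternal_informative" else
      "paternal_informative"
    inf <- classes$marker[classes$cross_type == want]
    if (length(inf) < 2L) next
    pairsInf <- twoPointAll(table, parent, markers = inf)
    grouping <- groupMarkers(pairsInf, cfg$lod_threshold, markers = inf)
    grouping <- descendingLodMerge(grouping, pairsInf,
                                   whitelist = cfg$whitelist,
                                   schedule = cfg$schedule)
    pairsAll <- if (length(dh)) twoPointAll(table, parent,
                                            markers = sort(c(inf, dh)))
      else pairsInf
    dhAssign <- if (length(dh))
      assignDhMarkers(grouping, pairsAll, dh, cfg$lod_threshold)
      else data.frame(marker = character(), group = character(),
                      lod = numeric())
    dhAssigned <- union(dhAssigned, dhAssign$marker[!is.na(dhAssign$group)])
    note("group\t%s\tgroups\t%d", parent, length(grouping$groups))
    .writeStage(grouping$joinLog, outDir,
                sprintf("join_log_%s.tsv", parent))
    report$groups[[parent]] <- list(grouping = grouping,
                                    dh_assignments = dhAssign,
                                    pairs = pairsInf)
    maps <- list()
    phase <- .phaseMatrix(table, parent, inf)
    for (gname in names(grouping$groups)) {
      mem <- intersect(grouping$groups[[gname]], inf)
      if (length(mem) < 2L) next
      ord <- orderRecord(mem, phase = phase[mem, , drop = FALSE],
                         parent = parent, restarts = cfg$restarts,
                         seed = cfg$seed)
      ord <- rippleRefine(ord, phase = phase[mem, , drop = FALSE],
                          window = cfg$ripple_window)
      map <- computeMap(ord, phase = phase[mem, , drop = FALSE],
                        excludeAdjacentDco = cfg$exclude_adjacent_dco,
                        mapFunction = cfg$map_function)
      maps[[gname]] <- map
      orderedCount <- orderedCount + nrow(map)
      perLg[[length(perLg) + 1L]] <- data.frame(
        group = gname, parent = parent, n_markers = nrow(map),
        length_cM = attr(map, "length_cM"),
        adjacent_dco = ord$adjacent_dco, stringsAsFactors = FALSE)
      .writeStage(map, outDir, sprintf("map_%s_%s.tsv", parent, gname))
    }
    report$maps[[parent]] <- maps

    if (!is.null(cfg$whitelist)) {
      calls <- detectPseudolinkage(table, parent, grouping, pairsAll,
                                   whitelist = cfg$whitelist,
                                   lodWindow = cfg$lod_window,
                                   orientation = cfg$orientation)
      report$pseudolinkage[[parent]] <- calls
      note("pseudolink\t%s\tcalls\t%d", parent, sum(calls$accepted))
      .writeStage(calls, outDir, sprintf("pseudolinkage_%s.tsv", parent))
    }
  }
  lgSummary <- if (length(perLg)) do.call(rbind, perLg) else
    data.frame(group = character(), parent = character(),
               n_markers = integer(), length_cM = numeric(),
               adjacent_dco = integer())
  report$lg_summary <- lgSummary
  .writeStage(lgSummary, outDir, "lg_summary.tsv")

  # --- homeology --------------------------------------------------------
  if (!is.null(cfg$hits) && !is.null(cfg$arms)) {
    hits <- cfg$hits
    if (is.character(hits)) hits <- readHitTable(hits)
    arms <- cfg$arms
    if (is.character(arms)) arms <- readArmTable(arms)
    kinds <- stats::setNames(
      ifelse(markerIds(table) %in% psv, "psv", "map_snp"), markerIds(table))
    res <- resolveTopHits(hits, arms, markerKinds = kinds,
                          tieTol = cfg$tie_tol)
    asg <- binQuarters(res$assignments, arms)
    hrta <- if (any(grepl("HRTA", arms$categories)))
      categoryContingency(asg, arms, "HRTA") else NULL
    qt <- quarterDistributionTest(asg)
    teRes <- NULL
    if (!is.null(cfg$te)) {
      te <- cfg$te
      if (is.character(te)) te <- readHitTable(te)
      hrtaArms <- .armsInCategory(arms, "HRTA")
      onHrta <- unique(asg$marker[asg$arm %in% hrtaArms])
      sets <- list(hrta_groups = intersect(markerIds(table), onHrta),
                   other_groups = setdiff(markerIds(table), onHrta))
      teRes <- teProportions(sets, te)
    }
    report$homeology <- list(assignments = asg, dropped = res$dropped,
                             hrta_test = hrta, quarter_test = qt,
                             te = teRes)
    note("homeology\tassigned\t%d", nrow(asg))
    .writeStage(asg, outDir, "arm_assignments.tsv")
  }

  # --- conservation accounting -----------------------------------------
  retained <- markerIds(table)
  informativeAll <- classes$marker[classes$cross_type %in%
    c("maternal_informative", "paternal_informative")]
  orderedMarkers <- unique(unlist(lapply(report$maps, function(mm)
    unlist(lapply(mm, function(m) m$marker)))))
  unlinked <- setdiff(retained, c(orderedMarkers, dhAssigned, psv))
  report$conservation <- list(
    retained = length(retained),
    ordered = length(orderedMarkers),
    dh_assigned = length(setdiff(dhAssigned, orderedMarkers)),
    psv = length(psv),
    unlinked = length(setdiff(unlinked, dhAssigned)))
  note("conservation\tretained\t%d\tordered\t%d\tdh\t%d\tpsv\t%d\tunlinked\t%d",
       report$conservation$retained, report$conservation$ordered,
       report$conservation$dh_assigned, report$conservation$psv,
       report$conservation$unlinked)
  # provenance: every effective parameter goes into the run log
  for (k in setdiff(names(cfg), c("genotypes", "hits", "te", "arms",
                                  "whitelist", "orientation", "out_dir")))
    note("param\t%s\t%s", k, paste(format(cfg[[k]]), collapse = ","))
  if (!is.null(outDir)) writeLines(log, file.path(outDir, "run_log.tsv"))
  report$log <- log
  if (is.null(outDir)) report else invisible(report)
}
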