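#' Pipeline configuration
#'
#' The pipeline is driven by a YAML file (or an equivalent named list)
#' with exactly one data source:
#'
#' * `simulation:` a block of [simulationConfig()] arguments in snake_case
#'   (`n_genes`, `replicates`, `library_size`, `nb_dispersion`,
#'   `frac_membrane_like`, `utr_len_logmean_by_class`, `utr_len_logsd`,
#'   `pars_mean_5utr_by_class`, `pars_mean_cds_by_class`, `pars_sd`,
#'   `cds_len`, `beta_structure_te`, `urea_te_boost_membrane_wt`); or
#' * `inputs:` paths `counts`, `samples`, and optionally `annotation`,
#'   `terms` (GMT), `labels` (gene_id/class TSV).
#'
#' Optional top-level keys: `seed` (default 1), `thresholds` (`tau`,
#' `min_count`, `pseudocount`, `fraction`, `q_cutoff`), `contrasts` (list
#' of `name` / `numerator` / `denominator` blocks; defaults to the four
#' standard strain-by-condition contrasts), and `polysome` (`trace` path,
#' `mono`, `poly` intervals, `baseline`).
#'
#' @name pipeline-config
NULL

.defaultThresholds <- list(
  tau = 1.5, min_count = 10, pseudocount = 0.5,
  fraction = 0.30, q_cutoff = 0.05
)

.defaultContrasts <- list(
  list(name = "urea_response_wt",
       numerator = list(strain = "WT", condition = "urea"),
       denominator = list(strain = "WT", condition = "SD")),
  list(name = "urea_response_ntd",
       numerator = list(strain = "ntd-del", condition = "urea"),
       denominator = list(strain = "ntd-del", condition = "SD")),
  list(name = "ntd_vs_wt_sd",
       numerator = list(strain = "ntd-del", condition = "SD"),
       denominator = list(strain = "WT", condition = "SD")),
  list(name = "ntd_vs_wt_urea",
       numerator = list(strain = "ntd-del", condition = "urea"),
       denominator = list(strain = "WT", condition = "urea"))
)

.simConfigFromList <- function(block, seed) {
  argMap <- c(
    n_genes = "nGenes", replicates = "replicates",
    library_size = "librarySize", nb_dispersion = "nbDispersion",
    frac_membrane_like = "fracMembraneLike",
    utr_len_logmean_by_class = "utrLenLogmeanByClass",
    utr_len_logsd = "utrLenLogsd",
    pars_mean_5utr_by_class = "parsMean5utrByClass",
    pars_mean_cds_by_class = "parsMeanCdsByClass",
    pars_sd = "parsSd", cds_len = "cdsLen",
    beta_structure_te = "betaStructureTE",
    urea_te_boost_membrane_wt = "ureaTeBoostMembraneWT",
    seed = "seed"
  )
  unknown <- setdiff(names(block), names(argMap))
  if (length(unknown)) {
    stop("unknown simulation key(s): ", paste(unknown, collapse = ", "))
  }
  args <- stats::setNames(block, argMap[names(block)])
  args <- lapply(args, function(v) if (is.list(v)) unlist(v) else v)
  if (is.null(args$seed)) args$seed <- seed
  do.call(simulationConfig, args)
}

#' Validate a pipeline config
#'
#' @param config named list (see [pipeline-config]).
#' @return The config with defaults filled in; errors name the offending
#'   field or file.
#' @export
validatePipelineConfig <- function(config) {
  hasSim <- !is.null(config$simulation)
  hasInputs <- !is.null(config$inputs)
  if (hasSim == hasInputs) {
    stop("config must have exactly one of 'simulation' or 'inputs'")
  }
  if (is.null(config$seed)) config$seed <- 1L
  thr <- utils::modifyList(.defaultThresholds, config$thresholds %||% list())
  if (thr$tau <= 1) stop("thresholds$tau must be > 1")
  if (thr$min_count < 0) stop("thresholds$min_count must be >= 0")
  if (thr$pseudocount <= 0) stop("thresholds$pseudocount must be > 0")
  if (thr$fraction <= 0 || thr$fraction >= 1) {
    stop("thresholds$fraction must lie in (0, 1)")
  }
  if (thr$q_cutoff <= 0 || thr$q_cutoff > 1) {
    stop("thresholds$q_cutoff must lie in (0, 1]")
  }
  config$thresholds <- thr
  if (is.null(config$contrasts)) config$contrasts <- .defaultContrasts
  for (ct in config$contrasts) {
    if (is.null(ct$name) || is.null(ct$numerator) || is.null(ct$denominator)) {
      stop("every contrast needs 'name', 'numerator' and 'denominator'")
    }
  }
  if (hasInputs) {
    needed <- c("counts", "samples")
    for (key in needed) {
      if (is.null(config$inputs[[key]])) {
        stop("inputs$", key, " is required")
      }
    }
    for (key in intersect(names(config$inputs),
                          c("counts", "samples", "annotation", "terms", "labels"))) {
      path <- config$inputs[[key]]
      if (!file.exists(path)) stop("input file not found: ", path, " (inputs$", key, ")")
    }
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.loadPipelineData <- function(config) {
  if (!is.null(config$simulation)) {
    simCfg <- .simConfigFromList(config$simulation, config$seed)
    sim <- simulateExperiment(simCfg)
    list(experiment = sim$experiment, transcripts = sim$transcripts,
         termMap = sim$termMap, classes = sim$classes, truth = sim$truth)
  } else {
    inp <- config$inputs
    out <- list(
      experiment = readCountExperiment(inp$counts, inp$samples),
      transcripts = NULL, termMap = NULL, classes = NULL, truth = NULL
    )
    if (!is.null(inp$annotation)) out$transcripts <- readAnnotation(inp$annotation)
    if (!is.null(inp$terms)) out$termMap <- readGmt(inp$terms)
    if (!is.null(inp$labels)) {
      lab <- utils::read.delim(inp$labels, stringsAsFactors = FALSE)
      out$classes <- stats::setNames(lab$class, lab$gene_id)
      if (is.null(out$termMap)) out$termMap <- split(lab$gene_id, lab$class)
    }
    out
  }
}

.setsToDf <- function(sets) {
  do.call(rbind, lapply(sets, function(gs) {
    if (length(gs) == 0L) return(NULL)
    data.frame(set = gs@name, contrast = gs@contrast, assay = gs@assay,
               direction = gs@direction, gene_id = members(gs),
               stringsAsFactors = FALSE)
  })) %||% data.frame(set = character(), contrast = character(),
                      assay = character(), direction = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end-to-end: data (simulation or files) ->
#' normalization -> contrasts -> fold-change gene sets -> cross-contrast
#' correlations and set overlaps -> 5'UTR/CDS window-score summaries with
#' group t tests -> term enrichment -> rank stratification -> optional
#' polysome quantification, writing a TSV/JSON report bundle plus a run
#' manifest (seed, package version, config hash, file checksums). A rerun
#' with the same config and seed is byte-identical.
#'
#' @param config path to a YAML file or a named list (see
#'   [pipeline-config]).
#' @param outdir output directory (default `config$outdir`, or
#'   `"structTE-report"`).
#' @param seed overrides `config$seed` when given.
#' @return Invisibly, a list with the in-memory results (`contrasts`,
#'   `sets`, `correlations`, `overlaps`, `windowSummary`, `windowTests`,
#'   `enrichment`, `rankOverlap`, `polysome`, `manifest`).
#' @export
runPipeline <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config <- validatePipelineConfig(config)
  outdir <- outdir %||% config$outdir %||% "structTE-report"
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  thr <- config$thresholds

  data <- .loadPipelineData(config)
  norm <- normalizeCounts(data$experiment,
                          method = config$normalization %||% "median-of-ratios")

  files <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    .writeTsv(df, path)
    files <<- c(files, path)
  }

  if (!is.null(data$truth)) emit(data$truth, "truth.tsv")

  # contrasts + fold-change sets
  contrasts <- list()
  sets <- list()
  for (ct in config$contrasts) {
    res <- teContrast(norm, ct$numerator, ct$denominator, label = ct$name,
                      minCount = thr$min_count)
    contrasts[[ct$name]] <- res
    emit(as.data.frame(contrastTable(res)), paste0("contrast_", ct$name, ".tsv"))
    sets[[ct$name]] <- classifySets(res, tau = thr$tau)
  }
  emit(.setsToDf(unlist(sets, recursive = FALSE)), "gene_sets.tsv")

  # cross-strain correlations of the urea response (when both exist)
  correlations <- NULL
  if (all(c("urea_response_wt", "urea_response_ntd") %in% names(contrasts))) {
    correlations <- do.call(rbind, lapply(c("rna", "ribo", "te"), function(f) {
      cr <- correlateContrasts(contrasts$urea_response_wt,
                               contrasts$urea_response_ntd, field = f)
      data.frame(field = f, r = cr$r, n = cr$n, stringsAsFactors = FALSE)
    }))
    emit(correlations, "correlations.tsv")
  }

  # overlap of up-regulated sets between strains, per assay
  overlaps <- NULL
  if (all(c("urea_response_wt", "urea_response_ntd") %in% names(contrasts))) {
    universe <- intersect(measurableGenes(contrasts$urea_response_wt),
                          measurableGenes(contrasts$urea_response_ntd))
    overlaps <- do.call(rbind, lapply(c("rna", "ribo", "te"), function(f) {
      a <- sets$urea_response_wt[[paste0(f, "_up")]]
      b <- sets$urea_response_ntd[[paste0(f, "_up")]]
      ov <- overlapFisher(intersect(members(a), universe),
                          intersect(members(b), universe), universe)
      cbind(data.frame(assay = f, stringsAsFactors = FALSE), as.data.frame(ov))
    }))
    emit(overlaps, "overlaps.tsv")
  }

  # window-score summaries + group tests for mutant TE-down sets
  windowSummary <- windowTests <- NULL
  structSets <- intersect(c("ntd_vs_wt_sd", "ntd_vs_wt_urea"), names(contrasts))
  if (!is.null(data$transcripts) && length(structSets)) {
    scored <- data$transcripts
    groupList <- list(all = geneIds(scored))
    for (nm in structSets) {
      down <- intersect(members(sets[[nm]]$te_down), geneIds(scored))
      if (length(down)) groupList[[paste0(nm, ".te_down")]] <- down
      up <- intersect(members(sets[[nm]]$te_up), geneIds(scored))
      if (length(up)) groupList[[paste0(nm, ".te_up")]] <- up
    }
    windowSummary <- featureTable(scored, groupList)
    emit(windowSummary, "window_summary.tsv")

    wt <- windowScoreTable(scored)
    feats <- c(.windowNames, "mean_5utr_per_nt", "utr5_len")
    windowTests <- do.call(rbind, lapply(
      setdiff(names(groupList), "all"),
      function(nm) {
        inSet <- wt$gene_id %in% groupList[[nm]]
        do.call(rbind, lapply(feats, function(f) {
          vals <- wt[[f]]
          if (sum(!is.na(vals[inSet])) < 2L || sum(!is.na(vals[!inSet])) < 2L) {
            return(NULL)
          }
          cmp <- compareGroups(vals[inSet], vals[!inSet])
          data.frame(set = nm, feature = f, mean_set = cmp@meanA,
                     mean_rest = cmp@meanB, n_set = cmp@nA, n_rest = cmp@nB,
                     t = cmp@t, p = cmp@p, significant = cmp@significant,
                     stringsAsFactors = FALSE)
        }))
      }
    ))
    if (!is.null(windowTests)) emit(windowTests, "window_tests.tsv")
  }

  # term enrichment for the mutant TE response under urea
  enrichment <- list()
  if (!is.null(data$termMap) && "ntd_vs_wt_urea" %in% names(contrasts)) {
    universe <- measurableGenes(contrasts$ntd_vs_wt_urea)
    for (dirn in c("te_down", "te_up")) {
      gs <- sets$ntd_vs_wt_urea[[dirn]]
      if (length(gs) == 0L) next
      enr <- enrichTerms(gs, data$termMap, universe)
      enrichment[[dirn]] <- enr
      emit(enr, paste0("enrichment_ntd_vs_wt_urea_", dirn, ".tsv"))
    }
  }

  # rank stratification of the mutant TE response, with term-list overlap
  rankOverlap <- NULL
  if (!is.null(data$termMap) && "ntd_vs_wt_urea" %in% names(contrasts)) {
    tab <- contrastTable(contrasts$ntd_vs_wt_urea)
    metric <- stats::setNames(tab$log2FC_te, tab$gene_id)
    universe <- measurableGenes(contrasts$ntd_vs_wt_urea)
    top <- rankSelect(metric, fraction = thr$fraction, side = "top")
    bottom <- rankSelect(metric, fraction = thr$fraction, side = "bottom")
    enrTop <- enrichTerms(top, data$termMap, universe)
    enrBottom <- enrichTerms(bottom, data$termMap, universe)
    tlo <- termListOverlap(enrTop, enrBottom, qCutoff = thr$q_cutoff)
    rankOverlap <- data.frame(
      fraction = thr$fraction, q_cutoff = thr$q_cutoff,
      jaccard = tlo$jaccard, n_top_terms = tlo$nA, n_bottom_terms = tlo$nB,
      shared_terms = paste(tlo$shared, collapse = ";"),
      stringsAsFactors = FALSE
    )
    emit(rankOverlap, "rank_term_overlap.tsv")
  }

  # optional polysome quantification
  polysome <- NULL
  if (!is.null(config$polysome)) {
    ps <- config$polysome
    trace <- readTrace(ps$trace)
    pm <- pmRatio(trace, unlist(ps$mono), unlist(ps$poly),
                  baseline = ps$baseline %||% 0)
    polysome <- data.frame(mono_area = pm@monoArea, poly_area = pm@polyArea,
                           pm_ratio = pm@pmRatio, stringsAsFactors = FALSE)
    emit(polysome, "polysome.tsv")
  }

  manifest <- list(
    package = "structTE",
    version = as.character(utils::packageVersion("structTE")),
    seed = config$seed,
    normalization = S4Vectors::metadata(norm)$normalization,
    thresholds = thr,
    config_md5 = .md5Of(config),
    files = lapply(sort(basename(files)), function(f) {
      list(name = f, md5 = unname(tools::md5sum(file.path(outdir, f))))
    })
  )
  manifestPath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    contrasts = contrasts, sets = sets, correlations = correlations,
    overlaps = overlaps, windowSummary = windowSummary,
    windowTests = windowTests, enrichment = enrichment,
    rankOverlap = rankOverlap, polysome = polysome, manifest = manifest
  ))
}
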