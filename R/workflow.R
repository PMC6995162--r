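# Workflow orchestration: one entry point behind the command-line tool.
# Each command reads Cq tables, runs the corresponding stage, and writes
# deterministic CSV outputs plus a machine-readable run manifest.

#' Assemble a workflow configuration
#'
#' Builds the configuration list consumed by [runWorkflow()], applying
#' defaults for everything not supplied. `configFile` (YAML or JSON) is
#' read first and explicit arguments override it.
#'
#' @param inputs character vector of input Cq table paths
#' @param outputDir directory for results (created if needed)
#' @param orientation,missingTokens,detectionCeiling,groupsPath passed to
#'   [readCqTable()] (one `groupsPath` per input, recycled)
#' @param controlPatterns passed to [curateCqSet()]
#' @param minGenes,minSamples,maxMissing inclusion thresholds for
#'   [checkInclusion()]
#' @param strict fail (instead of warn) on inclusion failure
#' @param k combination size for the `combos` command
#' @param poolFile optional file with one candidate gene id per line
#' @param excludeFile optional file with one gene id per line to drop from
#'   selected sets (literature-based exclusions)
#' @param setSize,nReplicates Monte-Carlo parameters
#' @param seed integer seed for every random stage
#' @param fastPath use cached combination scoring (`FALSE` = naive)
#' @param simulation named list of [simulateCqDataset()] arguments for the
#'   `simulate` command
#' @param configFile optional YAML/JSON file providing any of the above
#' @return a `RunConfig` list
#' @export
runConfig <- function(inputs = character(), outputDir = "normrank_out",
                      orientation = "genes-in-rows",
                      missingTokens = c("", "NA", "N/A", "Undetermined",
                                        "undetermined", "No Ct"),
                      detectionCeiling = NULL, groupsPath = NULL,
                      controlPatterns = character(),
                      minGenes = 170L, minSamples = 5L, maxMissing = 0.20,
                      strict = FALSE, k = 2L, poolFile = NULL,
                      excludeFile = NULL, setSize = 13L,
                      nReplicates = 2000L, seed = 1L, fastPath = TRUE,
                      simulation = list(), configFile = NULL) {
  cfg <- as.list(environment())
  cfg$configFile <- NULL
  if (!is.null(configFile)) {
    stopifnot(file.exists(configFile))
    fileCfg <- if (grepl("\\.json$", configFile, ignore.case = TRUE))
      jsonlite::read_json(configFile, simplifyVector = TRUE)
    else yaml::read_yaml(configFile)
    supplied <- names(as.list(match.call()))[-1L]
    for (nm in setdiff(names(fileCfg), supplied)) cfg[[nm]] <- fileCfg[[nm]]
  }
  structure(cfg, class = "RunConfig")
}

.loadCurated <- function(cfg, path, groupsPath = NULL) {
  raw <- readCqTable(path, orientation = cfg$orientation,
                     missingTokens = cfg$missingTokens,
                     groupsPath = groupsPath,
                     detectionCeiling = cfg$detectionCeiling)
  rep <- checkInclusion(raw, cfg$minGenes, cfg$minSamples, cfg$maxMissing)
  if (!rep$passed) {
    msg <- sprintf("dataset '%s' fails inclusion criteria: %s", path,
                   paste(rep$failed_rules, collapse = ", "))
    if (isTRUE(cfg$strict)) stop(msg) else warning(msg, call. = FALSE)
  }
  list(curated = curateCqSet(raw, cfg$controlPatterns), inclusion = rep)
}

.readIdFile <- function(path) {
  if (is.null(path)) return(NULL)
  ids <- trimws(readLines(path))
  ids[nzchar(ids)]
}

.writeManifest <- function(cfg, command, outputs, extra = list()) {
  manifest <- c(list(command = command,
                     package = "NormRank",
                     version = as.character(utils::packageVersion("NormRank")),
                     inputs = cfg$inputs, seed = cfg$seed,
                     parameters = cfg[setdiff(names(cfg),
                                              c("inputs", "simulation"))],
                     outputs = outputs),
                extra)
  path <- file.path(cfg$outputDir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  path
}

#' Run a workflow command
#'
#' Orchestrates the full pipeline from the shell or from R. Commands:
#' `curate` (read, quality-gate and curate each input; write curated
#' tables, curation logs and inclusion reports), `rank` (single-gene final
#' normalization scores per input plus the cross-dataset combined
#' ranking), `combos` (enumerate and score k-gene combinations plus the
#' global-mean factor per input), `select-set` (first-place index over
#' pairs and triples, minimal cover sets, triple validation, affinity
#' matrix), `mc-validate` (Monte-Carlo distribution and candidate
#' percentile; the candidate set is the pool file), `simulate` (write a
#' synthetic dataset and its ground truth). All outputs are CSV/JSON under
#' `cfg$outputDir`; content is deterministic for fixed inputs and seed.
#'
#' @param cfg a `RunConfig` from [runConfig()]
#' @param command one of `"curate"`, `"rank"`, `"combos"`, `"select-set"`,
#'   `"mc-validate"`, `"simulate"`
#' @return invisibly, a named list of written file paths
#' @export
runWorkflow <- function(cfg, command = c("curate", "rank", "combos",
                                         "select-set", "mc-validate",
                                         "simulate")) {
  command <- match.arg(command)
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  groupsPaths <- if (is.null(cfg$groupsPath)) rep(list(NULL),
                                                  length(cfg$inputs))
                 else rep_len(as.list(cfg$groupsPath), length(cfg$inputs))
  outputs <- character()
  extra <- list()
  dsName <- function(p) sub("\\.[^.]*$", "", basename(p))

  if (command == "simulate") {
    sim <- do.call(simulateCqDataset,
                   c(cfg$simulation, list(seed = cfg$seed)))
    tab <- file.path(cfg$outputDir, "simulated_cq.csv")
    writeCqTable(sim$dataset, tab)
    truth <- file.path(cfg$outputDir, "simulated_truth.csv")
    write.csv(sim$truth$genes, truth, row.names = FALSE)
    g <- sampleGroups(sim$dataset)
    outputs <- c(table = tab, truth = truth)
    if (!is.null(g)) {
      gp <- file.path(cfg$outputDir, "simulated_groups.csv")
      write.csv(data.frame(sample = colnames(sim$dataset), group = g),
                gp, row.names = FALSE)
      outputs <- c(outputs, groups = gp)
    }
  } else if (command == "curate") {
    for (i in seq_along(cfg$inputs)) {
      res <- .loadCurated(cfg, cfg$inputs[i], groupsPaths[[i]])
      out <- file.path(cfg$outputDir,
                       paste0(dsName(cfg$inputs[i]), "_curated.csv"))
      paths <- writeCqTable(res$curated, out)
      outputs <- c(outputs, paths)
      extra$inclusion[[dsName(cfg$inputs[i])]] <-
        unclass(res$inclusion)
    }
  } else if (command == "rank") {
    perDataset <- list()
    for (i in seq_along(cfg$inputs)) {
      res <- .loadCurated(cfg, cfg$inputs[i], groupsPaths[[i]])
      fs <- finalScores(res$curated)
      nm <- dsName(cfg$inputs[i])
      perDataset[[nm]] <- fs
      out <- file.path(cfg$outputDir, paste0(nm, "_ranking.csv"))
      write.csv(fs, out, row.names = FALSE)
      outputs <- c(outputs, out)
    }
    comb <- aggregateRankings(perDataset)
    out <- file.path(cfg$outputDir, "combined_ranking.csv")
    write.csv(comb, out, row.names = FALSE)
    outputs <- c(outputs, combined = out)
  } else if (command == "combos") {
    pool <- .readIdFile(cfg$poolFile)
    for (i in seq_along(cfg$inputs)) {
      res <- .loadCurated(cfg, cfg$inputs[i], groupsPaths[[i]])
      nm <- dsName(cfg$inputs[i])
      recs <- enumerateCombinations(res$curated, k = cfg$k, pool = pool,
                                    datasetId = nm,
                                    fastPath = cfg$fastPath)
      gm <- globalMeanFactor(res$curated, datasetId = nm,
                             fastPath = cfg$fastPath)
      out <- file.path(cfg$outputDir,
                       sprintf("%s_combos_k%d.csv", nm, cfg$k))
      write.csv(rbind(recs, gm), out, row.names = FALSE)
      outputs <- c(outputs, out)
    }
  } else if (command == "select-set") {
    exclude <- .readIdFile(cfg$excludeFile)
    pool <- .readIdFile(cfg$poolFile)
    allRecs <- list()
    for (i in seq_along(cfg$inputs)) {
      res <- .loadCurated(cfg, cfg$inputs[i], groupsPaths[[i]])
      nm <- dsName(cfg$inputs[i])
      for (kk in 2:3)
        allRecs[[paste(nm, kk)]] <-
          enumerateCombinations(res$curated, k = kk, pool = pool,
                                datasetId = nm, fastPath = cfg$fastPath)
    }
    idx <- collectFirstPlace(allRecs)
    cover <- minimalCoverSet(idx, k = 2L)
    sets <- cover$sets
    if (length(exclude))
      sets <- Filter(function(S) !any(S %in% exclude), sets)
    setsTxt <- file.path(cfg$outputDir, "candidate_sets.txt")
    writeLines(vapply(sets, paste, character(1L), collapse = ";"), setsTxt)
    val <- lapply(sets, validateSetWithTriples, index = idx)
    aff <- pairAffinityMatrix(idx)
    affCsv <- file.path(cfg$outputDir, "affinity_matrix.csv")
    write.csv(data.frame(gene_id = rownames(aff), aff,
                         check.names = FALSE), affCsv, row.names = FALSE)
    outputs <- c(sets = setsTxt, affinity = affCsv)
    extra$cover <- list(feasible = cover$feasible, size = cover$size,
                        n_sets = length(sets),
                        triple_validated =
                          vapply(val, `[[`, logical(1L), "passed"))
  } else if (command == "mc-validate") {
    candidate <- .readIdFile(cfg$poolFile)
    if (is.null(candidate))
      stop("mc-validate needs a candidate set via poolFile")
    res <- .loadCurated(cfg, cfg$inputs[1L], groupsPaths[[1L]])
    dist <- randomSetDistribution(res$curated, setSize = cfg$setSize,
                                  nReplicates = cfg$nReplicates,
                                  seed = cfg$seed)
    cm <- candidateMeanRanking(res$curated, candidate)
    mc <- percentileOfCandidate(dist, cm)
    histCsv <- file.path(cfg$outputDir, "mc_histogram.csv")
    write.csv(mcHistogram(dist), histCsv, row.names = FALSE)
    resJson <- file.path(cfg$outputDir, "mc_result.json")
    jsonlite::write_json(c(unclass(mc), list(set_size = dist$set_size,
                                             seed = cfg$seed)),
                         resJson, auto_unbox = TRUE, digits = NA)
    outputs <- c(histogram = histCsv, result = resJson)
  }
  manifest <- .writeManifest(cfg, command, outputs, extra)
  message(sprintf("[%s] done in %.1fs -> %s", command,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  cfg$outputDir))
  invisible(c(as.list(outputs), manifest = manifest))
}
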