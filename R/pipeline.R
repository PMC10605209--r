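#' Pipeline configuration
#'
#' Validated configuration for \code{\link{runPipeline}}: either input CSV
#' paths or a \linkS4class{SyntheticSpec}, a grouping rule (explicit group
#' column, or a PSQI column with scores above the cutoff labeled as the
#' sleep-disorder group), the sparsity grid, and the simulation counts.
#' Defaults follow the study design: grid 0.19--0.49 step 0.02, 1000
#' permutations, 100 rewired nulls for the small-world index, 1000
#' random-failure simulations, PSQI cutoff 5.
#'
#' @param gmvCsv,covariatesCsv input paths (CSV, header row, subject id first
#'   column); or
#' @param synthetic a \linkS4class{SyntheticSpec} to simulate the cohort.
#' @param groupColumn covariate column carrying group labels.
#' @param psqiColumn optional covariate column of PSQI scores; when given,
#'   groups are assigned by `score > psqiCutoff`.
#' @param psqiCutoff PSQI threshold (default 5; a score above it indicates
#'   poor sleep quality).
#' @param psqiLabels labels for (above, at-or-below) the cutoff.
#' @param regionLabels expected region columns; when set, all must be present.
#' @param grid,nPerm,nNull,nSim,seed analysis parameters.
#' @param ranking edge ranking ("signed" or "absolute").
#' @param outDir output directory for \code{\link{runPipeline}}.
#' @return a validated config list of class `scnConfig`.
#' @export
pipelineConfig <- function(gmvCsv = NULL, covariatesCsv = NULL,
                           synthetic = NULL, groupColumn = "group",
                           psqiColumn = NULL, psqiCutoff = 5,
                           psqiLabels = c("SD", "noSD"),
                           regionLabels = NULL, grid = sparsityGrid(),
                           nPerm = 1000L, nNull = 100L, nSim = 1000L,
                           seed = 1L, ranking = "signed", outDir = NULL) {
  hasFiles <- !is.null(gmvCsv) && !is.null(covariatesCsv)
  if (!hasFiles && is.null(synthetic))
    stop("either input CSV paths or a synthetic spec must be given")
  if (hasFiles && !is.null(synthetic))
    stop("give input paths or a synthetic spec, not both")
  for (cnt in c(nPerm = nPerm, nNull = nNull, nSim = nSim))
    if (cnt < 1) stop("all simulation counts must be positive")
  structure(list(gmvCsv = gmvCsv, covariatesCsv = covariatesCsv,
                 synthetic = synthetic, groupColumn = groupColumn,
                 psqiColumn = psqiColumn, psqiCutoff = psqiCutoff,
                 psqiLabels = psqiLabels, regionLabels = regionLabels,
                 grid = grid, nPerm = as.integer(nPerm),
                 nNull = as.integer(nNull), nSim = as.integer(nSim),
                 seed = as.integer(seed), ranking = ranking,
                 outDir = outDir),
            class = "scnConfig")
}

#' Load (or simulate) a cohort according to a configuration
#'
#' Reads the GMV and covariate CSVs, validates them (unique subject ids,
#' numeric region columns, all configured regions present) and attaches group
#' labels — either from the configured group column or by the PSQI rule
#' (score strictly above the cutoff gets the sleep-disorder label). With a
#' synthetic spec in the config, generates the cohort instead.
#'
#' @param config an `scnConfig` from \code{\link{pipelineConfig}}.
#' @return A \linkS4class{GMVCohort}.
#' @export
loadCohort <- function(config) {
  if (!is.null(config$synthetic))
    return(generateCohort(config$synthetic, seed = config$seed))
  gmv <- utils::read.csv(config$gmvCsv, check.names = FALSE)
  cov <- utils::read.csv(config$covariatesCsv, check.names = FALSE)
  ids <- as.character(gmv[[1]])
  if (anyDuplicated(ids))
    stop("duplicated subject id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  regions <- colnames(gmv)[-1]
  if (!is.null(config$regionLabels)) {
    missing <- setdiff(config$regionLabels, regions)
    if (length(missing))
      stop("region column(s) missing from the GMV table: ",
           paste(missing, collapse = ", "))
    regions <- config$regionLabels
  }
  raw <- gmv[, regions, drop = FALSE]
  vals <- suppressWarnings(
    vapply(raw, function(col) as.numeric(col), numeric(nrow(raw))))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-numeric or missing GMV value at row %d, column '%s'",
                 bad[1], regions[bad[2]]))
  }
  dimnames(vals) <- list(ids, regions)
  covIds <- as.character(cov[[1]])
  if (!setequal(covIds, ids) || anyDuplicated(covIds))
    stop("covariate subject ids do not match the GMV table")
  cov <- cov[match(ids, covIds), -1, drop = FALSE]
  rownames(cov) <- ids
  if (!is.null(config$psqiColumn)) {
    score <- cov[[config$psqiColumn]]
    if (is.null(score)) stop("PSQI column '", config$psqiColumn, "' not found")
    cov$group <- ifelse(score > config$psqiCutoff,
                        config$psqiLabels[1], config$psqiLabels[2])
  } else if (config$groupColumn != "group") {
    cov$group <- cov[[config$groupColumn]]
  }
  if (is.null(cov$group)) stop("no group labels: configure groupColumn or psqiColumn")
  gmvCohort(vals, cov)
}

.writeTidyCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  basename(path)
}

# evaluate a stage, turning any error into a stage-tagged abort with a
# FAILED marker so partially written outputs are identifiable
.stage <- function(name, expr, outDir) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", name, conditionMessage(e)),
               file.path(outDir, "FAILED"))
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full structural covariance network pipeline
#'
#' Orchestrates every stage for every group and pairwise contrast: covariate
#' residualization, correlation networks, binary graphs across the sparsity
#' grid, global metric curves with small-world indices, nodal metrics,
#' degree-based hubs, truncated power-law degree fits with pairwise log-rank
#' tests, robustness under random failure and targeted attack, and
#' AUC-summarized permutation tests for the global metrics. All tables are
#' written as CSV/TSV/JSON under `config$outDir` together with a
#' machine-readable manifest (versions, seed, configuration flags) and a log.
#' Outputs are deterministic for identical config and seed. A stage failure
#' aborts with a stage-tagged message and leaves a `FAILED` marker next to
#' any partial outputs.
#'
#' @param config an `scnConfig`; `outDir` must be set.
#' @param statistics global summaries to permutation-test (default the five
#'   headline curve metrics).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config,
                        statistics = c("clustering", "pathLength",
                                       "transitivity", "globalEfficiency",
                                       "localEfficiency")) {
  if (is.null(config$outDir)) stop("config$outDir must be set")
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "graphs"), showWarnings = FALSE)
  logFile <- file.path(out, "pipeline.log")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "", file = logFile,
                               append = TRUE)
  cat(sprintf("scovnet %s pipeline log (%s)\n",
              as.character(utils::packageVersion("scovnet")), date()),
      file = logFile)
  logLine("seed=%d nPerm=%d nNull=%d nSim=%d ranking=%s grid=[%.2f..%.2f]",
          config$seed, config$nPerm, config$nNull, config$nSim,
          config$ranking, min(config$grid), max(config$grid))
  logLine("flags: %s-ranked thresholding; adaptive targeted attack; BH-FDR for nodal metrics; hub degree basis = grid average; Lp over reachable pairs",
          config$ranking)
  manifest <- list(package = as.character(utils::packageVersion("scovnet")),
                   r_version = as.character(getRversion()),
                   seed = config$seed, nPerm = config$nPerm,
                   nNull = config$nNull, nSim = config$nSim,
                   ranking = config$ranking, grid = config$grid,
                   files = character())

  cohort <- .stage("load", loadCohort(config), out)
  cohort <- .stage("residualize", residualize(cohort), out)
  groups <- unique(groupLabels(cohort))
  manifest$groups <- groups
  grid <- config$grid

  graphsByGroup <- list()
  metricRows <- list(); aucRows <- list(); nodalRows <- list()
  hubRows <- list(); fitList <- list(); robRows <- list(); robAucRows <- list()

  for (g in groups) {
    net <- .stage("netbuild", correlationNetwork(cohort, g), out)
    f <- writeAdjacency(net, file.path(out, sprintf("covariance_%s.tsv", g)))
    manifest$files <- c(manifest$files, basename(f))
    graphs <- .stage("netbuild", thresholdGrid(net, grid, config$ranking), out)
    graphsByGroup[[g]] <- graphs
    for (s in names(graphs)) {
      f <- writeAdjacency(graphs[[s]],
                          file.path(out, "graphs", sprintf("%s_s%s.edge", g, s)),
                          format = "edge")
      manifest$files <- c(manifest$files, file.path("graphs", basename(f)))
    }

    .stage("metrics", {
      swSeed <- .subSeed(config$seed, match(g, groups))
      for (m in c("clustering", "pathLength", "transitivity",
                  "globalEfficiency", "localEfficiency")) {
        mc <- metricCurve(graphs, m, grid)
        metricRows[[length(metricRows) + 1L]] <-
          data.frame(group = g, density = grid, metric = m, value = mc@values)
        aucRows[[length(aucRows) + 1L]] <-
          data.frame(group = g, metric = m, auc = mc@auc)
      }
      sig <- vapply(seq_along(grid), function(i)
        unlist(smallWorld(graphs[[i]], nNull = config$nNull,
                          seed = .subSeed(swSeed, i))), numeric(3))
      for (m in c("gamma", "lambda", "sigma"))
        metricRows[[length(metricRows) + 1L]] <-
          data.frame(group = g, density = grid, metric = m, value = sig[m, ])
      nodalRows[[length(nodalRows) + 1L]] <-
        data.frame(group = g, density = grid[1], nodalMetrics(graphs[[1]]))
    }, out)

    .stage("degreestruct", {
      hubs <- hubAnalysis(graphs)
      if (length(hubRegions(hubs)))
        hubRows[[length(hubRows) + 1L]] <-
          data.frame(group = g, region = hubRegions(hubs),
                     degree = hubs@degreeBasis[hubRegions(hubs)],
                     threshold = hubs@threshold)
      deg <- rowMeans(vapply(graphs, function(x) rowSums(adjacency(x)),
                             numeric(length(regionLabels(graphs[[1]])))))
      fit <- fitTruncatedPowerlaw(pmax(1L, as.integer(round(deg))))
      fitList[[g]] <- list(k = fit@k, dc = fit@dc, r2 = fit@r2,
                           converged = fit@converged)
    }, out)

    .stage("attack", {
      for (i in seq_along(grid)) {
        rnd <- randomFailure(graphs[[i]], nSim = config$nSim,
                             seed = .subSeed(config$seed, 1000L + i))
        tgt <- targetedAttack(graphs[[i]])
        robRows[[length(robRows) + 1L]] <- data.frame(
          group = g, density = grid[i],
          attack_type = rep(c("random", "targeted"),
                            each = length(rnd@fractionsRemoved)),
          fraction_removed = c(rnd@fractionsRemoved, tgt@fractionsRemoved),
          mean_lcc = c(rnd@lccRelativeSize, tgt@lccRelativeSize))
        robAucRows[[length(robAucRows) + 1L]] <- data.frame(
          group = g, density = grid[i],
          attack_type = c("random", "targeted"), auc = c(rnd@auc, tgt@auc))
      }
    }, out)
  }

  addTidy <- function(df, name) {
    manifest$files <<- c(manifest$files, .writeTidyCsv(df, file.path(out, name)))
  }
  addTidy(do.call(rbind, metricRows), "global_metrics.csv")
  addTidy(do.call(rbind, aucRows), "auc_summary.csv")
  addTidy(do.call(rbind, nodalRows), "nodal_metrics.csv")
  if (length(hubRows)) addTidy(do.call(rbind, hubRows), "hubs.csv")
  jsonlite::write_json(fitList, file.path(out, "degree_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$files <- c(manifest$files, "degree_fits.json")
  addTidy(do.call(rbind, robRows), "robustness_curves.csv")
  addTidy(do.call(rbind, robAucRows), "robustness_auc.csv")

  pairs <- if (length(groups) > 1) utils::combn(groups, 2, simplify = FALSE) else list()
  contrasts <- list(); lrRows <- list()
  res <- residValues(cohort)
  for (pr in pairs) {
    a <- res[groupLabels(cohort) == pr[1], , drop = FALSE]
    b <- res[groupLabels(cohort) == pr[2], , drop = FALSE]
    key <- paste(pr, collapse = "_vs_")
    .stage("inference", {
      for (st in statistics) {
        pt <- permutationTest(a, b, statistic = st, grid = grid,
                              nPerm = config$nPerm,
                              seed = .subSeed(config$seed,
                                              5000L + length(contrasts)),
                              ranking = config$ranking)
        contrasts[[length(contrasts) + 1L]] <- list(
          contrast = key, statistic = st, observed_auc_diff = pt@observedAUC,
          p = pt@p, n_perm = pt@nPerm)
      }
    }, out)
    .stage("degreestruct", {
      meanDegree <- function(gl) rowMeans(vapply(
        gl, function(x) rowSums(adjacency(x)), numeric(ncol(res))))
      lr <- logrankDegreeTest(meanDegree(graphsByGroup[[pr[1]]]),
                              meanDegree(graphsByGroup[[pr[2]]]))
      lrRows[[length(lrRows) + 1L]] <- data.frame(
        contrast = key, statistic = lr$statistic, p = lr$p)
    }, out)
  }
  if (length(contrasts)) {
    jsonlite::write_json(contrasts, file.path(out, "contrasts.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$files <- c(manifest$files, "contrasts.json")
  }
  if (length(lrRows)) addTidy(do.call(rbind, lrRows), "logrank_degree.csv")

  manifest$n_graphs <- length(groups) * length(grid)
  manifest$n_contrasts <- length(pairs)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logLine("completed: %d groups x %d densities, %d contrasts",
          length(groups), length(grid), length(pairs))
  invisible(manifest)
}

#' Export BrainNet Viewer node/edge files
#'
#' Writes the `.node` file (six whitespace-separated columns: x, y, z, color
#' code, size, label) with node size set to degree and hubs given a distinct
#' color code, and the `.edge` file (bare N x N adjacency). Missing
#' coordinates become zeros with a warning.
#'
#' @param g a \linkS4class{BinaryGraph}.
#' @param hubs optional \linkS4class{HubSet}; hub nodes get color code 2,
#'   others 1.
#' @param coords optional N x 3 matrix of region coordinates (not bundled;
#'   user-supplied).
#' @param prefix output path prefix (writes `<prefix>.node`, `<prefix>.edge`).
#' @return invisibly, the two paths.
#' @export
exportBrainNet <- function(g, hubs = NULL, coords = NULL, prefix) {
  A <- adjacency(g)
  n <- nrow(A)
  labels <- rownames(A)
  if (is.null(coords)) {
    warning("no coordinates supplied; writing zeros")
    coords <- matrix(0, n, 3)
  }
  stopifnot(nrow(coords) == n)
  color <- rep(1L, n)
  if (!is.null(hubs)) color[labels %in% hubRegions(hubs)] <- 2L
  node <- data.frame(coords[, 1], coords[, 2], coords[, 3], color,
                     rowSums(A), labels)
  nodeFile <- paste0(prefix, ".node")
  edgeFile <- paste0(prefix, ".edge")
  utils::write.table(node, nodeFile, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeAdjacency(g, edgeFile, format = "edge")
  invisible(c(nodeFile, edgeFile))
}
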