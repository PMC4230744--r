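## Delimited-text readers/writers, the run configuration, and the pipeline
## entry points used by the command-line script.

.detectSep <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Read a coupling matrix from delimited text
#'
#' Accepts a square numeric matrix in tab-, comma- or whitespace-separated
#' text. A header row of region labels is auto-detected (first row
#' non-numeric) and preserved as dimnames. Ragged rows, non-numeric cells,
#' non-square shapes and negative entries are rejected with row/column
#' context.
#'
#' @param path File path.
#' @return A [CouplingMatrix-class] (weights taken as stored; the largest
#'   row sum is rescaled to 1 if it is not already).
#' @export
readCouplingMatrix <- function(path) {
  if (!file.exists(path)) stop("coupling matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty coupling matrix file: ", path)
  sep <- .detectSep(lines[1])
  split1 <- function(x) {
    f <- if (sep == "") strsplit(trimws(x), "[[:space:]]+")
    else strsplit(x, sep, fixed = TRUE)
    trimws(f[[1]])
  }
  first <- split1(lines[1])
  hasHeader <- anyNA(suppressWarnings(as.numeric(first)))
  header <- if (hasHeader) first else NULL
  body <- if (hasHeader) lines[-1] else lines
  cells <- lapply(body, split1)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1)
    stop("ragged rows in ", path, ": row ", which(ncols != ncols[1])[1] +
           hasHeader, " has ", ncols[which(ncols != ncols[1])[1]],
         " fields, expected ", ncols[1])
  m <- matrix(NA_real_, length(cells), ncols[1])
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v))
      stop("non-numeric cell in ", path, " at row ", i + hasHeader,
           ", column ", which(is.na(v))[1])
    m[i, ] <- v
  }
  if (nrow(m) != ncol(m))
    stop("coupling matrix in ", path, " is ", nrow(m), " x ", ncol(m),
         ", expected square")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative coupling weight at row ", bad[1], ", column ", bad[2])
  }
  if (!is.null(header)) dimnames(m) <- list(header, header)
  couplingMatrix(m, setDiagonal = FALSE)
}

#' Write a coupling matrix as delimited text
#'
#' @param C A [CouplingMatrix-class] or numeric matrix.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeCouplingMatrix <- function(C, path, sep = "\t") {
  w <- if (is(C, "CouplingMatrix")) couplingWeights(C) else as.matrix(C)
  hasHeader <- !is.null(colnames(w))
  con <- file(path, "w"); on.exit(close(con))
  if (hasHeader) writeLines(paste(colnames(w), collapse = sep), con)
  utils::write.table(w, con, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write a region manifest
#'
#' Tab-separated text with columns `index`, `label`, `role`; the role column
#' names the four special regions (`lmc_left`, `lmc_right`, `snc_left`,
#' `snc_right`) and is empty elsewhere.
#'
#' @param path File path.
#' @return `readRegionManifest`: a [RegionSet-class].
#' @export
readRegionManifest <- function(path) {
  if (!file.exists(path)) stop("region manifest not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "character", "character"))
  if (!identical(names(df), c("index", "label", "role")))
    stop("manifest must have columns index, label, role")
  df <- df[order(df$index), ]
  withRole <- df[nzchar(df$role), ]
  regionSet(df$label, stats::setNames(withRole$index, withRole$role))
}

#' @rdname readRegionManifest
#' @param regions A [RegionSet-class].
#' @return `writeRegionManifest`: `path`, invisibly.
#' @export
writeRegionManifest <- function(regions, path) {
  roles <- regionRoles(regions)
  role <- character(nRegions(regions))
  role[roles] <- names(roles)
  df <- data.frame(index = seq_len(nRegions(regions)),
                   label = regionLabels(regions), role = role)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a BOLD signal as delimited text
#'
#' Tab-separated, one column per region with a label header; the sampling
#' interval is recorded in a `# interval_s:` comment line.
#'
#' @param bold A [BoldSignal-class].
#' @param path File path.
#' @return `path` / a [BoldSignal-class].
#' @export
writeBoldSignal <- function(bold, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("# interval_s: ", format(bold@interval, digits = 15)),
               paste0("# drive: ", bold@drive),
               paste(bold@labels, collapse = "\t")), con)
  utils::write.table(bold@series, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBoldSignal
#' @export
readBoldSignal <- function(path) {
  if (!file.exists(path)) stop("BOLD file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  interval <- as.numeric(sub("^# interval_s:\\s*", "",
                             grep("interval_s", meta, value = TRUE)[1]))
  drv <- sub("^# drive:\\s*", "", grep("drive", meta, value = TRUE)[1])
  body <- lines[!grepl("^#", lines)]
  labels <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  m <- do.call(rbind, lapply(body[-1], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  new("BoldSignal", series = m, interval = interval, drive = drv,
      labels = labels)
}

## ---- run configuration ----

#' Construct a run configuration
#'
#' @param paths Named list; recognized keys `coupling`, `manifest`,
#'   `outDir`. Empty entries mean synthetic inputs.
#' @param parameters Named list of [ModelParameters-class] overrides.
#' @param solver [SolverConfig-class].
#' @param schedule [TaskSchedule-class].
#' @param analysis Named list with any of `bins`, `nNull`, `nPerm`,
#'   `alpha`, `trS`; defaults 0 (auto), 100, 1000, 0.05, 2.
#' @param seed Global seed; per-stage substreams are derived from it.
#' @return A [RunConfig-class].
#' @export
runConfig <- function(paths = list(), parameters = list(),
                      solver = solverConfig(), schedule = taskSchedule("task"),
                      analysis = list(), seed = 1L) {
  knownPaths <- c("coupling", "manifest", "outDir")
  badP <- setdiff(names(paths), knownPaths)
  if (length(badP)) stop("unknown path key(s): ", paste(badP, collapse = ", "))
  for (p in unlist(paths[names(paths) != "outDir"]))
    if (!file.exists(p)) stop("referenced file does not exist: ", p)
  if (length(parameters)) {
    bad <- setdiff(names(parameters), .parameterNames())
    if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  }
  defaults <- list(bins = 0, nNull = 100, nPerm = 1000, alpha = 0.05, trS = 2)
  badA <- setdiff(names(analysis), names(defaults))
  if (length(badA)) stop("unknown analysis key(s): ", paste(badA, collapse = ", "))
  defaults[names(analysis)] <- analysis
  new("RunConfig", paths = paths, parameters = parameters, solver = solver,
      schedule = schedule, analysis = defaults, seed = as.integer(seed))
}

#' Read / write a run configuration (YAML)
#'
#' The YAML layout mirrors the [RunConfig-class] slots; unknown keys are
#' rejected and a write/read round trip reproduces the configuration
#' exactly.
#'
#' @param path File path.
#' @return `readRunConfig`: a [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("paths", "parameters", "solver", "schedule", "analysis", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  sv <- y$solver
  if (!is.null(sv)) {
    badS <- setdiff(names(sv), c("h", "durationMs", "scheme", "seed", "stride"))
    if (length(badS)) stop("unknown solver key(s): ", paste(badS, collapse = ", "))
  }
  sc <- y$schedule
  if (!is.null(sc)) {
    badC <- setdiff(names(sc), c("mode", "cycle_s", "speech_s", "n_cycles"))
    if (length(badC)) stop("unknown schedule key(s): ", paste(badC, collapse = ", "))
  }
  solver <- solverConfig(h = sv$h %||% 0.1,
                         durationMs = sv$durationMs %||% NA_real_,
                         scheme = sv$scheme %||% "rk15",
                         seed = sv$seed %||% y$seed %||% 1L,
                         stride = sv$stride %||% 1L)
  schedule <- taskSchedule(sc$mode %||% "task", cycleS = sc$cycle_s %||% 10.6,
                           speechS = sc$speech_s %||% 8.6,
                           nCycles = sc$n_cycles %||% 50)
  runConfig(paths = y$paths %||% list(), parameters = y$parameters %||% list(),
            solver = solver, schedule = schedule,
            analysis = y$analysis %||% list(), seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readRunConfig
#' @param config A [RunConfig-class].
#' @export
writeRunConfig <- function(config, path) {
  y <- list(
    paths = config@paths,
    parameters = config@parameters,
    solver = list(h = config@solver@h, durationMs = config@solver@durationMs,
                  scheme = config@solver@scheme, seed = config@solver@seed,
                  stride = config@solver@stride),
    schedule = list(mode = config@schedule@mode,
                    cycle_s = config@schedule@cycleS,
                    speech_s = config@schedule@speechS,
                    n_cycles = config@schedule@nCycles),
    analysis = config@analysis,
    seed = config@seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

.configDigest <- function(config) {
  s <- yaml::as.yaml(list(seed = config@seed, solver = config@solver@scheme,
                          h = config@solver@h, mode = config@schedule@mode))
  h <- 216613626
  for (k in utf8ToInt(s)) h <- (bitwXor(as.integer(h %% 2^31), k) * 31) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Simulate both task conditions from a configuration
#'
#' Loads (or synthesizes) the coupling matrix and region manifest, runs the
#' rest and task conditions with shared seeds and initial state, and writes
#' the trajectory, firing-rate and BOLD artifacts plus a provenance record
#' to the output directory.
#'
#' @param config A [RunConfig-class].
#' @param outDir Output directory (defaults to `config@paths$outDir`).
#' @return Named list of written file paths, invisibly; the in-memory
#'   results as attribute `"results"`.
#' @export
cmdSimulate <- function(config, outDir = NULL) {
  outDir <- outDir %||% config@paths$outDir %||% stop("no output directory configured")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(modelParameters, config@parameters)
  regions <- if (!is.null(config@paths$manifest))
    readRegionManifest(config@paths$manifest) else makeRegionManifest(10)
  coupling <- if (!is.null(config@paths$coupling))
    readCouplingMatrix(config@paths$coupling)
  else generateCouplingMatrix(syntheticConnectomeSpec(N = nRegions(regions),
                                                      seed = config@seed))
  if (nRegions(coupling) != nRegions(regions))
    stop("coupling matrix (", nRegions(coupling), ") and manifest (",
         nRegions(regions), ") disagree on the region count")
  het <- sampleHeterogeneity(params, nRegions(regions), seed = config@seed)
  init <- initialState(params, nRegions(regions), config@seed)
  files <- list()
  results <- list()
  for (mode in c("rest", "task")) {
    sched <- taskSchedule(mode, cycleS = config@schedule@cycleS,
                          speechS = config@schedule@speechS,
                          nCycles = config@schedule@nCycles)
    t0 <- proc.time()[["elapsed"]]
    path <- simulateModel(params, coupling, regions, sched, config@solver,
                          het = het, initial = init)
    bold <- balloonWindkessel(path, params = params)
    boldTR <- sampleAtTR(bold, config@analysis$trS)
    traj <- file.path(outDir, paste0("trajectory_", mode, ".tsv"))
    utils::write.table(cbind(time_ms = path@times, path@states), traj,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    bf <- file.path(outDir, paste0("bold_", mode, ".tsv"))
    writeBoldSignal(boldTR, bf)
    message(sprintf("[simulate] %s: %d steps in %.1f s -> %s", mode,
                    length(path@times) - 1,
                    proc.time()[["elapsed"]] - t0, bf))
    files[[paste0("trajectory_", mode)]] <- traj
    files[[paste0("bold_", mode)]] <- bf
    results[[mode]] <- list(path = path, bold = boldTR)
  }
  prov <- file.path(outDir, "provenance.yaml")
  yaml::write_yaml(list(seed = config@seed, configDigest = .configDigest(config),
                        package = "nigrosim",
                        version = as.character(utils::packageVersion("nigrosim")),
                        rVersion = R.version.string), prov)
  files$provenance <- prov
  invisible(structure(files, results = results))
}

#' Analyze BOLD files: NMI networks, graph metrics, permutation test
#'
#' With one condition, emits NMI matrices and metric tables. With two paired
#' conditions (equal-length file lists, one file per replicate), additionally
#' runs the paired max-statistic permutation test on each metric.
#'
#' @param rest,task Character vectors of BOLD file paths (`task` optional).
#' @param outDir Output directory.
#' @param bins NMI bins (0 = automatic).
#' @param nNull Null-model count.
#' @param nPerm Permutation count.
#' @param seed Seed.
#' @return Named list of written files, invisibly; in-memory results as
#'   attribute `"results"`.
#' @export
cmdAnalyze <- function(rest, task = NULL, outDir, bins = 0, nNull = 100,
                       nPerm = 1000, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  loadCondition <- function(paths, tag) {
    lapply(seq_along(paths), function(i) {
      b <- readBoldSignal(paths[i])
      net <- nmiMatrix(b, bins = if (bins > 0) bins else NULL,
                       source = paste0(tag, ":", i))
      list(bold = b, nmi = net, metrics = graphMetrics(net, nNull = nNull,
                                                       seed = seed + i))
    })
  }
  restRes <- loadCondition(rest, "rest")
  nodes <- restRes[[1]]$metrics@metrics$node
  files <- list()
  writeCond <- function(res, tag) {
    for (i in seq_along(res)) {
      nf <- file.path(outDir, sprintf("nmi_%s_%02d.tsv", tag, i))
      writeCouplingMatrix(res[[i]]$nmi@values, nf)
      mf <- file.path(outDir, sprintf("metrics_%s_%02d.tsv", tag, i))
      utils::write.table(res[[i]]$metrics@metrics, mf, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files[[paste0("nmi_", tag, i)]] <<- nf
      files[[paste0("metrics_", tag, i)]] <<- mf
    }
  }
  writeCond(restRes, "rest")
  results <- list(rest = restRes)
  if (!is.null(task)) {
    if (length(task) != length(rest))
      stop("paired analysis needs equally many task and rest files")
    nTask <- nRegions(readBoldSignal(task[1]))
    if (nTask != length(nodes))
      stop("region-count mismatch: rest has ", length(nodes),
           ", task has ", nTask)
    taskRes <- loadCondition(task, "task")
    writeCond(taskRes, "task")
    results$task <- taskRes
    if (length(rest) >= 2) {
      metricOf <- function(res, col)
        do.call(rbind, lapply(res, function(r) r$metrics@metrics[[col]]))
      tests <- lapply(c(strength = "strength", clustering = "clustering",
                        efficiency = "efficiency"), function(col)
        pairedPermutationTest(metricOf(taskRes, col), metricOf(restRes, col),
                              nPerm = nPerm, seed = seed))
      tf <- file.path(outDir, "permutation_tests.tsv")
      df <- do.call(rbind, lapply(names(tests), function(nm)
        data.frame(metric = nm, node = nodes,
                   observed = tests[[nm]]@observed,
                   p_FWE = tests[[nm]]@pFWE)))
      utils::write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
      files$tests <- tf
      results$tests <- tests
    }
  }
  invisible(structure(files, results = results))
}
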