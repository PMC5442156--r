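#' Default screen configuration
#'
#' Flat key-value configuration for [runScreen()]. Every parameter of the
#' simulated screen and of hit calling lives here; unknown keys are
#' rejected when a config is read or merged, and every run's manifest
#' records the fully resolved config and its hash.
#'
#' @param ... overrides of the default keys.
#' @return Named list of configuration values.
#' @examples
#' cfg <- screenConfig(nTargets = 40, zCut = 2.5)
#' cfg$zCut
#' @export
screenConfig <- function(...) {
  defaults <- list(
    nTargets = 638, maxSirnasPerTarget = 5,
    plateRows = 16, plateCols = 24, nEmpty = 1,
    nCells = 850, divisionRate = 0.029, deathRate = 5e-4,
    penetrationDelay = 12,
    posControlEffect = 0.85,
    mitoticControlEffect = 0.7,
    hitFraction = 0.08, hitEffectMin = 0.5, hitEffectMax = 0.9,
    manualNoiseSd = 0.5,
    zCut = 2, manualCut = 3, manualCutHigh = 4, mncCut = 0.8,
    path = "fast", seed = 1)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
  }
  defaults
}

#' Read / write a screen configuration
#'
#' Configs are flat key-value YAML documents. Reading merges the file over
#' the defaults of [screenConfig()] and rejects unknown keys.
#'
#' @param path file path.
#' @param config a config list (for writing).
#' @return `readConfig()` returns the resolved config list.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(screenConfig, vals)
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run a simulated RNAi screen end to end
#'
#' Drives the whole pipeline: build the siRNA library, lay out plates,
#' assign latent phenotypes, simulate per-well MitosisCounts, score plates
#' with robust z, synthesize manual scores, call hits and summarize. The
#' default `"fast"` path draws per-well division counts from the exact
#' branching-process law ([simulateWellCounts()]); the `"events"` path
#' simulates full event logs per well and counts divisions (small screens
#' only); the `"full"` path additionally renders, segments and tracks each
#' well (tiny screens only).
#'
#' Library targets are hits with probability `hitFraction`, drawing a
#' viability effect uniformly on [`hitEffectMin`, `hitEffectMax`];
#' positive controls carry the strong default viability effect
#' (`posControlEffect`, rate multiplier 0.15) and mitotic-defect controls
#' a `mitotic_arrest` effect. All randomness derives from `config$seed`;
#' per-well streams on the event/imaging paths use [wellSeed()].
#'
#' @param config a configuration from [screenConfig()] / [readConfig()].
#' @return List with `library`, `plates`, `phenotypes`, `wells` (scored
#'   well table), `calls` (per-siRNA), `targets` (per-target flags),
#'   `summary` (a [ScreenSummary-class]) and `manifest` (seed, config
#'   hash, resolved config).
#' @examples
#' res <- runScreen(screenConfig(nTargets = 30, seed = 7))
#' res$summary
#' @export
runScreen <- function(config = screenConfig()) {
  config <- do.call(screenConfig, config)   # validates keys
  seed <- config$seed
  lib <- .stage("library", makeLibrary(config$nTargets,
                                       config$maxSirnasPerTarget,
                                       seed = seed))
  layout <- .stage("plates", makePlates(
    lib, c(config$plateRows, config$plateCols), nEmpty = config$nEmpty,
    seed = seed + 1L))
  phen <- .stage("phenotypes", withSeed(seed + 2L, {
    tg <- libraryTargets(lib)
    isHit <- stats::runif(length(tg)) < config$hitFraction
    eff <- ifelse(isHit,
                  stats::runif(length(tg), config$hitEffectMin,
                               config$hitEffectMax), 0)
    data.frame(target = tg, hit = isHit, effect = eff,
               class = ifelse(isHit, "viability", "none"))
  }))
  wells <- .stage("simulate", {
    w <- layout
    sirnaTarget <- sub("_si\\d+$", "", w$content)
    w$effect <- 0
    i <- w$role == "sample"
    w$effect[i] <- phen$effect[match(sirnaTarget[i], phen$target)]
    w$effect[w$role == "positive"] <- config$posControlEffect
    mult <- 1 - w$effect
    ## mitotic-defect controls: arrested mitoses rarely divide, so on the
    ## count level the arrest probability acts like a rate multiplier
    w$effect[w$role == "mitotic"] <- config$mitoticControlEffect
    mult[w$role == "mitotic"] <- 1 - config$mitoticControlEffect
    if (config$path == "fast") {
      w$mitosisCount <- simulateWellCounts(
        nrow(w), multiplier = mult, nCells = config$nCells,
        rate = config$divisionRate, delay = config$penetrationDelay,
        seed = seed + 3L)
    } else {
      spec <- movieSpec()
      w$mitosisCount <- vapply(seq_len(nrow(w)), function(k) {
        ph <- wellPhenotype(w$effect[k],
                            if (w$effect[k] > 0) "viability" else "none",
                            config$penetrationDelay)
        log <- simulateWell(ph, nCells = config$nCells,
                            rate = config$divisionRate, spec = spec,
                            deathRate = config$deathRate,
                            seed = wellSeed(seed, w$plate[k], w$well[k]))
        if (config$path == "full")
          mitosisCount(trackWell(log, spec,
                                 seed = wellSeed(seed + 1L, w$plate[k],
                                                 w$well[k]))$events)
        else divisionCount(log)
      }, numeric(1))
    }
    w
  })
  wells <- .stage("score", scorePlate(wells))
  calls <- .stage("manual", {
    i <- wells$role == "sample"
    sw <- wells[i, , drop = FALSE]
    data.frame(target = sub("_si\\d+$", "", sw$content),
               sirna = sw$content, plate = sw$plate, well = sw$well,
               z = sw$z,
               manualScore = synthesizeManualScores(
                 sw$effect, config$manualNoiseSd, seed = seed + 4L))
  })
  primary <- .stage("call", callPrimary(calls, zCut = config$zCut,
                                        manualCut = config$manualCut,
                                        manualCutHigh = config$manualCutHigh))
  summary <- .stage("summarize", summarizeScreen(primary$target))
  resolved <- config
  list(library = lib, plates = layout, phenotypes = phen, wells = wells,
       calls = primary$sirna, targets = primary$target, summary = summary,
       manifest = list(seed = seed, configHash = .configHash(resolved),
                       config = resolved))
}

#' Write / read pipeline tables
#'
#' All pipeline tables are tab-separated text with a schema header line
#' `# mitoscreen-table v1 <type>`; readers verify the header and restore
#' numeric values losslessly (numbers are written with 17 significant
#' digits).
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param type short schema tag stored in the header.
#' @return `writeScreenTable()` the path, invisibly; `readScreenTable()`
#'   the data.frame, with the type in attribute `tableType`.
#' @export
writeScreenTable <- function(df, path, type = "table") {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mitoscreen-table v1 %s", type), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeScreenTable
#' @export
readScreenTable <- function(path) {
  head <- readLines(path, n = 1L)
  if (!grepl("^# mitoscreen-table v1 ", head))
    stop("not a mitoscreen table: ", path)
  type <- sub("^# mitoscreen-table v1 ", "", head)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          stringsAsFactors = FALSE)
  attr(df, "tableType") <- type
  df
}

#' Write / read a cell event log as tabular text
#'
#' The event table is stored as a mitoscreen table of type `eventlog`;
#' the seeding count and time range travel in extra header fields.
#'
#' @param log a [CellEventLog-class].
#' @param path file path.
#' @return `writeEventLog()` the path, invisibly; `readEventLog()` the
#'   reconstructed [CellEventLog-class].
#' @export
writeEventLog <- function(log, path) {
  writeScreenTable(eventTable(log), path,
                   type = sprintf("eventlog nSeeded=%d range=%.17g,%.17g",
                                  nSeeded(log), log@timeRange[1],
                                  log@timeRange[2]))
}

#' @rdname writeEventLog
#' @export
readEventLog <- function(path) {
  df <- readScreenTable(path)
  type <- attr(df, "tableType")
  if (!grepl("^eventlog ", type)) stop("not an event-log table")
  ns <- as.integer(sub(".*nSeeded=(\\d+).*", "\\1", type))
  rng <- as.numeric(strsplit(sub(".*range=", "", type), ",")[[1]])
  df$parent <- as.integer(df$parent)
  attr(df, "tableType") <- NULL
  cellEventLog(df, nSeeded = ns, timeRange = rng)
}

#' Simulate control-performance plates on the fast path
#'
#' Builds `nPlates` full plates whose sample wells are all null (no
#' effect), draws per-well MitosisCounts from the fast-path count law
#' with the configured control effects (positive viability controls at
#' `posControlEffect` after the penetration delay, mitotic-defect
#' controls at `mitoticControlEffect`, negative and empty wells null),
#' and scores every well with the per-plate robust z. This is the
#' standard control-performance readout of a screen: the fraction of
#' negative-control wells below the z cutoff measures specificity, the
#' fraction of positive-control wells at or above it measures
#' sensitivity.
#'
#' @param nPlates number of plates (default 20).
#' @param config a [screenConfig()] list.
#' @param seed integer seed.
#' @return The scored well table (columns of [makePlates()] plus
#'   `mitosisCount` and `z`).
#' @examples
#' wells <- simulateControlPlates(2, seed = 1)
#' with(subset(wells, role == "negative"), mean(z < 2))
#' @export
simulateControlPlates <- function(nPlates = 20, config = screenConfig(),
                                  seed = 1) {
  config <- do.call(screenConfig, config)
  perPlate <- config$plateRows * config$plateCols - 18L - config$nEmpty
  nTargets <- ceiling(perPlate * nPlates / 5)
  lib <- makeLibrary(nTargets, 5, seed = seed, policy = "max")
  layout <- makePlates(lib, c(config$plateRows, config$plateCols),
                       nEmpty = config$nEmpty, seed = seed + 1L)
  layout <- layout[layout$plate %in% unique(layout$plate)[seq_len(nPlates)], ]
  mult <- rep(1, nrow(layout))
  mult[layout$role == "positive"] <- 1 - config$posControlEffect
  mult[layout$role == "mitotic"] <- 1 - config$mitoticControlEffect
  layout$mitosisCount <- simulateWellCounts(
    nrow(layout), multiplier = mult, nCells = config$nCells,
    rate = config$divisionRate, delay = config$penetrationDelay,
    seed = seed + 2L)
  scorePlate(layout)
}
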