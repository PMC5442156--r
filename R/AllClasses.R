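#' @import methods
NULL

## Event vocabulary used throughout the package. `division` and
## `mitotic_death` terminate a cell; `mitotic_exit` and
## `cytokinesis_failure` leave the cell alive (slippage / binucleation).
.EVENT_LEVELS <- c("birth", "mitosis_entry", "division", "mitotic_death",
                   "mitotic_exit", "cytokinesis_failure", "interphase_death")
.MITOSIS_OUTCOMES <- c("division", "mitotic_death", "mitotic_exit",
                       "cytokinesis_failure")
.FATE_LEVELS <- c("mitotic_death", "mitotic_exit", "cytokinesis_failure",
                  "direct_apoptosis", "normal", "other")
.PHENOTYPIC_FATES <- c("mitotic_death", "mitotic_exit",
                       "cytokinesis_failure", "direct_apoptosis")

#' MovieSpec: geometry and acquisition parameters of a synthetic movie
#'
#' Describes the imaging setup emulated by the simulator: frame geometry,
#' pixel size, acquisition interval and window, nucleus size, point-spread
#' blur and noise levels. Defaults follow a wide-field 10x time-lapse assay
#' imaging every 30 min from 4 h to 72 h post-transfection (137 frames) in
#' two channels (chromatin, red; tubulin, green).
#'
#' @slot frameSize integer(2), frame width and height in pixels (x, y).
#' @slot pixelSize numeric(1), micrometres per pixel.
#' @slot frameInterval numeric(1), hours between frames.
#' @slot firstTime,lastTime numeric(1), acquisition window in hours
#'   post-transfection.
#' @slot nucleusRadius numeric(1), nominal interphase nucleus radius in
#'   micrometres.
#' @slot psfSigma numeric(1), Gaussian blur sigma in pixels.
#' @slot background numeric(1), background intensity (arbitrary units).
#' @slot shotNoise numeric(1), per-pixel Gaussian noise standard deviation.
#' @slot brownianStep numeric(1), per-frame Brownian displacement sigma in
#'   micrometres.
#'
#' @seealso [movieSpec()] for the user constructor, [renderMovie()].
#' @exportClass MovieSpec
setClass("MovieSpec",
  representation(frameSize = "integer", pixelSize = "numeric",
                 frameInterval = "numeric", firstTime = "numeric",
                 lastTime = "numeric", nucleusRadius = "numeric",
                 psfSigma = "numeric", background = "numeric",
                 shotNoise = "numeric", brownianStep = "numeric"))

setValidity("MovieSpec", function(object) {
  msg <- character()
  if (length(object@frameSize) != 2L || any(object@frameSize < 8L))
    msg <- c(msg, "frameSize must be two integers >= 8")
  if (object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be positive")
  if (object@lastTime <= object@firstTime)
    msg <- c(msg, "lastTime must exceed firstTime")
  if (object@pixelSize <= 0 || object@nucleusRadius <= 0)
    msg <- c(msg, "pixelSize and nucleusRadius must be positive")
  if (object@background < 0 || object@shotNoise < 0 ||
      object@brownianStep < 0)
    msg <- c(msg, "noise and motion parameters must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a MovieSpec
#'
#' @param frameSize integer(2), frame width and height in pixels.
#' @param pixelSize micrometres per pixel. The default 1.3 um/px matches a
#'   10x objective on a typical sCMOS sensor.
#' @param frameInterval acquisition interval in hours (default 0.5, i.e.
#'   every 30 min).
#' @param firstTime,lastTime imaging window in hours post-transfection
#'   (defaults 4 and 72, giving 137 frames at the default interval).
#' @param nucleusRadius nominal nucleus radius in micrometres.
#' @param psfSigma Gaussian blur sigma in pixels.
#' @param background background intensity level.
#' @param shotNoise per-pixel noise standard deviation.
#' @param brownianStep per-frame random-walk step sigma in micrometres.
#' @return A [MovieSpec-class] object.
#' @examples
#' sp <- movieSpec(frameSize = c(128, 128), lastTime = 12)
#' nFrames(sp)
#' @export
movieSpec <- function(frameSize = c(256L, 256L), pixelSize = 1.3,
                      frameInterval = 0.5, firstTime = 4, lastTime = 72,
                      nucleusRadius = 10, psfSigma = 1, background = 0.05,
                      shotNoise = 0.01, brownianStep = 0.8) {
  new("MovieSpec", frameSize = as.integer(frameSize), pixelSize = pixelSize,
      frameInterval = frameInterval, firstTime = firstTime,
      lastTime = lastTime, nucleusRadius = nucleusRadius,
      psfSigma = psfSigma, background = background, shotNoise = shotNoise,
      brownianStep = brownianStep)
}

#' @describeIn movieSpec number of frames,
#'   `floor((lastTime - firstTime) / frameInterval) + 1`.
#' @param spec a [MovieSpec-class].
#' @export
nFrames <- function(spec) {
  as.integer(floor((spec@lastTime - spec@firstTime) / spec@frameInterval)) + 1L
}

#' @describeIn movieSpec acquisition times (hours) of all frames.
#' @export
frameTimes <- function(spec) {
  spec@firstTime + (seq_len(nFrames(spec)) - 1L) * spec@frameInterval
}

#' @describeIn movieSpec nucleus radius in pixels.
#' @export
nucleusRadiusPx <- function(spec) spec@nucleusRadius / spec@pixelSize

#' @describeIn movieSpec nominal nucleus area in square pixels
#'   (`pi * r_px^2`); 25% of this is the default segmentation area filter.
#' @export
nominalNucleusArea <- function(spec) pi * nucleusRadiusPx(spec)^2

setMethod("show", "MovieSpec", function(object) {
  cat(sprintf(
    "MovieSpec: %dx%d px (%.2f um/px), t = [%g, %g] h every %g h (%d frames)\n",
    object@frameSize[1], object@frameSize[2], object@pixelSize,
    object@firstTime, object@lastTime, object@frameInterval,
    nFrames(object)))
  cat(sprintf("  nucleus radius %.1f um (%.1f px), PSF sigma %.1f px\n",
              object@nucleusRadius, nucleusRadiusPx(object),
              object@psfSigma))
})

#' WellPhenotype: latent knockdown effect of a well
#'
#' The generative model behind control and knockdown wells. A well carries a
#' unitless effect strength in [0, 1] and an effect class. For the
#' `viability` class the mitosis rate is multiplied by `1 - effect` once the
#' knockdown has penetrated; for `mitotic_arrest` the effect sets the
#' per-mitosis probability of a prolonged prometaphase arrest. Effect 0 is
#' indistinguishable from a negative control.
#'
#' @slot effect numeric(1) in [0, 1].
#' @slot effectClass character(1), one of `viability`, `mitotic_arrest`,
#'   `nuclear_morphology`, `none`.
#' @slot penetrationDelay numeric(1), hours post-transfection before the
#'   effect acts (default 12 h; phenotypes strengthen tens of hours after
#'   transfection).
#' @seealso [wellPhenotype()]
#' @exportClass WellPhenotype
setClass("WellPhenotype",
  representation(effect = "numeric", effectClass = "character",
                 penetrationDelay = "numeric"))

setValidity("WellPhenotype", function(object) {
  msg <- character()
  if (object@effect < 0 || object@effect > 1)
    msg <- c(msg, "effect must lie in [0, 1]")
  if (!object@effectClass %in% c("viability", "mitotic_arrest",
                           "nuclear_morphology", "none"))
    msg <- c(msg, "unknown phenotype class")
  if (object@penetrationDelay < 0)
    msg <- c(msg, "penetrationDelay must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a WellPhenotype
#'
#' @param effect effect strength in [0, 1].
#' @param class effect class; see [WellPhenotype-class].
#' @param penetrationDelay hours before the effect acts (default 12).
#' @return A [WellPhenotype-class].
#' @examples
#' wellPhenotype(0.85, "viability")   # strong viability knockdown
#' rateMultiplier(wellPhenotype(0.85, "viability"))
#' @export
wellPhenotype <- function(effect = 0, class = c("none", "viability",
                          "mitotic_arrest", "nuclear_morphology"),
                          penetrationDelay = 12) {
  new("WellPhenotype", effect = effect, effectClass = match.arg(class),
      penetrationDelay = penetrationDelay)
}

#' @describeIn wellPhenotype mitosis-rate multiplier after penetration:
#'   `1 - effect` for the viability class, 1 otherwise.
#' @param phenotype a [WellPhenotype-class].
#' @export
rateMultiplier <- function(phenotype) {
  if (phenotype@effectClass == "viability") 1 - phenotype@effect else 1
}

#' @describeIn wellPhenotype per-mitosis arrest probability after
#'   penetration: `effect` for the mitotic_arrest class, 0 otherwise.
#' @export
arrestProbability <- function(phenotype) {
  if (phenotype@effectClass == "mitotic_arrest") phenotype@effect else 0
}

setMethod("show", "WellPhenotype", function(object) {
  cat(sprintf("WellPhenotype: class %s, effect %.2f, delay %g h\n",
              object@effectClass, object@effect, object@penetrationDelay))
})

#' FateMixture: distribution of terminal fates among phenotypic cells
#'
#' Probabilities over the four phenotypic outcomes: prometaphase arrest
#' followed by mitotic death, by mitotic exit (slippage), or by cytokinesis
#' failure, and direct apoptosis without prior arrest. The default mixture
#' (42% / 28% / 5% / 25%) reflects the observed fate distribution of
#' phenotypic HeLa cells after knockdown of a mitosis-linked lncRNA.
#'
#' @slot probs named numeric(4) summing to 1.
#' @seealso [fateMixture()], [assignFates()]
#' @exportClass FateMixture
setClass("FateMixture", representation(probs = "numeric"))

setValidity("FateMixture", function(object) {
  p <- object@probs
  if (length(p) != 4L ||
      !identical(names(p), .PHENOTYPIC_FATES))
    return("probs must be named mitotic_death, mitotic_exit, cytokinesis_failure, direct_apoptosis")
  if (any(p < 0)) return("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) return("probabilities must sum to 1")
  TRUE
})

#' Construct a FateMixture
#'
#' @param mitoticDeath,mitoticExit,cytokinesisFailure,directApoptosis
#'   probabilities of the four phenotypic fates; must be non-negative and
#'   sum to 1 (within 1e-8).
#' @return A [FateMixture-class].
#' @examples
#' fateMixture()            # the default 42/28/5/25 mixture
#' fateMixture(1, 0, 0, 0)  # point mass on arrest -> mitotic death
#' @export
fateMixture <- function(mitoticDeath = 0.42, mitoticExit = 0.28,
                        cytokinesisFailure = 0.05, directApoptosis = 0.25) {
  p <- c(mitotic_death = mitoticDeath, mitotic_exit = mitoticExit,
         cytokinesis_failure = cytokinesisFailure,
         direct_apoptosis = directApoptosis)
  new("FateMixture", probs = p)
}

#' @describeIn fateMixture probabilities as a named numeric vector.
#' @param mixture a [FateMixture-class].
#' @export
fateProbs <- function(mixture) mixture@probs

setMethod("show", "FateMixture", function(object) {
  cat("FateMixture:\n")
  print(round(object@probs, 4))
})

#' CellEventLog: timed per-cell event sequences of one well
#'
#' Ground-truth record of everything that happens to every cell in a well:
#' births (with lineage), mitosis entries and their outcomes, and deaths,
#' each stamped with a time in hours and an (x, y) position in micrometres.
#' Every downstream statistic (MitosisCount, fate profiles, time courses)
#' is defined against this log.
#'
#' Event grammar per cell:
#' `birth -> (mitosis_entry -> one of division | mitotic_death |
#' mitotic_exit | cytokinesis_failure)* -> optional interphase_death`,
#' where `division` and `mitotic_death` terminate the cell and a division
#' emits exactly two daughter births at the division time.
#'
#' @slot events data.frame with columns `cell` (integer id), `parent`
#'   (integer, NA for seeded cells), `time` (hours), `event` (see grammar),
#'   `x`, `y` (micrometres).
#' @slot nSeeded integer(1), number of initially seeded cells.
#' @slot timeRange numeric(2), admissible event-time window in hours.
#' @seealso [cellEventLog()], [simulateWell()], [assignFates()]
#' @exportClass CellEventLog
setClass("CellEventLog",
  representation(events = "data.frame", nSeeded = "integer",
                 timeRange = "numeric"))

setValidity("CellEventLog", function(object) {
  ev <- object@events
  need <- c("cell", "parent", "time", "event", "x", "y")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  if (nrow(ev) == 0L) return(TRUE)
  if (!all(ev$event %in% .EVENT_LEVELS))
    return("unknown event type in log")
  if (any(ev$time < object@timeRange[1] - 1e-9 |
          ev$time > object@timeRange[2] + 1e-9))
    return("event times outside the log's time range")
  ok <- checkEventGrammar(ev)
  if (!isTRUE(ok)) return(ok)
  TRUE
})

#' Construct a CellEventLog
#'
#' @param events data.frame of events; see [CellEventLog-class].
#' @param nSeeded number of initially seeded cells.
#' @param timeRange numeric(2) admissible time window (hours).
#' @return A [CellEventLog-class].
#' @export
cellEventLog <- function(events, nSeeded, timeRange = c(4, 72)) {
  events <- as.data.frame(events)
  o <- order(events$cell, events$time)
  events <- events[o, , drop = FALSE]
  rownames(events) <- NULL
  new("CellEventLog", events = events, nSeeded = as.integer(nSeeded),
      timeRange = as.numeric(timeRange))
}

#' @describeIn cellEventLog the event table, ordered by cell then time.
#' @param log a [CellEventLog-class].
#' @export
eventTable <- function(log) log@events

#' @describeIn cellEventLog number of initially seeded cells.
#' @export
nSeeded <- function(log) log@nSeeded

#' @describeIn cellEventLog number of division events in the log (the
#'   ground-truth MitosisCount of the well).
#' @export
divisionCount <- function(log) sum(log@events$event == "division")

setMethod("show", "CellEventLog", function(object) {
  ev <- object@events
  cat(sprintf("CellEventLog: %d seeded cells, %d cells total, %d events, t in [%g, %g] h\n",
              object@nSeeded,
              length(unique(ev$cell)), nrow(ev),
              object@timeRange[1], object@timeRange[2]))
  if (nrow(ev)) print(table(factor(ev$event, levels = .EVENT_LEVELS)))
})

#' Check the per-cell event grammar of an event table
#'
#' Validates the automaton `birth -> (mitosis_entry -> outcome)* ->
#' optional interphase_death` for every cell, that terminal events
#' (`division`, `mitotic_death`, `interphase_death`) end the sequence, and
#' that every division emits exactly two daughter births at the division
#' time.
#'
#' @param events event data.frame (see [CellEventLog-class]).
#' @return `TRUE`, or a character message describing the first violation.
#' @export
checkEventGrammar <- function(events) {
  ev <- events[order(events$cell, events$time), , drop = FALSE]
  for (cellEv in split(ev, ev$cell)) {
    types <- cellEv$event
    id <- cellEv$cell[1]
    if (types[1] != "birth")
      return(sprintf("cell %d does not start with birth", id))
    i <- 2L
    terminated <- FALSE
    while (i <= length(types)) {
      if (terminated)
        return(sprintf("cell %d has events after a terminal event", id))
      t <- types[i]
      if (t == "mitosis_entry") {
        if (i < length(types) && types[i + 1L] %in% .MITOSIS_OUTCOMES) {
          if (types[i + 1L] %in% c("division", "mitotic_death"))
            terminated <- TRUE
          i <- i + 2L
        } else if (i == length(types)) {
          i <- i + 1L   # unresolved mitosis at end of observation
        } else {
          return(sprintf("cell %d: mitosis_entry not followed by an outcome", id))
        }
      } else if (t == "interphase_death") {
        terminated <- TRUE
        i <- i + 1L
      } else {
        return(sprintf("cell %d: unexpected event '%s'", id, t))
      }
    }
  }
  ## division conservation: each division yields exactly two births
  div <- ev[ev$event == "division", , drop = FALSE]
  births <- ev[ev$event == "birth", , drop = FALSE]
  for (k in seq_len(nrow(div))) {
    nd <- sum(births$parent == div$cell[k] &
              abs(births$time - div$time[k]) < 1e-9, na.rm = TRUE)
    if (nd != 2L)
      return(sprintf("division of cell %d emits %d daughters (expected 2)",
                     div$cell[k], nd))
  }
  orphan <- births$parent[!is.na(births$parent)]
  if (!all(orphan %in% div$cell))
    return("daughter birth without a matching division")
  TRUE
}

#' TrackSet: linked object trajectories of one movie
#'
#' Tracks produced by frame-to-frame linking of segmented nuclei. Each
#' point assigns one object in one frame to a track; parents record
#' track splits (mitoses) once detected.
#'
#' @slot points data.frame with columns `track`, `frame`, `object`, `x`,
#'   `y` (pixels, 0-based), `area` (px^2).
#' @slot parents data.frame with columns `track`, `parent` (filled by
#'   [detectSplits()]).
#' @seealso [linkTracks()], [detectSplits()]
#' @exportClass TrackSet
setClass("TrackSet",
  representation(points = "data.frame", parents = "data.frame"))

setValidity("TrackSet", function(object) {
  pt <- object@points
  need <- c("track", "frame", "object", "x", "y", "area")
  if (!all(need %in% names(pt)))
    return(paste("points must have columns", paste(need, collapse = ", ")))
  if (nrow(pt)) {
    byTrack <- split(pt$frame, pt$track)
    if (any(vapply(byTrack, function(f) any(diff(sort(f)) < 1L), logical(1))))
      return("duplicate frame within a track")
  }
  TRUE
})

#' @describeIn linkTracks the per-point table of a TrackSet.
#' @export
trackPoints <- function(tracks) tracks@points

#' @describeIn linkTracks the track -> parent table of a TrackSet.
#' @export
trackParents <- function(tracks) tracks@parents

setMethod("show", "TrackSet", function(object) {
  pt <- object@points
  nt <- length(unique(pt$track))
  cat(sprintf("TrackSet: %d tracks, %d points over %d frames\n",
              nt, nrow(pt),
              if (nrow(pt)) length(unique(pt$frame)) else 0L))
  if (nrow(object@parents))
    cat(sprintf("  %d tracks have an assigned parent (mitoses)\n",
                nrow(object@parents)))
})

#' FateThresholds: operational definitions for fate classification
#'
#' @slot normalDuration numeric(1), typical mitosis duration in hours
#'   (about 1 h in unperturbed cells).
#' @slot arrestThreshold numeric(1), hours in mitosis beyond which a cell
#'   counts as arrested (default 2 h, twice the normal duration; the paper
#'   domain gives no numeric cutoff so this is a declared surrogate).
#' @slot earlyWindow numeric(2), hours post-transfection within which
#'   direct apoptosis is typically observed (default [12, 24]).
#' @seealso [fateThresholds()], [classifyFate()]
#' @exportClass FateThresholds
setClass("FateThresholds",
  representation(normalDuration = "numeric", arrestThreshold = "numeric",
                 earlyWindow = "numeric"))

setValidity("FateThresholds", function(object) {
  if (object@arrestThreshold <= object@normalDuration)
    return("arrestThreshold must exceed normalDuration")
  TRUE
})

#' Construct FateThresholds
#'
#' @param normalDuration typical mitosis duration (h).
#' @param arrestThreshold in-mitosis duration (h) above which a cell is
#'   classed as arrested.
#' @param earlyWindow numeric(2), early-apoptosis window (h).
#' @return A [FateThresholds-class].
#' @export
fateThresholds <- function(normalDuration = 1, arrestThreshold = 2,
                           earlyWindow = c(12, 24)) {
  new("FateThresholds", normalDuration = normalDuration,
      arrestThreshold = arrestThreshold, earlyWindow = as.numeric(earlyWindow))
}

setMethod("show", "FateThresholds", function(object) {
  cat(sprintf(
    "FateThresholds: normal mitosis %g h, arrest if > %g h, early window [%g, %g] h\n",
    object@normalDuration, object@arrestThreshold,
    object@earlyWindow[1], object@earlyWindow[2]))
})

#' ScreenSummary: hit arithmetic of a screen
#'
#' Counts of bioinformatic (z-score) hits, manual-score hits, their overlap
#' and union, validated hits, and hits validated after being called by both
#' primary analyses.
#'
#' @slot nBioinformatic,nManual,nOverlap,nUnion,nValidated,nValidatedBoth
#'   integer(1) counts; `nUnion = nBioinformatic + nManual - nOverlap`
#'   always holds.
#' @seealso [summarizeScreen()]
#' @exportClass ScreenSummary
setClass("ScreenSummary",
  representation(nBioinformatic = "integer", nManual = "integer",
                 nOverlap = "integer", nUnion = "integer",
                 nValidated = "integer", nValidatedBoth = "integer"))

setValidity("ScreenSummary", function(object) {
  msg <- character()
  if (object@nUnion != object@nBioinformatic + object@nManual - object@nOverlap)
    msg <- c(msg, "union must equal bioinformatic + manual - overlap")
  if (object@nOverlap > min(object@nBioinformatic, object@nManual))
    msg <- c(msg, "overlap cannot exceed either hit set")
  if (object@nValidatedBoth > object@nValidated)
    msg <- c(msg, "validated-by-both cannot exceed validated")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScreenSummary", function(object) {
  cat("ScreenSummary:\n")
  cat(sprintf("  bioinformatic hits : %d\n", object@nBioinformatic))
  cat(sprintf("  manual hits        : %d\n", object@nManual))
  cat(sprintf("  overlap            : %d\n", object@nOverlap))
  cat(sprintf("  union              : %d\n", object@nUnion))
  cat(sprintf("  validated          : %d\n", object@nValidated))
  cat(sprintf("  validated by both  : %d\n", object@nValidatedBoth))
})

#' @describeIn summarizeScreen extract the counts of a ScreenSummary as a
#'   named integer vector.
#' @param summary a [ScreenSummary-class].
#' @export
screenCounts <- function(summary) {
  c(bioinformatic = summary@nBioinformatic, manual = summary@nManual,
    overlap = summary@nOverlap, union = summary@nUnion,
    validated = summary@nValidated, validatedBoth = summary@nValidatedBoth)
}
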