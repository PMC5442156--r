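#' Classify the fate of each cell in an event log
#'
#' Applies the fate taxonomy to per-cell event sequences. A cell counts as
#' arrested when its first mitosis lasting longer than the arrest
#' threshold occurs; the event resolving that mitosis names the fate:
#' \itemize{
#'   \item arrest + mitotic_death -> `mitotic_death`
#'   \item arrest + mitotic_exit -> `mitotic_exit`
#'   \item arrest + cytokinesis_failure -> `cytokinesis_failure`
#'   \item interphase_death with no prior arrest -> `direct_apoptosis`
#'   \item mitoses within the normal duration ending in division (or no
#'     aberrant event at all) -> `normal`
#'   \item anything else (arrest resolving in a division, unresolved
#'     arrest at the end of the movie) -> `other`
#' }
#'
#' @param log a [CellEventLog-class] (grammar-checked on construction).
#' @param thresholds a [FateThresholds-class].
#' @return data.frame with columns `cell`, `fate` (factor with the levels
#'   above) and `arrestDuration` (hours in mitosis for arrested cells,
#'   otherwise `NA`).
#' @examples
#' log <- assignFates(50, seed = 1)
#' table(classifyFate(log)$fate)
#' @export
classifyFate <- function(log, thresholds = fateThresholds()) {
  stopifnot(is(log, "CellEventLog"), is(thresholds, "FateThresholds"))
  ev <- eventTable(log)
  tEnd <- log@timeRange[2]
  tArr <- thresholds@arrestThreshold
  out <- lapply(split(ev, ev$cell), function(ce) {
    ce <- ce[order(ce$time), , drop = FALSE]
    entries <- which(ce$event == "mitosis_entry")
    fate <- NA_character_
    dur <- NA_real_
    for (i in entries) {
      te <- ce$time[i]
      resolved <- i < nrow(ce) && ce$event[i + 1L] %in% .MITOSIS_OUTCOMES
      d <- if (resolved) ce$time[i + 1L] - te else tEnd - te
      if (d > tArr) {
        dur <- d
        fate <- if (!resolved) "other" else
          switch(ce$event[i + 1L],
                 mitotic_death = "mitotic_death",
                 mitotic_exit = "mitotic_exit",
                 cytokinesis_failure = "cytokinesis_failure",
                 division = "other")
        break
      }
    }
    if (is.na(fate)) {
      fate <- if (any(ce$event == "interphase_death")) "direct_apoptosis"
              else "normal"
    }
    data.frame(cell = ce$cell[1], fate = fate, arrestDuration = dur)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$fate <- factor(res$fate, levels = .FATE_LEVELS)
  res
}

#' Fate profile of phenotypic cells
#'
#' Fractions of the four phenotypic fates among phenotypic cells. Cells
#' classified `normal` or `other` are excluded from the denominator,
#' matching quantifications of fates "occurring in phenotypic cells".
#'
#' @param fates the data.frame from [classifyFate()], or a factor/character
#'   vector of fate labels.
#' @return Named numeric vector over the phenotypic fates, summing to 1.
#' @examples
#' fateProfile(rep("mitotic_death", 10))
#' @export
fateProfile <- function(fates) {
  labels <- if (is.data.frame(fates)) fates$fate else fates
  labels <- as.character(labels)
  pheno <- labels[labels %in% .PHENOTYPIC_FATES]
  if (!length(pheno)) stop("no phenotypic cells to profile")
  counts <- table(factor(pheno, levels = .PHENOTYPIC_FATES))
  fr <- as.numeric(counts) / length(pheno)
  names(fr) <- .PHENOTYPIC_FATES
  fr
}

#' Mitotic and apoptotic time course of a well
#'
#' At each requested time point, the mitotic fraction is the number of
#' cells currently in mitosis (between a mitosis entry and its resolution,
#' or unresolved) divided by the number of alive cells, and the apoptotic
#' fraction is the cumulative number of deaths divided by the number of
#' initially seeded cells.
#'
#' @param log a [CellEventLog-class].
#' @param timepoints hours (default 24, 48, 72); must lie within the
#'   log's time range.
#' @return data.frame `time`, `mitoticFraction`, `apoptoticFraction`,
#'   `aliveCells`.
#' @export
timeCourse <- function(log, timepoints = c(24, 48, 72)) {
  stopifnot(is(log, "CellEventLog"))
  rng <- log@timeRange
  if (any(timepoints < rng[1] - 1e-9 | timepoints > rng[2] + 1e-9))
    stop("timepoints outside the log's time range")
  ev <- eventTable(log)
  cells <- split(ev, ev$cell)
  birth <- vapply(cells, function(ce) ce$time[ce$event == "birth"][1],
                  numeric(1))
  endInfo <- vapply(cells, function(ce) {
    term <- ce[ce$event %in% c("division", "mitotic_death",
                               "interphase_death"), , drop = FALSE]
    if (nrow(term)) c(term$time[1], term$event[1] != "division")
    else c(Inf, 0)
  }, numeric(2))
  endTime <- endInfo[1, ]; isDeath <- endInfo[2, ] == 1
  mitIntervals <- lapply(cells, function(ce) {
    ce <- ce[order(ce$time), , drop = FALSE]
    entries <- which(ce$event == "mitosis_entry")
    if (!length(entries)) return(NULL)
    cbind(ce$time[entries],
          vapply(entries, function(i)
            if (i < nrow(ce) && ce$event[i + 1L] %in% .MITOSIS_OUTCOMES)
              ce$time[i + 1L] else Inf, numeric(1)))
  })
  res <- lapply(timepoints, function(t) {
    alive <- birth <= t & endTime > t
    inMit <- vapply(seq_along(cells), function(k) {
      iv <- mitIntervals[[k]]
      alive[k] && !is.null(iv) && any(t >= iv[, 1] & t < iv[, 2])
    }, logical(1))
    deaths <- sum(isDeath & endTime <= t)
    data.frame(time = t,
               mitoticFraction = if (any(alive)) sum(inMit) / sum(alive) else 0,
               apoptoticFraction = deaths / max(nSeeded(log), 1L),
               aliveCells = sum(alive))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Arrest durations of classified cells
#'
#' In-mitosis dwell times of all cells whose mitosis exceeded the arrest
#' threshold. Under the default simulator the arrest-duration law is
#' uniform on (2, 10] hours, so the maximum never exceeds 10 h.
#'
#' @param log a [CellEventLog-class].
#' @param thresholds a [FateThresholds-class].
#' @return Numeric vector of durations in hours (possibly empty).
#' @export
arrestDurations <- function(log, thresholds = fateThresholds()) {
  f <- classifyFate(log, thresholds)
  f$arrestDuration[!is.na(f$arrestDuration)]
}
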