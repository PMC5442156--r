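#' Simulate the cell-event log of one well
#'
#' Event-level branching-process simulation of a well seeded with `nCells`
#' cells at the start of imaging. Each cell waits an exponential time to
#' its next mitosis (baseline hazard `rate` per cell per hour, multiplied
#' by the phenotype's rate multiplier once the knockdown has penetrated)
#' in competition with a constant interphase-death hazard. A normal
#' mitosis lasts about an hour and ends in a division emitting two
#' daughters; under a `mitotic_arrest` phenotype a mitosis entered after
#' the penetration delay arrests with probability `effect`, dwells 2-10 h
#' in prometaphase, and resolves by mitotic death, mitotic exit or
#' cytokinesis failure according to the arrest components of `mixture`.
#'
#' For a null well the expected number of divisions is approximately
#' `nCells * rate * duration`, inflated by branching (daughters divide
#' too); the exact law is the Yule process used by [simulateWellCounts()].
#'
#' @param phenotype a [WellPhenotype-class] (default: no effect).
#' @param nCells number of seeded cells (default 850 per well).
#' @param rate baseline mitosis hazard, events/cell/h (default 0.029,
#'   i.e. a 24 h doubling time).
#' @param spec a [MovieSpec-class]; defines the observation window and the
#'   spatial extent of the well.
#' @param deathRate baseline interphase-death hazard per cell per hour.
#' @param mixture a [FateMixture-class] used for arrest outcomes.
#' @param seed integer seed.
#' @return A [CellEventLog-class].
#' @examples
#' log <- simulateWell(nCells = 50, spec = movieSpec(lastTime = 24), seed = 1)
#' divisionCount(log)
#' @export
simulateWell <- function(phenotype = wellPhenotype(), nCells = 850,
                         rate = 0.029, spec = movieSpec(),
                         deathRate = 5e-4, mixture = fateMixture(),
                         seed = NULL) {
  if (nCells < 0) stop("nCells must be non-negative")
  if (rate < 0) stop("rate must be non-negative")
  if (deathRate < 0) stop("deathRate must be non-negative")
  t0 <- spec@firstTime; tEnd <- spec@lastTime
  delay <- phenotype@penetrationDelay
  mult <- rateMultiplier(phenotype)
  pArrest <- arrestProbability(phenotype)
  arrestP <- fateProbs(mixture)[1:3]
  arrestP <- if (sum(arrestP) > 0) arrestP / sum(arrestP) else
    c(mitotic_death = 1, mitotic_exit = 0, cytokinesis_failure = 0)
  fieldW <- spec@frameSize[1] * spec@pixelSize
  fieldH <- spec@frameSize[2] * spec@pixelSize
  rexpSafe <- function(r) if (r > 0) stats::rexp(1, r) else Inf
  nextEntry <- function(s) {
    r1 <- rate; r2 <- rate * mult
    if (s >= delay) return(s + rexpSafe(r2))
    w <- rexpSafe(r1)
    if (s + w < delay) s + w else delay + rexpSafe(r2)
  }
  withSeed(seed, {
    ## event store, grown geometrically
    cap <- max(64L, nCells * 8L)
    evCell <- integer(cap); evPar <- integer(cap); evTime <- numeric(cap)
    evType <- character(cap); evX <- numeric(cap); evY <- numeric(cap)
    nEv <- 0L
    push <- function(cell, parent, time, type, x, y) {
      if (nEv == length(evCell)) {
        evCell <<- c(evCell, integer(nEv)); evPar <<- c(evPar, integer(nEv))
        evTime <<- c(evTime, numeric(nEv)); evType <<- c(evType, character(nEv))
        evX <<- c(evX, numeric(nEv)); evY <<- c(evY, numeric(nEv))
      }
      nEv <<- nEv + 1L
      evCell[nEv] <<- cell; evPar[nEv] <<- parent; evTime[nEv] <<- time
      evType[nEv] <<- type; evX[nEv] <<- x; evY[nEv] <<- y
    }
    ## cell queue; seeded positions keep a hard-core minimum separation
    ## (nuclei cannot overlap at plating), falling back to the best of the
    ## attempted positions when the well is too crowded
    minSep <- 2.2 * spec@nucleusRadius
    sx <- numeric(nCells); sy <- numeric(nCells)
    for (i in seq_len(nCells)) {
      best <- c(stats::runif(1, 0, fieldW), stats::runif(1, 0, fieldH))
      if (i > 1L) {
        bestD <- min(sqrt((sx[seq_len(i - 1L)] - best[1])^2 +
                          (sy[seq_len(i - 1L)] - best[2])^2))
        tries <- 0L
        while (bestD < minSep && tries < 50L) {
          cand <- c(stats::runif(1, 0, fieldW), stats::runif(1, 0, fieldH))
          d <- min(sqrt((sx[seq_len(i - 1L)] - cand[1])^2 +
                        (sy[seq_len(i - 1L)] - cand[2])^2))
          if (d > bestD) { best <- cand; bestD <- d }
          tries <- tries + 1L
        }
      }
      sx[i] <- best[1]; sy[i] <- best[2]
    }
    queue <- vector("list", nCells)
    for (i in seq_len(nCells))
      queue[[i]] <- list(id = i, parent = NA_integer_, birth = t0,
                         x = sx[i], y = sy[i])
    nextId <- nCells + 1L
    qi <- 1L
    while (qi <= length(queue)) {
      cl <- queue[[qi]]; qi <- qi + 1L
      push(cl$id, cl$parent, cl$birth, "birth", cl$x, cl$y)
      cur <- cl$birth
      repeat {
        te <- nextEntry(cur)
        td <- cur + rexpSafe(deathRate)
        if (min(te, td) > tEnd) break
        if (td < te) {
          push(cl$id, cl$parent, td, "interphase_death", cl$x, cl$y)
          break
        }
        push(cl$id, cl$parent, te, "mitosis_entry", cl$x, cl$y)
        arrested <- pArrest > 0 && te >= delay && stats::runif(1) < pArrest
        if (arrested) {
          dur <- stats::runif(1, 2, 10)
          outcome <- sample(names(arrestP), 1L, prob = arrestP)
        } else {
          dur <- stats::runif(1, 0.6, 1.4)
          outcome <- "division"
        }
        tout <- te + dur
        if (tout > tEnd) break   # unresolved mitosis at end of movie
        push(cl$id, cl$parent, tout, outcome, cl$x, cl$y)
        if (outcome == "division") {
          theta <- stats::runif(1, 0, 2 * pi)
          off <- 0.8 * spec@nucleusRadius
          dx <- off * cos(theta); dy <- off * sin(theta)
          for (sgn in c(1, -1)) {
            queue[[length(queue) + 1L]] <- list(
              id = nextId, parent = cl$id, birth = tout,
              x = min(max(cl$x + sgn * dx, 0), fieldW),
              y = min(max(cl$y + sgn * dy, 0), fieldH))
            nextId <- nextId + 1L
          }
          break
        } else if (outcome == "mitotic_death") {
          break
        } else {
          cur <- tout   # mitotic_exit / cytokinesis_failure: cell lives on
        }
      }
    }
    ev <- data.frame(cell = evCell[seq_len(nEv)], parent = evPar[seq_len(nEv)],
                     time = evTime[seq_len(nEv)], event = evType[seq_len(nEv)],
                     x = evX[seq_len(nEv)], y = evY[seq_len(nEv)],
                     stringsAsFactors = FALSE)
    cellEventLog(ev, nSeeded = nCells, timeRange = c(t0, tEnd))
  })
}

#' Fast-path per-well division counts
#'
#' Samples the total number of division events observed in the imaging
#' window for many wells at once, from the law of a linear birth (Yule)
#' process with instantaneous mitosis: the number of births over an
#' interval, given the population at its start, is negative binomial. The
#' per-cell mitosis hazard is `rate` before the penetration `delay` and
#' `rate * multiplier` after it.
#'
#' This is the scalable route for plate-level simulations: scoring-level
#' statistics need only a per-well MitosisCount distribution, and every
#' well on a plate is drawn from the same law. Note that
#' [simulateWell()] additionally models a finite (~1 h) mitosis dwell
#' during which a cell cannot re-enter mitosis, so its division totals
#' over the full 68 h window run below this idealized law; the two
#' simulators are different study conditions, not interchangeable counts.
#'
#' @param nWells number of wells to draw.
#' @param multiplier mitosis-rate multiplier(s) after the delay; recycled
#'   to `nWells`. 1 for null wells, `1 - effect` for viability knockdowns.
#' @param nCells seeded cells per well (default 850).
#' @param rate baseline mitosis hazard, events/cell/h.
#' @param delay penetration delay in hours post-transfection.
#' @param tStart,tEnd observation window in hours (default 4 to 72).
#' @param seed integer seed.
#' @return Integer vector of length `nWells` of division counts.
#' @examples
#' counts <- simulateWellCounts(10, seed = 1)
#' mean(counts)
#' @export
simulateWellCounts <- function(nWells, multiplier = 1, nCells = 850,
                               rate = 0.029, delay = 12, tStart = 4,
                               tEnd = 72, seed = NULL) {
  if (rate < 0) stop("rate must be non-negative")
  if (any(multiplier < 0 | multiplier > 1))
    stop("multiplier must lie in [0, 1]")
  mult <- rep_len(multiplier, nWells)
  withSeed(seed, {
    pop <- rep(as.numeric(nCells), nWells)
    counted <- integer(nWells)
    bounds <- sort(unique(pmax(0, pmin(c(0, delay, tStart, tEnd), tEnd))))
    growStep <- function(pop, r, dt) {
      births <- integer(length(pop))
      if (dt > 0) {
        p <- rep_len(exp(-r * dt), length(pop))
        live <- pop > 0 & p < 1
        if (any(live))
          births[live] <- stats::rnbinom(sum(live), size = pop[live],
                                         prob = p[live])
      }
      births
    }
    for (k in seq_len(length(bounds) - 1L)) {
      a <- bounds[k]; b <- bounds[k + 1L]
      r <- if (b <= delay) rep_len(rate, nWells) else rate * mult
      births <- growStep(pop, r, b - a)
      if (a >= tStart) counted <- counted + births
      pop <- pop + births
    }
    counted
  })
}

#' Generate phenotypic cell event sequences from a fate mixture
#'
#' Draws `n` phenotypic cells whose fates follow `mixture`. Arrest-first
#' fates (mitotic death, mitotic exit, cytokinesis failure) enter mitosis
#' between 20 and 60 h, dwell uniformly on (2, 10] hours in prometaphase
#' (the arrest can last up to ten hours), then resolve with the assigned
#' terminal event. Direct-apoptosis cells die in interphase between 12 and
#' 24 h, without a prior mitosis.
#'
#' @param n number of cells (>= 0).
#' @param mixture a [FateMixture-class].
#' @param spec a [MovieSpec-class], supplying the time range and field
#'   extent.
#' @param seed integer seed.
#' @return A [CellEventLog-class] of `n` single-cell sequences.
#' @examples
#' log <- assignFates(100, seed = 1)
#' table(eventTable(log)$event)
#' @export
assignFates <- function(n, mixture = fateMixture(), spec = movieSpec(),
                        seed = NULL) {
  stopifnot(is(mixture, "FateMixture"))
  n <- as.integer(n)
  if (n < 0) stop("n must be non-negative")
  fieldW <- spec@frameSize[1] * spec@pixelSize
  fieldH <- spec@frameSize[2] * spec@pixelSize
  t0 <- spec@firstTime
  withSeed(seed, {
    fates <- if (n) sample(names(fateProbs(mixture)), n, replace = TRUE,
                           prob = fateProbs(mixture)) else character()
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      x <- stats::runif(1, 0, fieldW); y <- stats::runif(1, 0, fieldH)
      if (fates[i] == "direct_apoptosis") {
        td <- stats::runif(1, 12, 24)
        rows[[i]] <- data.frame(
          cell = i, parent = NA_integer_,
          time = c(t0, td), event = c("birth", "interphase_death"),
          x = x, y = y, stringsAsFactors = FALSE)
      } else {
        te <- stats::runif(1, 20, 60)
        dur <- stats::runif(1, 2, 10)
        rows[[i]] <- data.frame(
          cell = i, parent = NA_integer_,
          time = c(t0, te, te + dur),
          event = c("birth", "mitosis_entry", fates[i]),
          x = x, y = y, stringsAsFactors = FALSE)
      }
    }
    ev <- if (n) do.call(rbind, rows) else
      data.frame(cell = integer(), parent = integer(), time = numeric(),
                 event = character(), x = numeric(), y = numeric(),
                 stringsAsFactors = FALSE)
    cellEventLog(ev, nSeeded = n, timeRange = c(spec@firstTime, spec@lastTime))
  })
}

#' Synthesize ordinal manual phenotype scores
#'
#' Emulates human end-point scoring of movie wells on the ordinal 1
#' (normal) to 5 (strong phenotype) scale. The score is a noisy ordinal
#' link to the latent effect:
#' `clamp(round(1 + 4 * effect + eps), 1, 5)` with
#' `eps ~ Normal(0, noiseSd)`, so the expected score increases
#' monotonically with the effect.
#'
#' @param effects numeric vector of latent effects in [0, 1].
#' @param noiseSd standard deviation of the scoring noise (default 0.5).
#' @param seed integer seed.
#' @return Integer vector of scores in 1..5.
#' @examples
#' synthesizeManualScores(c(0, 0.5, 1), noiseSd = 0)
#' @export
synthesizeManualScores <- function(effects, noiseSd = 0.5, seed = NULL) {
  if (any(effects < 0 | effects > 1)) stop("effects must lie in [0, 1]")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  withSeed(seed, {
    eps <- stats::rnorm(length(effects), 0, noiseSd)
    as.integer(pmin(pmax(round(1 + 4 * effects + eps), 1), 5))
  })
}
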