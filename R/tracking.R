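#' Link per-frame objects into tracks
#'
#' Greedy mutual-nearest-neighbour linker: between an active track's last
#' centroid and the objects of the next frame, a link is made only when
#' the two are each other's nearest candidate and closer than `maxDist`.
#' Unmatched objects start new tracks; a track not extended for more than
#' `maxGap` frames is closed. Ties are broken deterministically by
#' (distance, then track id).
#'
#' Global assignment is deliberately not used: at the cell densities this
#' package simulates, mutual nearest neighbours are unambiguous, and the
#' greedy linker is transparent and fast.
#'
#' @param objects data.frame with columns `frame` (integer, ascending),
#'   `id`, `x`, `y` (pixels), `area` — e.g. the output of
#'   [segmentMovie()].
#' @param maxDist gating radius in pixels. The default (4 px, about half
#'   a nucleus radius) is several sigma above the per-frame Brownian
#'   displacement yet below the separation at which daughter nuclei
#'   appear, so a dividing mother's track ends rather than continuing
#'   into one daughter — the split then registers as two new tracks.
#' @param maxGap maximum number of skipped frames a track survives
#'   (default 1, tolerating single-frame segmentation dropouts).
#' @param gapAreaRatio gap-bridging links (a track absent in the previous
#'   frame) are rejected when the candidate object is more than this
#'   factor larger than the track's last area: an object that doubles in
#'   size across a dropout is a merge of touching nuclei, not the same
#'   cell, and bridging onto it would resurrect ended tracks (notably a
#'   divided mother onto her merged daughters).
#' @return A [TrackSet-class].
#' @examples
#' obj <- data.frame(frame = rep(1:3, each = 2), id = rep(1:2, 3),
#'                   x = rep(c(10, 40), 3), y = rep(c(10, 40), 3), area = 50)
#' tr <- linkTracks(obj, maxDist = 5)
#' length(unique(trackPoints(tr)$track))   # 2 immobile tracks
#' @export
linkTracks <- function(objects, maxDist = 4, maxGap = 1,
                       gapAreaRatio = 1.7) {
  if (maxDist <= 0) stop("maxDist must be positive")
  emptyPts <- data.frame(track = integer(), frame = integer(),
                         object = integer(), x = numeric(), y = numeric(),
                         area = numeric())
  if (!nrow(objects))
    return(new("TrackSet", points = emptyPts,
               parents = data.frame(track = integer(), parent = integer())))
  frames <- sort(unique(objects$frame))
  byFrame <- split(objects, objects$frame)
  ## active endpoints
  act <- data.frame(track = integer(), frame = integer(),
                    x = numeric(), y = numeric(), area = numeric())
  nextTrack <- 1L
  pts <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    obj <- byFrame[[as.character(f)]]
    alive <- act$frame >= f - 1L - maxGap
    act <- act[alive, , drop = FALSE]
    assigned <- rep(NA_integer_, nrow(obj))     # track for each object
    if (nrow(act) && nrow(obj)) {
      D <- outer(act$x, obj$x, "-")^2 + outer(act$y, obj$y, "-")^2
      D <- sqrt(D)
      D[D > maxDist] <- Inf
      gap <- act$frame < f - 1L
      if (any(gap))
        D[gap, ] <- ifelse(outer(act$area[gap] * gapAreaRatio, obj$area,
                                 ">="), D[gap, , drop = FALSE], Inf)
      ## mutual nearest neighbours, deterministic order
      repeat {
        if (!any(is.finite(D))) break
        linked <- FALSE
        ord <- order(act$track)
        for (i in ord) {
          if (!any(is.finite(D[i, ]))) next
          j <- which.min(D[i, ])
          if (which.min(D[, j]) == i) {
            assigned[j] <- i
            D[i, ] <- Inf
            D[, j] <- Inf
            linked <- TRUE
          }
        }
        if (!linked) break
      }
    }
    trackOf <- integer(nrow(obj))
    for (j in seq_len(nrow(obj))) {
      if (!is.na(assigned[j])) {
        trackOf[j] <- act$track[assigned[j]]
      } else {
        trackOf[j] <- nextTrack
        nextTrack <- nextTrack + 1L
      }
    }
    pts[[fi]] <- data.frame(track = trackOf, frame = f, object = obj$id,
                            x = obj$x, y = obj$y, area = obj$area)
    ## update endpoints
    upd <- data.frame(track = trackOf, frame = f, x = obj$x, y = obj$y,
                      area = obj$area)
    act <- act[!(act$track %in% trackOf), , drop = FALSE]
    act <- rbind(act, upd)
  }
  points <- do.call(rbind, pts)
  points <- points[order(points$track, points$frame), , drop = FALSE]
  rownames(points) <- NULL
  new("TrackSet", points = points,
      parents = data.frame(track = integer(), parent = integer()))
}

#' Detect mitoses as track splits
#'
#' A mitotic event is emitted when a track ends at frame `f` and at least
#' two new tracks begin within `(f, f + window]` frames, each within
#' `radius` pixels of the parent's last centroid. Every candidate new
#' track is first attributed to its nearest eligible ending track (so
#' simultaneous nearby divisions cannot steal each other's daughters);
#' an ending track owning two or more candidates emits one event with
#' exactly its two nearest as daughters (ties broken by distance, then
#' track id); each new track is consumed by at most one event. Parents
#' are processed in order of end frame, then track id, so daughter
#' assignment is deterministic.
#'
#' @param tracks a [TrackSet-class] from [linkTracks()].
#' @param radius spatial gate in pixels (default twice the nucleus radius
#'   of the default [movieSpec()], the anaphase displacement scale).
#' @param window temporal gate in frames (default 2, i.e. 1 h at the
#'   default interval).
#' @return A list with `events` (data.frame: `frame` of the split = the
#'   parent's last frame, `parent`, `daughter1`, `daughter2`, `x`, `y`)
#'   and `tracks` (the TrackSet with parents filled in).
#' @export
detectSplits <- function(tracks, radius = 2 * nucleusRadiusPx(movieSpec()),
                         window = 2) {
  pt <- trackPoints(tracks)
  emptyEv <- data.frame(frame = integer(), parent = integer(),
                        daughter1 = integer(), daughter2 = integer(),
                        x = numeric(), y = numeric())
  if (!nrow(pt)) return(list(events = emptyEv, tracks = tracks))
  lastFrame <- max(pt$frame)
  firstOf <- do.call(rbind, lapply(split(pt, pt$track), function(tp) {
    tp[which.min(tp$frame), c("track", "frame", "x", "y")]
  }))
  lastOf <- do.call(rbind, lapply(split(pt, pt$track), function(tp) {
    tp[which.max(tp$frame), c("track", "frame", "x", "y")]
  }))
  ## parents: tracks that end before the movie does
  ends <- lastOf[lastOf$frame < lastFrame, , drop = FALSE]
  ends <- ends[order(ends$frame, ends$track), , drop = FALSE]
  ## candidate daughters: tracks that start after the first frame
  starts <- firstOf[firstOf$frame > min(pt$frame), , drop = FALSE]
  evs <- list()
  if (nrow(ends) && nrow(starts)) {
    ## each new track belongs to its nearest eligible ending track, so
    ## simultaneous nearby divisions cannot steal each other's daughters
    D <- outer(ends$x, starts$x, "-")^2 + outer(ends$y, starts$y, "-")^2
    D <- sqrt(D)
    gateOk <- outer(ends$frame, starts$frame,
                    function(fe, fs) fs > fe & fs <= fe + window) &
              D <= radius &
              outer(ends$track, starts$track, "!=")
    D[!gateOk] <- Inf
    owner <- apply(D, 2L, function(col) {
      if (!any(is.finite(col))) NA_integer_ else which.min(col)
    })
    for (k in order(ends$frame, ends$track)) {
      mine <- which(!is.na(owner) & owner == k)
      if (length(mine) < 2L) next
      d <- D[k, mine]
      ord <- order(d, starts$track[mine])
      pick <- starts$track[mine[ord[1:2]]]
      pe <- ends[k, ]
      evs[[length(evs) + 1L]] <- data.frame(
        frame = pe$frame, parent = pe$track,
        daughter1 = min(pick), daughter2 = max(pick), x = pe$x, y = pe$y)
    }
  }
  events <- if (length(evs)) do.call(rbind, evs) else emptyEv
  rownames(events) <- NULL
  parents <- if (nrow(events))
    data.frame(track = c(events$daughter1, events$daughter2),
               parent = rep(events$parent, 2L)) else
    data.frame(track = integer(), parent = integer())
  list(events = events,
       tracks = new("TrackSet", points = pt, parents = parents))
}

#' MitosisCount of a well
#'
#' The MitosisCount is the total number of mitotic events observed in a
#' well over all time points, one per detected track split.
#'
#' @param events the `events` data.frame from [detectSplits()] (or any
#'   object with one row per event).
#' @return Integer count.
#' @examples
#' mitosisCount(data.frame())   # 0
#' @export
mitosisCount <- function(events) {
  if (is.null(events)) return(0L)
  nrow(as.data.frame(events))
}

#' Summarize the tracks of one well
#'
#' Per-well track statistics: MitosisCount, number of apoptotic track
#' terminations (track ends before the movie does, is not a split parent,
#' and its area collapses by more than 50% over its last two frames
#' relative to the track's median area), track count and mean track
#' length.
#'
#' @param tracks a [TrackSet-class].
#' @param events split events from [detectSplits()].
#' @param plate,well identifiers carried into the output row.
#' @return One-row data.frame: `plate`, `well`, `mitosisCount`,
#'   `apoptoticTerminations`, `nTracks`, `meanTrackLength`.
#' @export
summarizeWellTracks <- function(tracks, events, plate = "P001",
                                well = "A01") {
  pt <- trackPoints(tracks)
  nTracks <- length(unique(pt$track))
  if (!nTracks)
    return(data.frame(plate = plate, well = well, mitosisCount = 0L,
                      apoptoticTerminations = 0L, nTracks = 0L,
                      meanTrackLength = 0))
  lens <- tapply(pt$frame, pt$track, length)
  lastFrame <- max(pt$frame)
  splitParents <- if (nrow(events)) events$parent else integer()
  apo <- 0L
  for (tp in split(pt, pt$track)) {
    tid <- tp$track[1]
    if (max(tp$frame) >= lastFrame || tid %in% splitParents) next
    tp <- tp[order(tp$frame), , drop = FALSE]
    tail2 <- utils::tail(tp$area, 2)
    if (min(tail2) < 0.5 * stats::median(tp$area)) apo <- apo + 1L
  }
  data.frame(plate = plate, well = well,
             mitosisCount = mitosisCount(events),
             apoptoticTerminations = apo, nTracks = nTracks,
             meanTrackLength = mean(lens))
}

#' Full imaging path for one well
#'
#' Renders the event log, segments the chromatin channel, links tracks and
#' detects splits; the resulting MitosisCount agrees with the event-level
#' division count within the tracking tolerance on default movies.
#'
#' @param log a [CellEventLog-class].
#' @param spec a [MovieSpec-class].
#' @param seed integer seed for rendering.
#' @param ... passed to [segmentNuclei()] via [segmentMovie()].
#' @return A list with `objects`, `tracks`, `events`, `summary`.
#' @export
trackWell <- function(log, spec = movieSpec(), seed = NULL, ...) {
  mv <- renderMovie(log, spec, seed = seed)
  obj <- segmentMovie(mv$h2b,
                      minArea = 0.25 * nominalNucleusArea(spec), ...)
  tr <- linkTracks(obj, maxDist = 0.52 * nucleusRadiusPx(spec), maxGap = 1)
  sp <- detectSplits(tr, radius = 2 * nucleusRadiusPx(spec), window = 2)
  list(objects = obj, tracks = sp$tracks, events = sp$events,
       summary = summarizeWellTracks(sp$tracks, sp$events))
}
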