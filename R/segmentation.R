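#' Segment nuclei in one frame
#'
#' Standard intensity pipeline for uniformly illuminated fluorescence
#' frames: Gaussian smoothing, global thresholding by between-class
#' variance maximization (Otsu), distance-transform watershed to split
#' touching nuclei, and an area filter. The pipeline is intensity-scale
#' invariant: multiplying the frame by a positive constant leaves the mask
#' unchanged.
#'
#' A global threshold always "finds" structure in a signal-free frame, so
#' a multiplicative contrast gate rejects frames whose above-threshold
#' mean is less than `minContrast` times the below-threshold mean; such
#' frames (and constant frames) yield an empty mask.
#'
#' @param frame numeric matrix, non-negative intensities, indexed
#'   `[x + 1, y + 1]` (x = column/width).
#' @param smoothSigma Gaussian smoothing sigma in pixels.
#' @param minArea minimum object area in px^2; the recommended default is
#'   25% of the nominal nucleus area ([nominalNucleusArea()]), which
#'   intentionally drops apoptotic fragments (they are recovered as track
#'   terminations downstream).
#' @param minContrast foreground/background mean-ratio gate (default 1.5).
#' @param tolerance watershed tolerance (passed to [EBImage::watershed()]);
#'   the default 0.5 px splits daughter-nucleus pairs whose distance-map
#'   saddle sits less than 1 px below the two maxima.
#' @return Integer label matrix of the same shape: 0 = background, labels
#'   contiguous 1..K.
#' @examples
#' sp <- movieSpec(frameSize = c(96, 96), lastTime = 8)
#' log <- simulateWell(nCells = 4, spec = sp, seed = 2)
#' mv <- renderMovie(log, sp, seed = 2)
#' mask <- segmentNuclei(mv$h2b[, , 1])
#' max(mask)
#' @export
segmentNuclei <- function(frame, smoothSigma = 2,
                          minArea = 0.25 * nominalNucleusArea(movieSpec()),
                          minContrast = 1.5, tolerance = 0.5) {
  if (!is.matrix(frame) || !length(frame)) stop("frame must be a non-empty matrix")
  empty <- matrix(0L, nrow(frame), ncol(frame))
  rng <- range(frame)
  if (diff(rng) == 0) return(empty)             # constant frame
  norm <- (frame - rng[1]) / diff(rng)          # scale/offset invariant
  sm <- EBImage::gblur(EBImage::Image(norm), sigma = smoothSigma)
  th <- EBImage::otsu(sm, range = c(0, 1))
  mask <- sm > th
  if (!any(mask) || all(mask)) return(empty)
  fg <- mean(frame[mask]); bg <- mean(frame[!mask])
  if (bg <= 0 || fg / bg < minContrast) return(empty)
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  lab <- EBImage::imageData(lab)
  ## area filter + contiguous relabeling
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= minArea)
  if (!length(keep)) return(empty)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  out <- empty
  pos <- lab > 0
  out[pos] <- remap[lab[pos]]
  out
}

#' Measure segmented objects
#'
#' One row per label: intensity-weighted centroid (0-based pixel
#' coordinates, x = column), area, mean intensity and eccentricity
#' (via [EBImage::computeFeatures.moment()] /
#' [EBImage::computeFeatures.shape()]).
#'
#' @param mask integer label matrix from [segmentNuclei()].
#' @param frame intensity matrix of the same shape.
#' @return data.frame with columns `id`, `x`, `y`, `area`,
#'   `meanIntensity`, `eccentricity`.
#' @export
measureObjects <- function(mask, frame) {
  if (!all(dim(mask) == dim(frame)))
    stop("mask and frame shapes differ")
  K <- max(mask)
  if (K == 0L)
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      area = numeric(), meanIntensity = numeric(),
                      eccentricity = numeric()))
  mom <- EBImage::computeFeatures.moment(mask, frame)
  shp <- EBImage::computeFeatures.shape(mask)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                       dimnames = list(NULL, names(mom)))
  if (is.null(dim(shp))) shp <- matrix(shp, nrow = 1,
                                       dimnames = list(NULL, names(shp)))
  meanInt <- as.numeric(tapply(frame[mask > 0], mask[mask > 0], mean))
  data.frame(id = seq_len(K),
             x = mom[, "m.cx"] - 1,   # EBImage centroids are 1-based
             y = mom[, "m.cy"] - 1,
             area = shp[, "s.area"],
             meanIntensity = meanInt,
             eccentricity = mom[, "m.eccentricity"],
             row.names = NULL)
}

#' Segment and measure every frame of a movie channel
#'
#' Convenience wrapper applying [segmentNuclei()] and [measureObjects()]
#' per frame and stacking the results.
#'
#' @param channel numeric array `[x, y, frame]`.
#' @param ... passed to [segmentNuclei()].
#' @return data.frame with a `frame` column (1-based index) plus the
#'   [measureObjects()] columns.
#' @export
segmentMovie <- function(channel, ...) {
  out <- lapply(seq_len(dim(channel)[3]), function(f) {
    fr <- channel[, , f]
    tab <- measureObjects(segmentNuclei(fr, ...), fr)
    if (nrow(tab)) cbind(frame = f, tab) else
      cbind(frame = integer(), tab)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
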