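## Rendering turns a CellEventLog into two-channel synthetic microscopy
## frames. The chromatin (H2B, red) channel is the analysis channel:
## interphase nuclei are Gaussian blobs, mitotic nuclei render condensed
## (smaller, brighter), dying cells fragment into small blobs and vanish,
## and a division replaces one blob with two separating blobs. The tubulin
## (green) channel is decorative and is not segmented.

.addBlob <- function(img, cx, cy, sigma, amp) {
  W <- nrow(img); H <- ncol(img)
  r <- ceiling(4 * sigma)
  xs <- max(1L, floor(cx + 1 - r)):min(W, ceiling(cx + 1 + r))
  ys <- max(1L, floor(cy + 1 - r)):min(H, ceiling(cy + 1 + r))
  if (!length(xs) || !length(ys)) return(img)
  gx <- exp(-((xs - 1 - cx)^2) / (2 * sigma^2))
  gy <- exp(-((ys - 1 - cy)^2) / (2 * sigma^2))
  img[xs, ys] <- img[xs, ys] + amp * outer(gx, gy)
  img
}

#' Render a two-channel movie from a cell event log
#'
#' Produces synthetic time-lapse frames of the well described by `log`.
#' Each alive cell renders as a Gaussian-profile nucleus in the chromatin
#' channel; between mitosis entry and resolution the nucleus is condensed
#' (0.75x radius, 1.8x brighter); for one hour after a death the cell
#' renders as >= 3 small fragments and then vanishes; a division replaces
#' the mother blob with two daughter blobs born roughly 1.6 nucleus radii
#' apart (newborn nuclei render compact for their first hour, as
#' re-forming telophase nuclei are). Cells move by a per-frame Brownian
#' walk (`spec@brownianStep`)
#' with hard-core volume exclusion (nuclei repel below 2 radii, as
#' physical nuclei cannot interpenetrate). Frames carry a constant
#' background plus Gaussian noise.
#'
#' Frames are matrices indexed `[x + 1, y + 1]` with 0-based pixel
#' coordinates, x = column (image width), consistent with
#' [measureObjects()].
#'
#' @param log a [CellEventLog-class]; event times must lie within the
#'   spec's time range. An empty log yields pure-background frames.
#' @param spec a [MovieSpec-class].
#' @param seed integer seed (motion, fragment geometry and noise).
#' @return A list with elements `h2b` and `tub` (numeric arrays of
#'   dimension `c(frameSize, nFrames)`), `spec`, and `times` (frame times
#'   in hours).
#' @examples
#' sp <- movieSpec(frameSize = c(96, 96), lastTime = 10)
#' log <- simulateWell(nCells = 5, spec = sp, seed = 1)
#' mv <- renderMovie(log, sp, seed = 1)
#' dim(mv$h2b)
#' @export
renderMovie <- function(log, spec = movieSpec(), seed = NULL) {
  times <- frameTimes(spec)
  W <- spec@frameSize[1]; H <- spec@frameSize[2]
  nF <- length(times)
  ev <- eventTable(log)
  if (nrow(ev) && (min(ev$time) < spec@firstTime - 1e-9 ||
                   max(ev$time) > spec@lastTime + 1e-9))
    stop("log events outside the movie's time range")
  rPx <- nucleusRadiusPx(spec)
  sigmaNuc <- sqrt((rPx / 2)^2 + spec@psfSigma^2)
  stepPx <- spec@brownianStep / spec@pixelSize
  minSep <- 2 * rPx         # hard-core diameter: nuclei do not interpenetrate
  margin <- 2.5 * rPx       # nuclei keep clear of the field border
  reflect <- function(p, lo, hi) {
    p <- ifelse(p < lo, 2 * lo - p, p)
    p <- ifelse(p > hi, 2 * hi - p, p)
    pmin(pmax(p, lo), hi)
  }
  withSeed(seed, {
    cells <- if (nrow(ev)) split(ev, ev$cell) else list()
    info <- lapply(cells, function(ce) {
      ce <- ce[order(ce$time), , drop = FALSE]
      term <- ce[ce$event %in% c("division", "mitotic_death",
                                 "interphase_death"), , drop = FALSE]
      entries <- ce$time[ce$event == "mitosis_entry"]
      resolves <- ce$time[ce$event %in% .MITOSIS_OUTCOMES]
      mit <- cbind(entries,
                   vapply(entries, function(te) {
                     after <- resolves[resolves > te]
                     if (length(after)) min(after) else Inf
                   }, numeric(1)))
      nFrag <- sample(3:5, 1)
      fragTheta <- stats::runif(nFrag, 0, 2 * pi)
      fragR <- stats::runif(nFrag, 0.3, 0.9) * rPx
      list(id = ce$cell[1], parent = ce$parent[1],
           birth = ce$time[ce$event == "birth"][1],
           endTime = if (nrow(term)) term$time[1] else Inf,
           deathTime = if (nrow(term) && term$event[1] != "division")
             term$time[1] else Inf,
           mit = mit,
           failures = ce$time[ce$event == "cytokinesis_failure"],
           x0 = ce$x[1] / spec@pixelSize, y0 = ce$y[1] / spec@pixelSize,
           fdx = fragR * cos(fragTheta), fdy = fragR * sin(fragTheta),
           nFrag = nFrag)
    })
    if (length(info)) names(info) <- vapply(info, function(i)
      as.character(i$id), character(1))
    ## frame-by-frame global position update with hard-core repulsion
    posX <- numeric(0); posY <- numeric(0)   # named by cell id
    lastPos <- list()                        # final position of ended cells
    divDir <- list(); divSign <- list()
    h2b <- array(0, dim = c(W, H, nF))
    tub <- array(0, dim = c(W, H, nF))
    ids <- names(info)
    for (f in seq_len(nF)) {
      t <- times[f]
      alive <- vapply(info, function(i)
        t >= i$birth - 1e-9 && t < min(i$endTime, i$deathTime) - 1e-9,
        logical(1))
      frag <- vapply(info, function(i)
        is.finite(i$deathTime) && t >= i$deathTime - 1e-9 &&
          t <= i$deathTime + 1, logical(1))
      ## retire cells that are neither alive nor fragmenting
      gone <- setdiff(names(posX), ids[alive | frag])
      for (g in gone) lastPos[[g]] <- c(posX[[g]], posY[[g]])
      posX <- posX[setdiff(names(posX), gone)]
      posY <- posY[setdiff(names(posY), gone)]
      ## activate newly appearing cells (in id order, deterministic)
      for (id in ids[(alive | frag) & !(ids %in% names(posX))]) {
        i <- info[[id]]
        pid <- as.character(i$parent)
        pp <- if (!is.na(i$parent)) {
          if (pid %in% names(posX)) c(posX[[pid]], posY[[pid]])
          else lastPos[[pid]]
        } else NULL
        if (!is.null(pp)) {
          if (is.null(divDir[[pid]])) {
            ## pick a separation axis that keeps both daughters inside the
            ## margin, so border divisions do not collapse onto the mother
            theta <- stats::runif(1, 0, 2 * pi)
            for (try in 1:20) {
              dd <- 1.0 * rPx * c(cos(theta), sin(theta))
              ok <- all(c(pp + dd, pp - dd) >= margin) &&
                    all((pp + dd)[1] <= W - 1 - margin,
                        (pp - dd)[1] <= W - 1 - margin,
                        (pp + dd)[2] <= H - 1 - margin,
                        (pp - dd)[2] <= H - 1 - margin)
              if (ok) break
              theta <- stats::runif(1, 0, 2 * pi)
            }
            divDir[[pid]] <- c(cos(theta), sin(theta))
            divSign[[pid]] <- 1
          }
          sgn <- divSign[[pid]]; divSign[[pid]] <- -sgn
          p <- pp + sgn * 1.0 * rPx * divDir[[pid]]
        } else {
          p <- c(i$x0, i$y0)
        }
        posX[[id]] <- reflect(p[1], margin, W - 1 - margin)
        posY[[id]] <- reflect(p[2], margin, H - 1 - margin)
      }
      ## Brownian step for alive cells (fragmenting cells stay frozen)
      mob <- ids[alive]
      mob <- mob[mob %in% names(posX)]
      if (length(mob) && stepPx > 0) {
        posX[mob] <- posX[mob] + stats::rnorm(length(mob), 0, stepPx)
        posY[mob] <- posY[mob] + stats::rnorm(length(mob), 0, stepPx)
      }
      ## volume exclusion: push overlapping alive nuclei apart
      if (length(mob) > 1L) {
        for (it in 1:8) {
          xs <- posX[mob]; ys <- posY[mob]
          moved <- FALSE
          for (a in seq_len(length(mob) - 1L)) {
            for (b in seq.int(a + 1L, length(mob))) {
              dx <- xs[b] - xs[a]; dy <- ys[b] - ys[a]
              d <- sqrt(dx^2 + dy^2)
              if (d < minSep) {
                if (d < 1e-6) { dx <- 1; dy <- 0; d <- 1 }
                push <- (minSep - d) / 2
                xs[a] <- xs[a] - push * dx / d; ys[a] <- ys[a] - push * dy / d
                xs[b] <- xs[b] + push * dx / d; ys[b] <- ys[b] + push * dy / d
                moved <- TRUE
              }
            }
          }
          posX[mob] <- xs; posY[mob] <- ys
          if (!moved) break
        }
      }
      if (length(posX)) {
        ## reflecting walls: nuclei stay clear of the border (no truncated
        ## blobs) without piling up on the boundary as clamping would
        posX[] <- reflect(posX, margin, W - 1 - margin)
        posY[] <- reflect(posY, margin, H - 1 - margin)
      }
      ## render
      imgN <- matrix(0, W, H)
      imgT <- matrix(0, W, H)
      for (id in names(posX)) {
        i <- info[[id]]
        cx <- posX[[id]]; cy <- posY[[id]]
        if (is.finite(i$deathTime) && t >= i$deathTime - 1e-9) {
          for (j in seq_len(i$nFrag))
            imgN <- .addBlob(imgN, cx + i$fdx[j], cy + i$fdy[j],
                             sigmaNuc * 0.35, 0.5)
          next
        }
        inMitosis <- nrow(i$mit) &&
          any(t >= i$mit[, 1] - 1e-9 & t < i$mit[, 2] - 1e-9)
        newborn <- !is.na(i$parent) && t < i$birth + 1
        enlarge <- if (any(i$failures <= t)) 1.2 else 1
        if (inMitosis) {
          ## condensed chromatin: smaller but brighter
          imgN <- .addBlob(imgN, cx, cy, sigmaNuc * 0.75, 0.9)
          imgT <- .addBlob(imgT, cx, cy, sigmaNuc * 1.5, 0.35)
        } else if (newborn) {
          ## re-forming telophase nuclei are still compact
          imgN <- .addBlob(imgN, cx, cy, sigmaNuc * 0.75, 0.7)
          imgT <- .addBlob(imgT, cx, cy, sigmaNuc * 2, 0.15)
        } else {
          imgN <- .addBlob(imgN, cx, cy, sigmaNuc * enlarge, 0.5)
          imgT <- .addBlob(imgT, cx, cy, sigmaNuc * 2.5, 0.15)
        }
      }
      noiseN <- matrix(stats::rnorm(W * H, 0, spec@shotNoise), W, H)
      noiseT <- matrix(stats::rnorm(W * H, 0, spec@shotNoise), W, H)
      h2b[, , f] <- pmax(imgN + spec@background + noiseN, 0)
      tub[, , f] <- pmax(imgT + spec@background + noiseT, 0)
    }
    list(h2b = h2b, tub = tub, spec = spec, times = times)
  })
}

#' Write / read a movie channel as a multi-frame TIFF stack
#'
#' One file per channel, 32-bit float grayscale, one TIFF directory per
#' frame. `readMovieChannel()` returns the array in the package's
#' `[x, y, frame]` orientation.
#'
#' @param channel numeric array `[x, y, frame]`.
#' @param path output TIFF path.
#' @return `writeMovieChannel()` returns `path` invisibly;
#'   `readMovieChannel()` returns the array.
#' @export
writeMovieChannel <- function(channel, path) {
  frames <- lapply(seq_len(dim(channel)[3]),
                   function(f) t(channel[, , f]))   # TIFF rows = y
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeMovieChannel
#' @export
readMovieChannel <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(frames)) frames <- list(frames)
  arr <- array(0, dim = c(ncol(frames[[1]]), nrow(frames[[1]]),
                          length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- t(frames[[f]])
  arr
}
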