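spSmall <- movieSpec(frameSize = c(96, 96), lastTime = 10)

test_that("empty and constant frames segment to nothing", {
  emptyLog <- cellEventLog(
    data.frame(cell = integer(), parent = integer(), time = numeric(),
               event = character(), x = numeric(), y = numeric()),
    nSeeded = 0, timeRange = c(4, 10))
  mv <- renderMovie(emptyLog, spSmall, seed = 1)
  for (f in c(1, 7, 13))
    expect_identical(max(segmentNuclei(mv$h2b[, , f])), 0L)
  expect_identical(max(segmentNuclei(matrix(0.3, 64, 64))), 0L)
})

test_that("a single immobile interphase cell is one object in every frame", {
  sp <- movieSpec(frameSize = c(96, 96), lastTime = 10, brownianStep = 0)
  ev <- data.frame(cell = 1L, parent = NA_integer_, time = 4,
                   event = "birth", x = 60, y = 60)
  log <- cellEventLog(ev, nSeeded = 1, timeRange = c(4, 10))
  mv <- renderMovie(log, sp, seed = 2)
  for (f in seq_len(nFrames(sp))) {
    expect_identical(max(segmentNuclei(mv$h2b[, , f])), 1L)
    ## independent labeling oracle (plain threshold, no watershed)
    expect_identical(componentCount(mv$h2b[, , f], 0.3), 1L)
  }
})

test_that("a division doubles the component count across its frame", {
  sp <- movieSpec(frameSize = c(96, 96), lastTime = 10, brownianStep = 0)
  ev <- data.frame(cell = c(1, 1, 1, 2, 3), parent = c(NA, NA, NA, 1, 1),
                   time = c(4, 6.2, 7.2, 7.2, 7.2),
                   event = c("birth", "mitosis_entry", "division",
                             "birth", "birth"),
                   x = 60, y = 60)
  log <- cellEventLog(ev, nSeeded = 1, timeRange = c(4, 10))
  mv <- renderMovie(log, sp, seed = 3)
  ## division at t = 7.2 falls between frames 7 (t = 7) and 8 (t = 7.5)
  expect_identical(componentCount(mv$h2b[, , 7], 0.3), 1L)
  expect_identical(componentCount(mv$h2b[, , 8], 0.3), 2L)
  expect_identical(max(segmentNuclei(mv$h2b[, , 8])), 2L)
})

test_that("well-separated nuclei and touching pairs are resolved", {
  mkGauss <- function(centers) {
    img <- matrix(0, 128, 128)
    for (k in seq_len(nrow(centers)))
      for (x in 1:128) img[x, ] <- img[x, ] +
        0.5 * exp(-((x - 1 - centers[k, 1])^2 +
                    ((1:128) - 1 - centers[k, 2])^2) / (2 * 3.97^2))
    img + 0.05
  }
  five <- cbind(c(20, 60, 100, 30, 90), c(20, 30, 25, 90, 95))
  expect_identical(max(segmentNuclei(mkGauss(five))), 5L)
  ## touching disc-profile nuclei at 1.2x radius separation: the union
  ## mask keeps two distance-transform maxima, so the watershed splits it
  mkDiscs <- function(centers, r) {
    img <- matrix(0.02, 128, 128)
    for (k in seq_len(nrow(centers)))
      img[outer((0:127 - centers[k, 1])^2,
                (0:127 - centers[k, 2])^2, "+") <= r^2] <- 0.7
    img
  }
  pair <- cbind(c(55, 55 + 1.2 * 7.7), c(64, 64))
  expect_identical(max(segmentNuclei(mkDiscs(pair, 7.7), smoothSigma = 1)),
                   2L)
})

test_that("segmentation is intensity-scale invariant", {
  log <- simulateWell(nCells = 4, spec = spSmall, seed = 4)
  fr <- renderMovie(log, spSmall, seed = 4)$h2b[, , 3]
  expect_identical(segmentNuclei(fr), segmentNuclei(7.3 * fr))
})

test_that("object measurements recover geometry and intensity", {
  expect_identical(nrow(measureObjects(matrix(0L, 32, 32),
                                       matrix(0, 32, 32))), 0L)
  expect_error(measureObjects(matrix(0L, 32, 32), matrix(0, 16, 16)),
               "shapes differ")
  ## symmetric Gaussian blob centered at (64, 32): centroid within 0.5 px
  img <- matrix(0.02, 128, 64)
  img <- img + 0.6 * exp(-(outer((0:127 - 64)^2, (0:63 - 32)^2, "+")) /
                           (2 * 4^2))
  mask <- segmentNuclei(img, minArea = 20)
  tab <- measureObjects(mask, img)
  expect_identical(nrow(tab), 1L)
  expect_lt(abs(tab$x - 64), 0.5)
  expect_lt(abs(tab$y - 32), 0.5)
  ## rendered disc of radius r: area within 10% of pi r^2
  disc <- matrix(0.02, 96, 96)
  r <- 9
  disc[outer((0:95 - 48)^2, (0:95 - 48)^2, "+") <= r^2] <- 0.8
  tabD <- measureObjects(segmentNuclei(disc, smoothSigma = 0.5,
                                       minArea = 20), disc)
  expect_identical(nrow(tabD), 1L)
  expect_lt(abs(tabD$area - pi * r^2) / (pi * r^2), 0.1)
})

test_that("per-frame object counts track the ground-truth population", {
  sp <- movieSpec(frameSize = c(192, 192), lastTime = 16)
  log <- simulateWell(nCells = 12, rate = 0.05, spec = sp, seed = 21)
  mv <- renderMovie(log, sp, seed = 22)
  obj <- segmentMovie(mv$h2b, minArea = 0.25 * nominalNucleusArea(sp))
  tf <- frameTimes(sp)
  ev <- eventTable(log)
  cells <- split(ev, ev$cell)
  alive <- vapply(tf, function(t) sum(vapply(cells, function(ce) {
    b <- ce$time[ce$event == "birth"][1]
    term <- ce[ce$event %in% c("division", "mitotic_death",
                               "interphase_death"), , drop = FALSE]
    e <- if (nrow(term)) term$time[1] else Inf
    t >= b - 1e-9 && t < e - 1e-9
  }, logical(1))), numeric(1))
  segN <- as.integer(table(factor(obj$frame, levels = seq_along(tf))))
  expect_gte(mean(segN == alive), 0.95)
})

test_that("movie channels round-trip through TIFF stacks", {
  log <- simulateWell(nCells = 3, spec = spSmall, seed = 6)
  mv <- renderMovie(log, spSmall, seed = 6)
  path <- tempfile(fileext = ".tif")
  writeMovieChannel(mv$h2b, path)
  back <- readMovieChannel(path)
  expect_identical(dim(back), dim(mv$h2b))
  expect_lt(max(abs(back - mv$h2b)), 1e-6)   # float32 storage
})
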