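immobile <- function(K, F, spread = 40) {
  do.call(rbind, lapply(seq_len(F), function(f)
    data.frame(frame = f, id = seq_len(K), x = spread * seq_len(K),
               y = spread * seq_len(K), area = 150)))
}

test_that("immobile objects give one full-length track each", {
  tr <- linkTracks(immobile(3, 5))
  pt <- trackPoints(tr)
  expect_identical(length(unique(pt$track)), 3L)
  expect_true(all(tapply(pt$frame, pt$track, length) == 5))
})

test_that("a vanishing object ends its track", {
  obj <- immobile(2, 6)
  obj <- obj[!(obj$id == 2 & obj$frame > 3), ]
  tr <- linkTracks(obj)
  pt <- trackPoints(tr)
  ends <- tapply(pt$frame, pt$track, max)
  expect_identical(sort(as.integer(ends)), c(3L, 6L))
})

test_that("jumps beyond the gate start new tracks", {
  ## two objects jump > maxDist between frames -> 4 tracks; brute-force
  ## check that no cross-frame pairing lies within the gate
  obj <- data.frame(frame = c(1, 1, 2, 2), id = c(1, 2, 1, 2),
                    x = c(10, 50, 30, 75), y = c(10, 50, 30, 75), area = 150)
  gate <- 4
  d <- outer(seq_len(2), seq_len(2), function(i, j)
    sqrt((obj$x[i] - obj$x[j + 2])^2 + (obj$y[i] - obj$y[j + 2])^2))
  expect_true(all(d > gate))
  tr <- linkTracks(obj, maxDist = gate)
  expect_identical(length(unique(trackPoints(tr)$track)), 4L)
})

test_that("a synthetic split yields exactly one event; scatter yields none", {
  mother <- data.frame(frame = 1:4, id = 1, x = 50, y = 50, area = 150)
  daughters <- data.frame(frame = rep(5:8, each = 2), id = rep(2:3, 4),
                          x = rep(c(44, 56), 4), y = 50,
                          area = 110)
  tr <- linkTracks(rbind(mother, daughters,
                         immobile(1, 8, spread = 130)))  # bystander
  res <- detectSplits(tr, radius = 15, window = 2)
  expect_identical(mitosisCount(res$events), 1L)
  expect_identical(res$events$frame, 4L)
  expect_identical(nrow(trackParents(res$tracks)), 2L)
  ## a death plus two unrelated distant births -> no event
  dead <- data.frame(frame = 1:4, id = 1, x = 50, y = 50, area = 150)
  births <- data.frame(frame = rep(5:8, each = 2), id = rep(2:3, 4),
                       x = rep(c(100, 10), 4), y = rep(c(100, 10), 4),
                       area = 150)
  d2 <- detectSplits(linkTracks(rbind(dead, births)), radius = 15, window = 2)
  expect_identical(mitosisCount(d2$events), 0L)
  ## no divisions at all
  d3 <- detectSplits(linkTracks(immobile(4, 6)), radius = 15, window = 2)
  expect_identical(mitosisCount(d3$events), 0L)
})

test_that("daughter assignment ties break by distance then track id", {
  mother <- data.frame(frame = 1:3, id = 1, x = 50, y = 50, area = 150)
  ## three candidates: two at distance 6, one at 10; the two nearest win
  cands <- data.frame(frame = 4, id = 2:4, x = c(44, 56, 60),
                      y = 50, area = 110)
  tr <- linkTracks(rbind(mother, cands))
  res <- detectSplits(tr, radius = 15, window = 2)
  expect_identical(mitosisCount(res$events), 1L)
  pt <- trackPoints(res$tracks)
  picked <- sort(pt$object[pt$track %in%
    c(res$events$daughter1, res$events$daughter2)])
  expect_equal(picked, c(2, 3))
})

test_that("MitosisCount is invariant to object-id relabeling", {
  sp <- movieSpec(frameSize = c(128, 128), lastTime = 12)
  log <- simulateWell(nCells = 8, rate = 0.06, spec = sp, seed = 41)
  mv <- renderMovie(log, sp, seed = 42)
  obj <- segmentMovie(mv$h2b, minArea = 0.25 * nominalNucleusArea(sp))
  count1 <- mitosisCount(detectSplits(linkTracks(obj))$events)
  ## shuffle ids within each frame (order-preserving relabeling of rows)
  set.seed(1)
  obj2 <- do.call(rbind, lapply(split(obj, obj$frame), function(d)
    d[sample(nrow(d)), , drop = FALSE]))
  obj2$id <- ave(obj2$id, obj2$frame, FUN = seq_along)
  count2 <- mitosisCount(detectSplits(linkTracks(obj2))$events)
  expect_identical(count1, count2)
})

test_that("apoptotic terminations are counted from the area collapse", {
  healthy <- immobile(1, 8, spread = 40)
  dying <- data.frame(frame = 1:6, id = 2, x = 100, y = 100,
                      area = c(150, 150, 150, 150, 60, 40))
  tr <- linkTracks(rbind(healthy, dying))
  res <- detectSplits(tr, radius = 15, window = 2)
  s <- summarizeWellTracks(res$tracks, res$events)
  expect_identical(s$apoptoticTerminations, 1L)
  expect_identical(s$nTracks, 2L)
  expect_identical(s$mitosisCount, 0L)
})

test_that("mitosisCount is the event count", {
  expect_identical(mitosisCount(data.frame()), 0L)
  expect_identical(mitosisCount(data.frame(frame = 1:7)), 7L)
})
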