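mkSeq <- function(events, times, x = 50, y = 50) {
  cellEventLog(data.frame(cell = 1L, parent = NA_integer_, time = times,
                          event = events, x = x, y = y),
               nSeeded = 1, timeRange = c(4, 72))
}

test_that("fate rules classify canonical sequences", {
  ## arrested 6 h then died in mitosis
  f1 <- classifyFate(mkSeq(c("birth", "mitosis_entry", "mitotic_death"),
                           c(4, 40, 46)))
  expect_identical(as.character(f1$fate), "mitotic_death")
  expect_equal(f1$arrestDuration, 6)
  ## early interphase death without prior arrest
  f2 <- classifyFate(mkSeq(c("birth", "interphase_death"), c(4, 14)))
  expect_identical(as.character(f2$fate), "direct_apoptosis")
  ## a 1 h mitosis ending in division is normal
  log3 <- cellEventLog(data.frame(
    cell = c(1, 1, 1, 2, 3), parent = c(NA, NA, NA, 1, 1),
    time = c(4, 30, 31, 31, 31),
    event = c("birth", "mitosis_entry", "division", "birth", "birth"),
    x = 50, y = 50), nSeeded = 1, timeRange = c(4, 72))
  f3 <- classifyFate(log3)
  expect_true(all(as.character(f3$fate) == "normal"))
  ## arrest resolving by exit / failure
  f4 <- classifyFate(mkSeq(c("birth", "mitosis_entry", "mitotic_exit"),
                           c(4, 30, 35)))
  expect_identical(as.character(f4$fate), "mitotic_exit")
  f5 <- classifyFate(mkSeq(c("birth", "mitosis_entry", "cytokinesis_failure"),
                           c(4, 30, 39)))
  expect_identical(as.character(f5$fate), "cytokinesis_failure")
  ## unresolved arrest at the end of the movie is 'other'
  f6 <- classifyFate(mkSeq(c("birth", "mitosis_entry"), c(4, 69)))
  expect_identical(as.character(f6$fate), "other")
})

test_that("grammar-invalid sequences are rejected at construction", {
  expect_error(cellEventLog(data.frame(
    cell = 1L, parent = NA_integer_, time = c(4, 10),
    event = c("birth", "division"), x = 0, y = 0),
    nSeeded = 1, timeRange = c(4, 72)))
  expect_error(cellEventLog(data.frame(
    cell = 1L, parent = NA_integer_, time = c(4, 10, 12),
    event = c("birth", "mitosis_entry", "mitosis_entry"), x = 0, y = 0),
    nSeeded = 1, timeRange = c(4, 72)))
})

test_that("classification is the identity on noiseless generator output", {
  for (fate in c("mitotic_death", "mitotic_exit", "cytokinesis_failure",
                 "direct_apoptosis")) {
    p <- as.numeric(fate == c("mitotic_death", "mitotic_exit",
                              "cytokinesis_failure", "direct_apoptosis"))
    log <- assignFates(120, fateMixture(p[1], p[2], p[3], p[4]),
                       seed = 17)
    got <- classifyFate(log)
    expect_true(all(as.character(got$fate) == fate))
  }
})

test_that("fate profiles use the phenotypic denominator", {
  expect_identical(fateProfile(rep("mitotic_death", 7))[["mitotic_death"]], 1)
  mixed <- c(rep("mitotic_death", 3), rep("normal", 5), "mitotic_exit")
  fr <- fateProfile(mixed)
  expect_equal(sum(fr), 1)
  expect_equal(fr[["mitotic_death"]], 3 / 4)   # normals excluded by hand count
  expect_error(fateProfile(rep("normal", 5)), "no phenotypic")
})

test_that("mixture recovery tightens with sample size", {
  p <- fateProbs(fateMixture())
  for (n in c(500, 2000, 10000)) {
    fr <- fateProfile(classifyFate(assignFates(n, seed = n)))
    for (lab in names(p)) {
      se <- sqrt(p[lab] * (1 - p[lab]) / n)
      expect_lt(abs(fr[lab] - p[lab]), 4 * se)
    }
  }
})

test_that("time courses measure mitotic and apoptotic fractions", {
  quiet <- mkSeq("birth", 4)
  tc <- timeCourse(quiet, c(24, 48, 72))
  expect_true(all(tc$mitoticFraction == 0))
  expect_true(all(tc$apoptoticFraction == 0))
  arrested <- mkSeq(c("birth", "mitosis_entry", "mitotic_death"),
                    c(4, 46, 54))
  expect_identical(timeCourse(arrested, 50)$mitoticFraction, 1)
  expect_identical(timeCourse(arrested, 60)$apoptoticFraction, 1)
  expect_error(timeCourse(quiet, 100), "outside")
  ## knockdown wells show a higher mitotic fraction at 60 h than controls
  kd <- simulateWell(wellPhenotype(0.85, "mitotic_arrest"), nCells = 150,
                     rate = 0.035, seed = 61)
  ctrl <- simulateWell(nCells = 150, rate = 0.035, seed = 62)
  expect_gt(timeCourse(kd, 60)$mitoticFraction,
            timeCourse(ctrl, 60)$mitoticFraction)
})

test_that("arrest durations respect the simulator cap", {
  log <- assignFates(400, seed = 3)
  durs <- arrestDurations(log)
  expect_lte(max(durs), 10)
  expect_true(all(durs > fateThresholds()@arrestThreshold))
  quiet <- mkSeq("birth", 4)
  expect_length(arrestDurations(quiet), 0)
})
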