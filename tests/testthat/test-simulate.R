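test_that("event logs obey the grammar and division conservation", {
  for (sd in c(1, 2, 3)) {
    log <- simulateWell(nCells = 40, rate = 0.05,
                        spec = movieSpec(lastTime = 30), seed = sd)
    ev <- eventTable(log)
    expect_true(isTRUE(checkEventGrammar(ev)))
    births <- sum(ev$event == "birth")
    expect_identical(births, 2L * sum(ev$event == "division") + nSeeded(log))
    expect_true(all(ev$time >= 4 - 1e-9 & ev$time <= 30 + 1e-9))
  }
  ## arrest phenotype produces arrest outcomes
  log <- simulateWell(wellPhenotype(0.9, "mitotic_arrest"), nCells = 150,
                      rate = 0.04, spec = movieSpec(lastTime = 40), seed = 5)
  ev <- eventTable(log)
  expect_true(isTRUE(checkEventGrammar(ev)))
  expect_gt(sum(ev$event %in% c("mitotic_death", "mitotic_exit",
                                "cytokinesis_failure")), 0)
})

test_that("seed determinism gives identical logs and movies", {
  sp <- movieSpec(frameSize = c(64, 64), lastTime = 8)
  a <- simulateWell(nCells = 10, spec = sp, seed = 99)
  b <- simulateWell(nCells = 10, spec = sp, seed = 99)
  expect_identical(eventTable(a), eventTable(b))
  expect_identical(renderMovie(a, sp, seed = 7)$h2b,
                   renderMovie(b, sp, seed = 7)$h2b)
})

test_that("division counts follow the simulator's expectation", {
  ## Monte-Carlo oracle: independent discrete-time simulation of the same
  ## process; observed divisions must fall in its 99% interval
  sp <- movieSpec(lastTime = 72)
  set.seed(202)
  oracle <- mcDivisionOracle(200, 0.02, 4, 72, dt = 0.1, reps = 50)
  obs <- divisionCount(simulateWell(nCells = 200, rate = 0.02, spec = sp,
                                    deathRate = 0, seed = 31))
  lo <- mean(oracle) - qnorm(0.995) * sd(oracle)
  hi <- mean(oracle) + qnorm(0.995) * sd(oracle)
  expect_gte(obs, lo)
  expect_lte(obs, hi)
})

test_that("strong viability knockdown stops divisions after the delay", {
  log <- simulateWell(wellPhenotype(1, "viability", penetrationDelay = 12),
                      nCells = 300, rate = 0.03, seed = 8)
  ev <- eventTable(log)
  expect_false(any(ev$event == "division" & ev$time > 16))
  expect_gt(sum(ev$event == "division"), 0)   # pre-delay divisions remain
})

test_that("degenerate simulator inputs are handled", {
  expect_identical(nrow(eventTable(simulateWell(nCells = 0, seed = 1))), 0L)
  expect_error(simulateWell(rate = -1, seed = 1), "non-negative")
  expect_error(simulateWellCounts(5, multiplier = 2), "\\[0, 1\\]")
  expect_identical(simulateWellCounts(4, rate = 0, seed = 1), rep(0L, 4))
})

test_that("fast-path counts match the two-phase branching law", {
  ## mean of the Yule law with a rate change at the delay, computed
  ## analytically as the oracle
  n <- 400; r <- 0.029; e <- 0.85
  counts <- simulateWellCounts(n, nCells = 850, seed = 4)
  expected <- 850 * (exp(r * 72) - exp(r * 4))   # births in [4, 72]
  expect_lt(abs(mean(counts) - expected) / expected, 0.01)
  kd <- simulateWellCounts(n, multiplier = 1 - e, nCells = 850, seed = 5)
  expKd <- 850 * (exp(r * 12) - exp(r * 4)) +
           850 * exp(r * 12) * (exp(r * (1 - e) * 60) - 1)
  expect_lt(abs(mean(kd) - expKd) / expKd, 0.02)
})

test_that("assigned fates recover the mixture and respect the time laws", {
  ## point mass
  log1 <- assignFates(50, fateMixture(1, 0, 0, 0), seed = 1)
  f1 <- classifyFate(log1)
  expect_true(all(f1$fate == "mitotic_death"))
  ## empty
  expect_identical(nrow(eventTable(assignFates(0, seed = 1))), 0L)
  ## invalid mixtures rejected
  expect_error(fateMixture(0.5, 0.5, 0.5, 0.5), "sum to 1")
  expect_error(fateMixture(-0.1, 0.6, 0.25, 0.25), "non-negative")
  ## default mixture recovered within 3 binomial SE at n = 2000
  log <- assignFates(2000, seed = 77)
  fr <- fateProfile(classifyFate(log))
  p <- fateProbs(fateMixture())
  for (lab in names(p)) {
    se <- sqrt(p[lab] * (1 - p[lab]) / 2000)
    expect_lt(abs(fr[lab] - p[lab]), 3 * se + 1e-12)
  }
  ## time laws: arrest durations on (2, 10], direct deaths in [12, 24]
  ev <- eventTable(log)
  durs <- arrestDurations(log)
  expect_true(all(durs > 2 & durs <= 10))
  dd <- ev$time[ev$event == "interphase_death"]
  expect_true(all(dd >= 12 & dd <= 24))
})

test_that("manual scores follow the ordinal link", {
  expect_identical(synthesizeManualScores(0, 0), 1L)
  expect_identical(synthesizeManualScores(1, 0), 5L)
  expect_error(synthesizeManualScores(1.2), "\\[0, 1\\]")
  ## Monte-Carlo monotonicity of the mean score in the effect
  grid <- seq(0, 1, by = 0.25)
  means <- vapply(seq_along(grid), function(i)
    mean(synthesizeManualScores(rep(grid[i], 1e4), 0.5, seed = 100 + i)),
    numeric(1))
  expect_true(all(diff(means) > 0))
})
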