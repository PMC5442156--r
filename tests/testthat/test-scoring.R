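test_that("robust z matches hand computation and conventions", {
  ## hand-recomputed: median 14, raw MAD 2 -> (14-8)/(1.4826*2)
  expect_equal(robustZ(c(10, 12, 14, 16, 18), 8), 6 / (1.4826 * 2),
               tolerance = 1e-12)
  samp <- c(10, 12, 14, 16, 18, 20, 11, 13)
  expect_identical(robustZ(samp, median(samp)), 0)
  expect_error(robustZ(rep(5, 10), 3), "MAD is zero")
  expect_error(robustZ(c(1, 2, 3), 1), "at least 5")
  ## sign: fewer mitoses => positive z
  expect_gt(robustZ(samp, 2), 0)
})

test_that("robust z is location/scale equivariant", {
  set.seed(5)
  for (i in 1:20) {
    samp <- rpois(40, 200); x <- rpois(1, 150)
    a <- runif(1, 0.1, 10); b <- runif(1, -50, 50)
    expect_equal(robustZ(a * samp + b, a * x + b), robustZ(samp, x),
                 tolerance = 1e-9)
  }
})

test_that("null z-scores have the expected tail mass", {
  set.seed(9)
  samp <- rnorm(1e4, 100, 10)
  x <- rnorm(1e4, 100, 10)
  frac <- mean(robustZ(samp, x) < 2)
  expect_gt(frac, 0.96)   # analytic: pnorm(2) = 0.9772
  expect_lt(frac, 0.99)
})

test_that("raw/mnc normalization follows the definition", {
  expect_identical(rawOverMnc(median(c(100, 110, 90)), c(100, 110, 90)), 1)
  expect_identical(rawOverMnc(40, c(100, 110, 90)), 0.4)
  expect_error(rawOverMnc(5, numeric()), "no negative-control")
  expect_error(rawOverMnc(5, c(0, 0)), "positive")
})

test_that("plate scoring normalizes to sample wells only", {
  set.seed(2)
  wells <- data.frame(plate = rep(c("P1", "P2"), each = 30),
                      well = sprintf("W%02d", 1:30),
                      role = rep(c(rep("sample", 26), "positive", "positive",
                                   "negative", "negative"), 2),
                      mitosisCount = c(rpois(30, 300), rpois(30, 500)))
  sc <- scorePlate(wells)
  for (p in c("P1", "P2")) {
    i <- sc$plate == p
    samp <- sc$mitosisCount[i & sc$role == "sample"]
    expect_equal(sc$z[i], robustZ(samp, sc$mitosisCount[i]),
                 tolerance = 1e-12)
  }
})

test_that("primary hit calling matches the stated rules", {
  mk <- function(z, s) data.frame(target = "T", sirna = paste0("s", 1:5),
                                  z = z, manualScore = as.integer(s))
  r1 <- callPrimary(mk(c(2.1, 2.5, 0.3, 0.1, 0.0), c(1, 1, 1, 1, 1)))
  expect_true(r1$target$bioinformaticHit)
  expect_false(r1$target$manualHit)
  r2 <- callPrimary(mk(rep(0, 5), c(3, 3, 2, 2, 1)))
  expect_false(r2$target$manualHit)   # only two scores >= 3
  r3 <- callPrimary(mk(rep(0, 5), c(4, 4, 1, 1, 1)))
  expect_true(r3$target$manualHit)    # two scores >= 4
  r4 <- callPrimary(mk(rep(0.5, 5), rep(1, 5)))
  expect_false(any(unlist(r4$target[-1])))
  expect_error(callPrimary(mk(rep(0, 5), c(0, 1, 1, 1, 1))), "1..5")
  ## z cutoff is inclusive
  r5 <- callPrimary(mk(c(2, 2, 0, 0, 0), rep(1, 5)))
  expect_true(r5$target$bioinformaticHit)
})

test_that("calling agrees with brute-force subset oracles exhaustively", {
  zOpts <- c(0, 3)
  sOpts <- c(1, 3, 4)
  zGrid <- as.matrix(expand.grid(rep(list(zOpts), 5)))
  sGrid <- as.matrix(expand.grid(rep(list(sOpts), 5)))
  for (i in seq_len(nrow(zGrid))) {
    for (j in seq_len(nrow(sGrid))) {
      calls <- data.frame(target = "T", sirna = paste0("s", 1:5),
                          z = zGrid[i, ], manualScore = as.integer(sGrid[j, ]))
      got <- callPrimary(calls)$target
      expect_identical(got$bioinformaticHit, bfBioinformatic(zGrid[i, ]))
      expect_identical(got$manualHit, bfManual(sGrid[j, ]))
    }
  }
})

test_that("validation requires the same siRNAs that had a primary effect", {
  prim <- data.frame(target = "T", sirna = paste0("s", 1:5),
                     primaryEffect = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  mkVal <- function(rm, ms = rep(1L, 5))
    data.frame(target = "T", sirna = paste0("s", 1:5), rawMnc = rm,
               manualScore = ms)
  expect_true(callValidation(prim, mkVal(c(0.7, 0.75, 1, 1, 1)))$validated)
  expect_false(callValidation(prim, mkVal(c(0.9, 0.95, 1, 1, 1)))$validated)
  ## a strong value on a non-effect siRNA must not count
  expect_false(callValidation(prim, mkVal(c(0.5, 0.95, 1, 1, 0.5)))$validated)
  ## manual route validates too
  expect_true(callValidation(prim,
    mkVal(c(0.9, 0.9, 1, 1, 1), c(3L, 4L, 1L, 1L, 1L)))$validated)
  ## missing record for an effect siRNA is rejected
  expect_error(callValidation(prim, mkVal(c(0.7, 0.75, 1, 1, 1))[-1, ]),
               "missing")
})

test_that("validation agrees with a brute-force oracle on random cases", {
  set.seed(33)
  for (i in 1:60) {
    eff <- runif(5) < 0.5
    rm <- round(runif(5, 0.4, 1.2), 2)
    ms <- sample(1:5, 5, replace = TRUE)
    prim <- data.frame(target = "T", sirna = paste0("s", 1:5),
                       primaryEffect = eff)
    val <- data.frame(target = "T", sirna = paste0("s", 1:5),
                      rawMnc = rm, manualScore = ms)
    expect_identical(callValidation(prim, val)$validated,
                     bfValidated(eff, rm, ms))
  }
})

test_that("screen summary arithmetic is consistent", {
  flags <- data.frame(target = paste0("T", 1:10),
                      bioinformaticHit = c(rep(TRUE, 4), rep(FALSE, 6)),
                      manualHit = c(TRUE, TRUE, rep(FALSE, 4), TRUE, TRUE,
                                    TRUE, FALSE),
                      validated = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
                                    TRUE, FALSE, FALSE, FALSE))
  s <- screenCounts(summarizeScreen(flags))
  expect_identical(s[["union"]],
                   s[["bioinformatic"]] + s[["manual"]] - s[["overlap"]])
  expect_identical(s[["bioinformatic"]], 4L)
  expect_identical(s[["manual"]], 5L)
  expect_identical(s[["overlap"]], 2L)
  ## disjoint and identical sets
  dis <- data.frame(target = paste0("T", 1:6),
                    bioinformaticHit = c(TRUE, TRUE, rep(FALSE, 4)),
                    manualHit = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(screenCounts(summarizeScreen(dis))[["union"]], 5L)
  same <- data.frame(target = paste0("T", 1:4),
                     bioinformaticHit = c(TRUE, TRUE, FALSE, FALSE),
                     manualHit = c(TRUE, TRUE, FALSE, FALSE))
  sc <- screenCounts(summarizeScreen(same))
  expect_identical(sc[["union"]], 2L)
  expect_identical(sc[["overlap"]], 2L)
})
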