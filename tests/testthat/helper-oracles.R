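## Independent oracles used across the suite. Each deliberately takes a
## different computational route from the implementation it checks.

## Hit rules by exhaustive subset search (vs the counting rules in
## callPrimary / callValidation).
bfBioinformatic <- function(z, zCut = 2) {
  if (length(z) < 2) return(FALSE)
  any(combn(length(z), 2, function(i) all(z[i] >= zCut)))
}
bfManual <- function(scores, cut = 3, cutHigh = 4) {
  trip <- length(scores) >= 3 &&
    any(combn(length(scores), 3, function(i) all(scores[i] >= cut)))
  pair <- length(scores) >= 2 &&
    any(combn(length(scores), 2, function(i) all(scores[i] >= cutHigh)))
  trip || pair
}
bfValidated <- function(effect, rawMnc, manual, mncCut = 0.8, manualCut = 3) {
  ok <- effect & (rawMnc <= mncCut | manual >= manualCut)
  sum(ok) >= 2
}

## Hypergeometric upper tail by exhaustive enumeration of all draws.
bfHyperTail <- function(k, K, N, n) {
  draws <- combn(N, n)
  inTerm <- seq_len(K)   # term members are ids 1..K by construction
  hits <- apply(draws, 2, function(d) sum(d %in% inTerm))
  mean(hits >= k)
}

## Discrete-time Monte-Carlo of the well process (interphase cells divide
## at the hazard, mitosis dwells ~1 h, two daughters at resolution),
## independent of the continuous-time queue in simulateWell.
mcDivisionOracle <- function(nCells, rate, tStart = 4, tEnd = 72,
                             dt = 0.1, reps = 50) {
  vapply(seq_len(reps), function(r) {
    inter <- nCells
    mitLeft <- numeric(0)     # remaining dwell of cells in mitosis
    div <- 0L
    for (t in seq(tStart, tEnd, by = dt)) {
      if (length(mitLeft)) {
        mitLeft <- mitLeft - dt
        done <- mitLeft <= 0
        div <- div + sum(done)
        inter <- inter + 2L * sum(done)
        mitLeft <- mitLeft[!done]
      }
      entering <- rbinom(1, inter, 1 - exp(-rate * dt))
      if (entering) {
        inter <- inter - entering
        mitLeft <- c(mitLeft, runif(entering, 0.6, 1.4))
      }
    }
    div
  }, numeric(1))
}

## Connected components above an absolute threshold (independent of the
## watershed path in segmentNuclei).
componentCount <- function(frame, threshold) {
  max(EBImage::bwlabel(frame > threshold))
}

## Bipartite greedy matching of detected splits to ground-truth divisions
## (frames within window; distance used as tie-break only, since rendered
## cells drift away from their event-log anchor positions).
matchSplits <- function(events, log, spec, frameWindow = 2) {
  tf <- frameTimes(spec)
  ev <- eventTable(log)
  div <- ev[ev$event == "division", , drop = FALSE]
  evaluable <- div$time < spec@lastTime - frameWindow * spec@frameInterval
  gtF <- vapply(div$time, function(t) max(which(tf < t)), integer(1))
  gx <- div$x / spec@pixelSize; gy <- div$y / spec@pixelSize
  match1 <- function(keep) {
    if (!sum(keep) || !nrow(events))
      return(list(gt = rep(FALSE, sum(keep)), ev = rep(FALSE, nrow(events))))
    idx <- which(keep)
    pairs <- expand.grid(g = seq_along(idx), e = seq_len(nrow(events)))
    pairs$df <- abs(gtF[idx][pairs$g] - events$frame[pairs$e])
    pairs$d <- sqrt((gx[idx][pairs$g] - events$x[pairs$e])^2 +
                    (gy[idx][pairs$g] - events$y[pairs$e])^2)
    pairs <- pairs[pairs$df <= frameWindow & pairs$d <= 60, , drop = FALSE]
    pairs <- pairs[order(pairs$df, pairs$d), , drop = FALSE]
    gu <- rep(FALSE, length(idx)); eu <- rep(FALSE, nrow(events))
    for (i in seq_len(nrow(pairs))) {
      g <- pairs$g[i]; e <- pairs$e[i]
      if (!gu[g] && !eu[e]) { gu[g] <- TRUE; eu[e] <- TRUE }
    }
    list(gt = gu, ev = eu)
  }
  mEval <- match1(evaluable)
  mAll <- match1(rep(TRUE, nrow(div)))
  list(recall = if (sum(evaluable)) mean(mEval$gt) else NA_real_,
       precision = if (nrow(events)) mean(mAll$ev) else NA_real_,
       nEvaluable = sum(evaluable), nDetected = nrow(events))
}

## Run the imaging path on one simulated well and evaluate split detection.
trackingBenchmark <- function(seed, nCells = 20, rate = 0.05,
                              spec = movieSpec(frameSize = c(256, 256),
                                               lastTime = 20)) {
  log <- simulateWell(nCells = nCells, rate = rate, spec = spec, seed = seed)
  res <- trackWell(log, spec, seed = seed + 1L)
  c(matchSplits(res$events, log, spec),
    list(log = log, events = res$events))
}
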