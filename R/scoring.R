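#' Robust z-score of a well against the plate's sample wells
#'
#' Plate normalization for screening statistics:
#' `z = (median(sample) - x) / (1.4826 * MAD(sample))`, where the median
#' and MAD come from the plate's sample wells only (controls excluded).
#' The sign is oriented so that a REDUCED MitosisCount gives a POSITIVE z:
#' positive viability controls, which suppress mitosis, then score z >= 2.
#' The 1.4826 factor makes the MAD a consistent estimator of the standard
#' deviation under normality.
#'
#' @param sampleValues numeric vector of sample-well MitosisCounts
#'   (at least 8 wells).
#' @param x MitosisCount(s) of the well(s) to score; vectorized.
#' @return Numeric z-score(s).
#' @examples
#' robustZ(c(10, 12, 14, 16, 18), 8)   # 2.0235
#' @export
robustZ <- function(sampleValues, x) {
  ## a MAD over fewer than 5 values is too unstable to normalize against;
  ## real plates provide hundreds of sample wells
  if (length(sampleValues) < 5)
    stop("need at least 5 sample wells for plate normalization")
  s <- stats::mad(sampleValues, constant = 1.4826)
  if (s == 0)
    stop("sample-well MAD is zero; robust z undefined (caller may fall back to SD)")
  (stats::median(sampleValues) - x) / s
}

#' Normalize a MitosisCount to the plate's negative controls
#'
#' Validation-screen normalization: the raw MitosisCount divided by the
#' median MitosisCount of the plate's negative-control wells (raw/mnc).
#' Used where a sample-well median is meaningless because the validation
#' plate carries only pre-selected hits.
#'
#' @param x MitosisCount(s); vectorized.
#' @param ncValues MitosisCounts of the negative-control wells (non-empty,
#'   positive median).
#' @return `x / median(ncValues)`.
#' @examples
#' rawOverMnc(40, c(100, 110, 90))   # 0.4
#' @export
rawOverMnc <- function(x, ncValues) {
  if (!length(ncValues)) stop("no negative-control values")
  m <- stats::median(ncValues)
  if (m <= 0) stop("negative-control median must be positive")
  x / m
}

#' Score the wells of one or more plates
#'
#' Adds a robust z column to a well table, normalizing each plate against
#' its own sample wells ([robustZ()]).
#'
#' @param wells data.frame with columns `plate`, `well`, `role` (`sample`
#'   for library wells; anything else is a control) and `mitosisCount`.
#' @return The input with a `z` column appended.
#' @export
scorePlate <- function(wells) {
  stopifnot(all(c("plate", "role", "mitosisCount") %in% names(wells)))
  wells$z <- NA_real_
  for (p in unique(wells$plate)) {
    i <- wells$plate == p
    samp <- wells$mitosisCount[i & wells$role == "sample"]
    wells$z[i] <- robustZ(samp, wells$mitosisCount[i])
  }
  wells
}

#' Call primary-screen hits
#'
#' Applies the primary-screen rules per target:
#' \itemize{
#'   \item bioinformatic hit: at least two siRNAs with z-score >= 2
#'     (`zCut`);
#'   \item manual hit: at least three siRNAs with a manual score >= 3
#'     (`manualCut`) OR at least two siRNAs with a manual score >= 4
#'     (`manualCutHigh`).
#' }
#' The two flags are independent. Each siRNA additionally receives a
#' `primaryEffect` flag — it counted toward either rule (z >= `zCut` or
#' manual score >= `manualCut`) — which the validation screen consumes.
#' The z cutoff is inclusive (z >= 2).
#'
#' @param calls data.frame with columns `target`, `sirna`, `z`,
#'   `manualScore` (integers 1..5), one row per siRNA.
#' @param zCut z-score cutoff (default 2).
#' @param manualCut,manualCutHigh manual-score cutoffs (defaults 3 and 4).
#' @return A list with `sirna` (the input plus `primaryEffect`) and
#'   `target` (data.frame: `target`, `bioinformaticHit`, `manualHit`).
#' @examples
#' calls <- data.frame(target = "T1", sirna = paste0("s", 1:5),
#'                     z = c(2.1, 2.5, 0.3, 0.1, 0),
#'                     manualScore = c(3L, 3L, 2L, 2L, 1L))
#' callPrimary(calls)$target
#' @export
callPrimary <- function(calls, zCut = 2, manualCut = 3, manualCutHigh = 4) {
  stopifnot(all(c("target", "sirna", "z", "manualScore") %in% names(calls)))
  if (!nrow(calls)) stop("each candidate needs at least one siRNA record")
  if (any(calls$manualScore < 1 | calls$manualScore > 5 |
          calls$manualScore != round(calls$manualScore)))
    stop("manual scores must be integers in 1..5")
  calls$primaryEffect <- calls$z >= zCut | calls$manualScore >= manualCut
  agg <- lapply(split(calls, calls$target), function(cc) {
    data.frame(target = cc$target[1],
               bioinformaticHit = sum(cc$z >= zCut) >= 2L,
               manualHit = sum(cc$manualScore >= manualCut) >= 3L |
                           sum(cc$manualScore >= manualCutHigh) >= 2L)
  })
  target <- do.call(rbind, agg)
  rownames(target) <- NULL
  list(sirna = calls, target = target)
}

#' Call validation-screen hits
#'
#' A target validates when at least two of the SAME siRNAs that had an
#' effect in the primary screen (`primaryEffect`) show raw/mnc <= `mncCut`
#' or a manual score >= `manualCut` in the validation screen. siRNAs
#' without a primary effect cannot contribute, however strong their
#' validation values.
#'
#' @param primarySirna the `sirna` table from [callPrimary()] (columns
#'   `target`, `sirna`, `primaryEffect`).
#' @param validation data.frame with columns `target`, `sirna`, `rawMnc`,
#'   `manualScore`, one row per re-screened siRNA. Every primary-effect
#'   siRNA of a target present in `validation` must have a record;
#'   otherwise the call is rejected.
#' @param mncCut raw/mnc cutoff (default 0.8).
#' @param manualCut manual-score cutoff (default 3).
#' @return data.frame `target`, `validated`.
#' @export
callValidation <- function(primarySirna, validation, mncCut = 0.8,
                           manualCut = 3) {
  stopifnot(all(c("target", "sirna", "primaryEffect") %in%
                names(primarySirna)),
            all(c("target", "sirna", "rawMnc", "manualScore") %in%
                names(validation)))
  out <- lapply(split(validation, validation$target), function(vv) {
    tg <- vv$target[1]
    eff <- primarySirna$sirna[primarySirna$target == tg &
                              primarySirna$primaryEffect]
    missing <- setdiff(eff, vv$sirna)
    if (length(missing))
      stop(sprintf("validation records missing for primary-effect siRNA(s) of %s: %s",
                   tg, paste(missing, collapse = ", ")))
    vv <- vv[vv$sirna %in% eff, , drop = FALSE]
    ok <- vv$rawMnc <= mncCut | vv$manualScore >= manualCut
    data.frame(target = tg, validated = sum(ok) >= 2L)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a screen's hit arithmetic
#'
#' Counts bioinformatic hits, manual hits, their overlap and union
#' (`union = bioinformatic + manual - overlap` by construction), validated
#' hits, and validated hits that were called by both primary analyses.
#'
#' @param targetFlags data.frame with columns `target`,
#'   `bioinformaticHit`, `manualHit` and optionally `validated`.
#' @return A [ScreenSummary-class].
#' @export
summarizeScreen <- function(targetFlags) {
  b <- targetFlags$bioinformaticHit
  m <- targetFlags$manualHit
  v <- if ("validated" %in% names(targetFlags)) targetFlags$validated else
    rep(FALSE, nrow(targetFlags))
  v[is.na(v)] <- FALSE
  new("ScreenSummary",
      nBioinformatic = sum(b), nManual = sum(m), nOverlap = sum(b & m),
      nUnion = sum(b | m), nValidated = sum(v),
      nValidatedBoth = sum(v & b & m))
}
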