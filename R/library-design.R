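#' LibraryDesign: an siRNA knockdown library
#'
#' A set of target genes, each covered by one to five sequence-independent
#' siRNAs. The default build mirrors a custom library against 638
#' cancer-deregulated lncRNAs with up to five siRNAs per target and more
#' than 3100 siRNAs in total.
#'
#' @slot targets character vector of target ids.
#' @slot sirnas named list, target id -> character vector of siRNA ids;
#'   siRNA ids are globally unique.
#' @seealso [makeLibrary()]
#' @exportClass LibraryDesign
setClass("LibraryDesign",
  representation(targets = "character", sirnas = "list"))

setValidity("LibraryDesign", function(object) {
  if (!identical(names(object@sirnas), object@targets))
    return("sirnas must be named by targets, in order")
  n <- lengths(object@sirnas)
  if (length(n) && (any(n < 1L) || any(n > 5L)))
    return("every target must have between 1 and 5 siRNAs")
  all <- unlist(object@sirnas, use.names = FALSE)
  if (anyDuplicated(all)) return("siRNA ids must be globally unique")
  TRUE
})

setMethod("show", "LibraryDesign", function(object) {
  cat(sprintf("LibraryDesign: %d targets, %d siRNAs (%s per target)\n",
              length(object@targets), sirnaCount(object),
              if (length(object@targets))
                paste(range(lengths(object@sirnas)), collapse = "-")
              else "0"))
})

#' @describeIn makeLibrary target ids of a library.
#' @param library a [LibraryDesign-class].
#' @export
libraryTargets <- function(library) library@targets

#' @describeIn makeLibrary named list of siRNA ids per target.
#' @export
librarySirnas <- function(library) library@sirnas

#' @describeIn makeLibrary total number of siRNAs in a library.
#' @export
sirnaCount <- function(library) sum(lengths(library@sirnas))

#' Generate a synthetic siRNA library
#'
#' Builds a library of `nTargets` targets with 1-5 siRNAs each. Under the
#' default `"weighted"` policy, per-target counts are drawn from
#' `{max-2, max-1, max}` with weights 0.01 / 0.04 / 0.95, so the default
#' build (638 targets, max 5) carries about 4.94 siRNAs per target and
#' always exceeds 3100 siRNAs in total. Policy `"max"` gives every target
#' exactly `maxSirnasPerTarget` siRNAs.
#'
#' @param nTargets number of targets (>= 0).
#' @param maxSirnasPerTarget maximum siRNAs per target, in 1..5.
#' @param seed integer seed for reproducibility.
#' @param policy `"weighted"` (default) or `"max"`.
#' @return A [LibraryDesign-class].
#' @examples
#' lib <- makeLibrary(seed = 1)
#' length(libraryTargets(lib))   # 638
#' sirnaCount(lib) > 3100        # TRUE
#' @export
makeLibrary <- function(nTargets = 638, maxSirnasPerTarget = 5, seed = NULL,
                        policy = c("weighted", "max")) {
  policy <- match.arg(policy)
  if (nTargets < 0) stop("nTargets must be non-negative")
  if (maxSirnasPerTarget < 1 || maxSirnasPerTarget > 5)
    stop("maxSirnasPerTarget must be between 1 and 5")
  nTargets <- as.integer(nTargets)
  m <- as.integer(maxSirnasPerTarget)
  targets <- sprintf("LNC%04d", seq_len(nTargets))
  counts <- withSeed(seed, {
    if (policy == "max" || m == 1L) {
      rep(m, nTargets)
    } else if (m == 2L) {
      sample(c(1L, 2L), nTargets, replace = TRUE, prob = c(0.05, 0.95))
    } else {
      sample(c(m - 2L, m - 1L, m), nTargets, replace = TRUE,
             prob = c(0.01, 0.04, 0.95))
    }
  })
  sirnas <- lapply(seq_len(nTargets), function(i)
    sprintf("%s_si%d", targets[i], seq_len(counts[i])))
  names(sirnas) <- targets
  new("LibraryDesign", targets = targets, sirnas = sirnas)
}

.POSITIVE_CONTROLS <- c("COPB2", "KIF11", "PLK1")
.NEGATIVE_CONTROLS <- c("NC_A", "NC_B", "NC_D")
.MITOTIC_CONTROLS <- c("MITOTIC_CTRL_1", "MITOTIC_CTRL_2", "MITOTIC_CTRL_3")

#' Lay an siRNA library out on screening plates
#'
#' Distributes every library siRNA exactly once across plates of the given
#' format. Every plate carries duplicated wells of the three positive
#' viability controls (COPB2, KIF11, PLK1), duplicated wells of the three
#' non-targeting negative controls (NC A/B/D), `nEmpty` empty wells, and
#' duplicated wells of three mitotic-defect controls. Control positions are
#' drawn at random per plate (seeded); remaining wells take sample siRNAs
#' in library order, and unfilled wells on the last plate are empty.
#'
#' @param library a [LibraryDesign-class]; must be non-empty.
#' @param plateFormat integer(2), rows and columns (default 16 x 24, i.e.
#'   384-well; the plate format is configurable, not fixed by the assay).
#' @param nEmpty empty wells per plate (default 1).
#' @param seed integer seed for control placement.
#' @return A data.frame with columns `plate`, `well`, `content` (siRNA id
#'   or control label), `role` (`sample`, `positive`, `negative`, `empty`,
#'   `mitotic`).
#' @examples
#' lib <- makeLibrary(60, seed = 1)
#' pl <- makePlates(lib, seed = 1)
#' table(pl$role)
#' @export
makePlates <- function(library, plateFormat = c(16, 24), nEmpty = 1,
                       seed = NULL) {
  sir <- unlist(library@sirnas, use.names = FALSE)
  if (!length(sir)) stop("library is empty: nothing to plate")
  nWells <- prod(plateFormat)
  ctrl <- c(rep(.POSITIVE_CONTROLS, each = 2L),
            rep(.NEGATIVE_CONTROLS, each = 2L),
            rep("EMPTY", nEmpty),
            rep(.MITOTIC_CONTROLS, each = 2L))
  nCtrl <- length(ctrl)
  if (nWells < nCtrl + 1L)
    stop(sprintf("plate format %dx%d too small: needs >= %d control wells plus samples",
                 plateFormat[1], plateFormat[2], nCtrl))
  perPlate <- nWells - nCtrl
  nPlates <- ceiling(length(sir) / perPlate)
  wells <- .wellNames(plateFormat[1], plateFormat[2])
  roleOf <- function(content) {
    ifelse(content %in% .POSITIVE_CONTROLS, "positive",
    ifelse(content %in% .NEGATIVE_CONTROLS, "negative",
    ifelse(content == "EMPTY", "empty",
    ifelse(content %in% .MITOTIC_CONTROLS, "mitotic", "sample"))))
  }
  withSeed(seed, {
    out <- vector("list", nPlates)
    taken <- 0L
    for (p in seq_len(nPlates)) {
      plateId <- sprintf("P%03d", p)
      ctrlPos <- sample(nWells, nCtrl)
      content <- rep(NA_character_, nWells)
      content[ctrlPos] <- sample(ctrl)   # shuffle control identities too
      free <- which(is.na(content))
      avail <- sir[seq.int(taken + 1L, min(taken + perPlate, length(sir)))]
      taken <- taken + length(avail)
      content[free[seq_along(avail)]] <- avail
      content[is.na(content)] <- "EMPTY"
      out[[p]] <- data.frame(plate = plateId, well = wells,
                             content = content, role = roleOf(content),
                             stringsAsFactors = FALSE)
    }
    layout <- do.call(rbind, out)
    rownames(layout) <- NULL
    layout
  })
}
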