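#' iBAQ protein quantification
#'
#' Intensity-based absolute quantification: the sum of all peptide peak
#' intensities of a protein divided by its number of theoretically
#' observable tryptic peptides. Linear in the intensities.
#'
#' @param peptides data.frame with columns `protein`, `peptide`,
#'   `intensity` (>= 0), or a bare numeric vector of intensities for a
#'   single protein.
#' @param nTheoretical named integer vector (or scalar for the
#'   single-protein form) of theoretically observable tryptic peptides per
#'   protein; all >= 1.
#' @return data.frame `protein`, `iBAQ`, `nTheoretical` (for the
#'   single-protein numeric form, a single iBAQ value). Proteins listed in
#'   `nTheoretical` but without peptides get iBAQ 0.
#' @examples
#' computeIbaq(c(10, 20, 30), 3)   # 20
#' @export
computeIbaq <- function(peptides, nTheoretical) {
  if (any(nTheoretical < 1))
    stop("nTheoretical must be at least 1 for every protein")
  if (is.numeric(peptides) && is.null(dim(peptides))) {
    if (length(nTheoretical) != 1L)
      stop("scalar nTheoretical required for a bare intensity vector")
    if (any(peptides < 0)) stop("intensities must be non-negative")
    return(sum(peptides) / nTheoretical)
  }
  stopifnot(all(c("protein", "intensity") %in% names(peptides)))
  if (any(peptides$intensity < 0)) stop("intensities must be non-negative")
  if (is.null(names(nTheoretical)))
    stop("nTheoretical must be named by protein id")
  sums <- tapply(peptides$intensity, peptides$protein, sum)
  prot <- names(nTheoretical)
  s <- ifelse(prot %in% names(sums), sums[prot], 0)
  data.frame(protein = prot, iBAQ = as.numeric(s) / as.numeric(nTheoretical),
             nTheoretical = as.integer(nTheoretical), row.names = NULL)
}

#' Target-versus-control pulldown enrichment
#'
#' Scores each protein by the pseudocount-stabilized log2 ratio of its
#' target-pulldown iBAQ to the mean iBAQ over the control pulldowns:
#' `log2((target + pc) / (mean(controls) + pc))`. A protein is flagged
#' enriched when the ratio reaches `minLog2` AND the protein is detected
#' (iBAQ > 0) in the target pulldown. The mean (not median) across
#' controls matches a two-control pulldown design. The thresholds are not
#' canonical — no standard rule exists for this assay — and are exposed as
#' parameters.
#'
#' @param target iBAQ table of the target pulldown (`protein`, `iBAQ`).
#' @param controls list of one or more control iBAQ tables over the same
#'   protein universe.
#' @param pseudocount stabilizing constant (default 1).
#' @param minLog2 enrichment cutoff in log2 units (default 1).
#' @return data.frame `protein`, `targetIbaq`, `controlMean`, `log2Ratio`,
#'   `enriched`.
#' @export
enrichedProteins <- function(target, controls, pseudocount = 1,
                             minLog2 = 1) {
  if (!is.list(controls) || is.data.frame(controls))
    controls <- list(controls)
  if (!length(controls)) stop("at least one control pulldown is required")
  prot <- target$protein
  ctrl <- sapply(controls, function(cc) {
    if (!setequal(cc$protein, prot))
      stop("control and target pulldowns must share the protein universe")
    cc$iBAQ[match(prot, cc$protein)]
  })
  ctrlMean <- if (is.matrix(ctrl)) rowMeans(ctrl) else ctrl
  l2 <- log2((target$iBAQ + pseudocount) / (ctrlMean + pseudocount))
  data.frame(protein = prot, targetIbaq = target$iBAQ,
             controlMean = ctrlMean, log2Ratio = l2,
             enriched = l2 >= minLog2 & target$iBAQ > 0)
}

#' Hypergeometric term enrichment
#'
#' Over-representation analysis of a protein (or gene) set against an
#' annotation of terms: for each term with `K` members in the universe of
#' size `N`, of which `k` fall in the query set of size `n`, the upper-tail
#' hypergeometric probability `P(X >= k)` is computed and
#' Benjamini-Hochberg adjusted across all tested terms.
#'
#' @param set character vector, the query set (must be a subset of
#'   `universe`).
#' @param annotation data.frame with columns `term`, `protein` (one row
#'   per membership); memberships outside the universe are ignored.
#' @param universe character vector of all assayed ids (non-empty).
#' @return data.frame sorted by p: `term`, `k`, `K`, `n`, `N`, `p`, `fdr`.
#' @examples
#' ann <- data.frame(term = rep("T1", 3), protein = c("a", "b", "c"))
#' termEnrichment(c("a", "b"), ann, letters[1:10])
#' @export
termEnrichment <- function(set, annotation, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  if (!all(set %in% universe)) stop("set must be a subset of the universe")
  set <- unique(set)
  ann <- annotation[annotation$protein %in% universe, , drop = FALSE]
  if (!length(set) || !nrow(ann))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric()))
  N <- length(universe); n <- length(set)
  terms <- split(unique(ann[c("term", "protein")])$protein,
                 unique(ann[c("term", "protein")])$term)
  rows <- lapply(names(terms), function(tm) {
    members <- terms[[tm]]
    K <- length(members)
    k <- length(intersect(members, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulate a pulldown proteomics experiment
#'
#' Generates peptide-intensity tables for one target pulldown and
#' `nControls` control pulldowns over a shared protein universe, with a
#' planted subset of truly enriched proteins whose target intensities are
#' scaled up `foldChange`-fold. Peptide counts per protein are drawn in
#' 3..12; intensities are log-normal.
#'
#' @param nProteins universe size.
#' @param nEnriched number of planted enriched proteins.
#' @param nControls number of control pulldowns (default 2).
#' @param foldChange target/control intensity ratio of planted proteins.
#' @param seed integer seed.
#' @return list with `target` and `controls` (peptide data.frames:
#'   `protein`, `peptide`, `intensity`), `nTheoretical` (named vector) and
#'   `truth` (ids of planted proteins).
#' @export
simulatePulldown <- function(nProteins = 400, nEnriched = 40,
                             nControls = 2, foldChange = 8, seed = NULL) {
  withSeed(seed, {
    prot <- sprintf("PROT%04d", seq_len(nProteins))
    nTheo <- sample(5:40, nProteins, replace = TRUE)
    names(nTheo) <- prot
    truth <- sample(prot, nEnriched)
    base <- stats::rlnorm(nProteins, meanlog = 10, sdlog = 1)
    ## peptide coverage is protein-intrinsic: the same peptides fly in
    ## every pulldown, so counts are drawn once and shared
    nPep <- pmin(sample(3:12, nProteins, replace = TRUE), nTheo)
    mkTable <- function(scale) {
      do.call(rbind, lapply(seq_len(nProteins), function(i) {
        data.frame(protein = prot[i],
                   peptide = sprintf("%s_p%d", prot[i], seq_len(nPep[i])),
                   intensity = stats::rlnorm(nPep[i],
                                             meanlog = log(base[i] * scale[i]),
                                             sdlog = 0.3))
      }))
    }
    target <- mkTable(ifelse(prot %in% truth, foldChange, 1))
    controls <- lapply(seq_len(nControls), function(j) mkTable(rep(1, nProteins)))
    list(target = target, controls = controls, nTheoretical = nTheo,
         truth = truth)
  })
}
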