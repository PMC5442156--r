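## Internal helpers: seeded RNG scoping and stable string hashing so that
## per-well random streams are reproducible functions of (seed, plate, well).

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed` (when non-NULL), evaluates `expr`, and restores
#' the previous RNG state, so seeded simulators do not disturb the caller's
#' random stream.
#'
#' @param seed integer seed or `NULL` (use the current stream).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## 32-bit FNV-1a over a string, reduced to a positive R integer.
.hashString <- function(s) {
  h <- 2166136261 %% 2147483647   # FNV offset basis, kept in integer range
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), b %% 256)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483629L) + 1L
}

#' Derive a per-well RNG seed
#'
#' Stable hash of `(plate, well)` mixed with the run seed, keeping every
#' well's random stream reproducible from a single user-visible seed.
#'
#' @param seed master integer seed.
#' @param plate,well identifiers (coerced to character).
#' @return A positive integer below 2^31.
#' @export
wellSeed <- function(seed, plate, well) {
  h <- .hashString(paste(plate, well, sep = ":"))
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483629) + 1L
}

## Deterministic FNV-1a hash of an arbitrary R object (for run manifests).
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  sprintf("%08x", .hashString(s))
}

.wellNames <- function(nrow, ncol) {
  rows <- strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]][seq_len(nrow)]
  as.vector(t(outer(rows, sprintf("%02d", seq_len(ncol)), paste0)))
}
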