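#' @useDynLib fadkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats hclust as.dist sd setNames rnorm runif
#' @importFrom utils data
NULL

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation helpers never perturb the session stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

check_protein_alphabet <- function(sequence, allow_x = TRUE, what = "sequence") {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ok <- chars %in% AA20 | (allow_x & chars == "X")
  if (!all(ok)) {
    pos <- which(!ok)[1]
    stop(sprintf("invalid residue '%s' at position %d of %s",
                 chars[pos], pos, what), call. = FALSE)
  }
  invisible(chars)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
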