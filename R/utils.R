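#' @keywords internal
"_PACKAGE"

#' @useDynLib evomicro, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom prcomp setNames rgeom
#' @importFrom utils head modifyList write.table read.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

## Run `code` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards. Used where an operation takes its own seed.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Named per-phase RNG streams derived from one master seed, so that turning
## one stochastic phase off (e.g. mutations in a dependency assay) does not
## shift the draws of the others. Streams are stored as .Random.seed blobs.
make_rng_streams <- function(master_seed,
                             phases = c("death", "lottery", "mutation",
                                        "hgt", "shuffle", "init")) {
  streams <- vector("list", length(phases))
  names(streams) <- phases
  for (i in seq_along(phases)) {
    ## stay below 2^31; distinct affine offsets per phase
    set.seed((as.integer(master_seed) + 104729L * i) %% 2147483629L)
    streams[[i]] <- get(".Random.seed", envir = globalenv())
  }
  streams
}

## Evaluate `code` drawing from stream `phase`; returns list(value, streams).
use_stream <- function(streams, phase, code) {
  assign(".Random.seed", streams[[phase]], envir = globalenv())
  value <- force(code)
  streams[[phase]] <- get(".Random.seed", envir = globalenv())
  list(value = value, streams = streams)
}

## Empty-safe integer sequence (from..to, length 0 when to < from).
seq2 <- function(from, to) if (to < from) integer(0) else seq.int(from, to)
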