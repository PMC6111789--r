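#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state; the caller's .Random.seed is restored
# on exit so library functions never clobber user-level reproducibility.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a reproducible stage seed from a master seed
#'
#' All pipeline randomness flows from one master seed. Each stage (and each
#' sample/fraction inside a stage) gets its own seed derived by hashing the
#' stage label with the master seed, so stages can be re-run in isolation and
#' still reproduce the full-pipeline results.
#'
#' @param seed master integer seed.
#' @param label character label of the stage or sub-stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label),
            length(label) == 1L)
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

stop_param <- function(...) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x == round(x) && x >= 1

# shared class -> ploidy-context lookup (subgenome of origin)
SUBGENOME_PLOIDY <- c(both = 6L, A_only = 4L, B_only = 2L)

GENOTYPE_CLASSES <- c("nulliplex", "simplex", "duplex", "triplex", "higher")
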