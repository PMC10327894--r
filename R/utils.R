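#' Derive a component seed from a global seed
#'
#' A counter-based scheme: every stochastic component of a run draws its own
#' seed as a pure function of the global seed and a fixed component index, so
#' adding a new component never perturbs the random streams of existing ones.
#'
#' @param seed Integer global seed.
#' @param index Non-negative integer component counter.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  # SplitMix-style mixing done in doubles; all intermediates stay below 2^53
  # so the arithmetic is exact, and the result stays below 2^31.
  m <- 2147483647 # 2^31 - 1
  x <- (abs(seed) %% m)
  x <- (x * 48271 + 12345 + (index %% m) * 2246822519) %% m
  x <- (x * 69621 + 1013904223) %% m
  as.integer(x)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Coerce (H,W), (H,W,C) or (H,W,C,N) input to a 4-D (H,W,C,N) array.
as_hwcn <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array with at least 2 dimensions")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected 2-, 3- or 4-D array")
  x
}

# Zero-pad the spatial dimensions of a (H,W,C,N) array.
pad_hw <- function(x, p, value = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
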