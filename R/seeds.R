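#' Derive a stage seed from a global seed
#'
#' One global seed fans out to deterministic per-stage, per-item seeds via a
#' small string hash, so cohorts and pipeline runs are reproducible without
#' threading RNG state through every call.
#'
#' @param seed Global integer seed.
#' @param stage Character tag naming the stage (e.g. `"mask"`, `"render"`).
#' @param index Integer item index within the stage.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "mask", 3)
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483629 # prime below 2^31
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% m
  h <- (h * 31 + as.numeric(index) %% m) %% m
  as.integer(h)
}

# run fn under a local RNG state seeded with `seed`, restoring caller state
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
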