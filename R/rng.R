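#' Derive a reproducible child seed from a parent seed and a tag path
#'
#' Hierarchical seed splitting: every stochastic component of the simulator
#' (discharge times, each fibre's jitter/blocking/amplitude streams, baseline
#' noise) draws from its own stream keyed by a tag path, so adding a fibre or
#' a motor unit never perturbs the draws of the others.
#'
#' @param seed integer parent seed.
#' @param ... tags (coerced to character) identifying the component.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "mu1", "fibre", 2)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  tags <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = "."),
                       character(1)), collapse = "/")
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(tags)) {
    h <- (h * 131 + ch) %% m
  }
  # one multiplicative scrambling pass so nearby parent seeds decorrelate
  as.integer((h * 48271) %% m)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
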