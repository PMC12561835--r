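#' @keywords internal
"_PACKAGE"

## Condition helper: all package errors carry class "zoospace_error" plus a
## specific subclass so callers (and tests) can distinguish contract violations.
zs_abort <- function(message, class) {
  stop(structure(
    class = c(class, "zoospace_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

## Deterministic sub-stream seeds. Streams are labelled by strings (channel,
## date, individual ...) so that every sampler gets an independent,
## reproducible RNG stream derived from one user-facing seed. Kept < 2^31.
derive_seed <- function(seed, ...) {
  label <- paste(..., sep = "/")
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 131 + cp) %% 2147480009
  as.integer((as.numeric(seed) * 48271 + h) %% 2147480009)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

clip_range <- function(v, lo, hi) pmin(pmax(v, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
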