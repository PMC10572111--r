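# Internal helpers shared across modules.

# Deterministic per-stage seed derived from one global seed, so pipeline
# stages can be rerun in isolation. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1009123
  as.integer((as.numeric(seed) %% 1000003) * 2011 + h) %% 2147483587L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483587))
  force(expr)
}

assert_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
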