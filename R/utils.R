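# Internal helpers shared across modules.

# Deterministic substream seeds. Mixes an arbitrary number of non-negative
# integers into a single seed < 2^31 via a splitmix-style LCG on doubles
# (exact below 2^53, so no integer overflow).
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  m <- 2147483629
  h <- 17
  for (p in parts) {
    # keep every product below 2^53 so the arithmetic stays exact
    p <- as.numeric(p) %% m
    h <- (h * 48271 + (p %% 65536) * 7919 + (p %/% 65536) * 104729 + 1) %% m
  }
  as.integer(h %% 2147483563) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round() uses banker's rounding; the balancing rule and voxel-window
# scaling want plain half-up rounding.
round_half_up <- function(x) floor(x + 0.5)

# Nearest-integer with halfway ties rounded toward -Inf (point-to-voxel rule).
round_half_down <- function(x) ceiling(x - 0.5)

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}

axis_levels <- function() c("sagittal", "coronal", "transverse")

# Axis name -> volume dimension index (sagittal planes are orthogonal to X).
axis_dim <- function(axis) {
  match(match.arg(axis, axis_levels()), axis_levels())
}
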