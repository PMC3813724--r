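#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-module seed derived from a global seed and a label,
# kept below 2^31 - 1 (double arithmetic: exact well past 2^31 * 2654435).
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435 + h %% 1000003) %% 2147483647)
}

# Wrap an angle to [0, pi) (ellipse orientations are axial quantities).
wrap_axial <- function(theta) {
  out <- theta %% pi
  out[out < 0] <- out[out < 0] + pi
  out
}

# Smallest absolute difference between two axial angles, in [0, pi/2].
axial_diff <- function(a, b) {
  d <- abs(wrap_axial(a) - wrap_axial(b))
  pmin(d, pi - d)
}

stop_if_not_positive <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    if (any(!is.finite(args[[i]])) || any(args[[i]] <= 0))
      stop(sprintf("'%s' must be positive and finite", nm[i]), call. = FALSE)
  }
  invisible(TRUE)
}
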