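# Internal helpers: seeded substreams, padding, numeric utilities.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit substream seed derived from a master seed and a set of
# string/integer labels. Polynomial rolling hash mod (2^31 - 1); adding a cell
# never perturbs the substream of another (cell index, purpose) pair.
substream_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (tok in as.character(c(...))) {
    for (ch in utf8ToInt(tok)) s <- (s * 31 + ch) %% m
  }
  as.integer(s)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Reflective (mirror) padding of a vector by `k` samples on each side.
pad_reflect <- function(x, k) {
  n <- length(x)
  if (k <= 0) return(x)
  if (k > n - 1) stop("reflection pad longer than signal")
  c(x[(k + 1):2], x, x[(n - 1):(n - k)])
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Machine-parsable warning line on stderr (pipeline log convention).
log_warn <- function(stage, msg) {
  message(sprintf("WARN [%s] %s", stage, msg))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && abs(x - round(x)) < 1e-8
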