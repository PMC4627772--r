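#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Nothing here is exported.

# Run `expr` under a reproducible RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Every stochastic generator in the package
# funnels its randomness through this helper so that a single integer seed
# fully determines its output.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent prefix and no call, so error messages are testable.
abort <- function(...) stop(..., call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is_scalar_num(x)) abort(name, " must be a finite numeric scalar")
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    abort(name, " = ", format(x), " outside allowed range [",
          min, ", ", max, "]",
          if (strict_min || strict_max) " (strict bound)" else "")
  }
  invisible(x)
}

# Significance stars used throughout (two-sided p):
# ns > 0.05, * <= 0.05, ** <= 0.01, *** <= 0.001, **** <= 0.0001.
p_stars <- function(p) {
  stopifnot(is.numeric(p))
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 1e-4) "****"
    else if (pi <= 1e-3) "***"
    else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*"
    else "ns"
  }, character(1))
}
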