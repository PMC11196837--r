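clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so that simulation calls never perturb unrelated randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

is_proportion <- function(x) is.numeric(x) && !anyNA(x) && all(x >= 0 & x <= 1)

assert_simplex <- function(p, what = "admixture", tol = 1e-9) {
  if (length(p) != 3L || anyNA(p) || any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop(sprintf("%s must be three non-negative proportions summing to 1 (got %s)",
                 what, paste(signif(p, 6), collapse = ", ")), call. = FALSE)
  }
  invisible(p)
}

# delimiter auto-detection for the tabular text formats: tab wins if the
# header line contains one, else comma
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}
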