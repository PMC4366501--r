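# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# If seed is NULL the current RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # force RNG initialisation so we can restore it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_pf <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, positive = FALSE, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_pf(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) stop_pf(sprintf("`%s` must be > 0", name))
  if (x < min || x > max) {
    stop_pf(sprintf("`%s` must be in [%s, %s]", name, min, max))
  }
  invisible(x)
}

check_probability <- function(x, name) check_number(x, name, min = 0, max = 1)

# root mean square
rms <- function(x) sqrt(mean(x^2))
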