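# Shared internal helpers: condition constructors, rounding, RNG scoping.

# Signal a classed error so callers can react to the failure mode rather
# than parse messages. `class` is the specific subclass; every condition
# also carries "elisashift_error".
es_stop <- function(msg, class, call = sys.call(-1), ...) {
  stop(errorCondition(msg, ..., class = c(class, "elisashift_error"),
                      call = call))
}

es_stopf <- function(class, fmt, ..., fields = list()) {
  do.call(es_stop, c(list(msg = sprintf(fmt, ...), class = class), fields))
}

# Round half away from zero (the convention used for printed CV percentages
# and fold ratios); base round() is round-half-even.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
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

# Format a double so that parsing the text recovers the identical bits.
fmt_num <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
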