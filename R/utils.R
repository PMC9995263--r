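# internal helpers: validation and deterministic seed derivation

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 open_lower = FALSE, open_upper = FALSE,
                                 integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "bwasrep_config_error")
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s; got %g.", name,
      if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]", x
    ), class = "bwasrep_config_error")
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be an integer; got %g.", name, x),
          class = "bwasrep_config_error")
  }
  invisible(x)
}

# Deterministic 31-bit seed stream: mixes a base seed with integer tags
# (e.g. sample size, replicate index) so replicates are independent of
# execution order and of how many of them are run.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) {
    h <- (h * 69069 + (as.numeric(t) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

# evaluate expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

sidedness_match <- function(sidedness) {
  match.arg(sidedness, c("two_sided", "one_sided"))
}
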