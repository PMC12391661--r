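# Internal helpers: classed conditions, seeded evaluation, small validators.

ph_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "porehull_error"), call = call))
}

#' @noRd
assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    ph_stop(sprintf("`%s` must be a single positive finite number", name),
            "porehull_domain_error")
  }
  invisible(x)
}

assert_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    ph_stop(sprintf("`%s` must be a single non-negative finite number", name),
            "porehull_domain_error")
  }
  invisible(x)
}

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_state) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}

# Deterministic seed splitting: child seed `i` of a master seed. Keeps values
# strictly below 2^31 so they remain valid R integers.
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 1103515245) %% 2147483647)
}
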