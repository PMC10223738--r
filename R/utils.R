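# Self-contained RNG stream: keeps its own .Random.seed so package
# generators are pure functions of (params, seed) and never disturb the
# caller's RNG state.
.seeded_rng <- function(seed) {
  state <- NULL
  run <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    out <- f(...)
    state <<- get(".Random.seed", globalenv())
    out
  }
  list(
    runif = function(n, min = 0, max = 1) run(stats::runif, n, min, max),
    rnorm = function(n, mean = 0, sd = 1) run(stats::rnorm, n, mean, sd),
    sample = function(x, size = NULL, replace = FALSE)
      run(function() if (is.null(size)) base::sample(x)
          else base::sample(x, size, replace)),
    rpois = function(n, lambda) run(stats::rpois, n, lambda),
    rint = function(n, max) run(function() sample.int(max, n, replace = TRUE))
  )
}

# Derive a distinct 31-bit child seed from (seed, tag) without consuming RNG.
.child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}
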