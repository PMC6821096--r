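# internal helpers shared across modules

# Run code under a temporary RNG state. seed = NULL leaves the current
# stream untouched; otherwise the global stream is restored afterwards so
# seeded helpers compose without clobbering callers.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_count <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 1) || any(x != floor(x)))
    stop(sprintf("`%s` must contain positive integers", name), call. = FALSE)
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-score a numeric vector with frozen centre/scale
zscore <- function(x, center, scale) (x - center) / scale

# Newton polish after a quasi-Newton run: drives the gradient norm down to
# tol * max(1, |objective|) so closed-form identities hold to high precision.
newton_polish <- function(par, fn, gr, tol = 1e-9, max_steps = 10, ...) {
  for (i in seq_len(max_steps)) {
    g <- gr(par, ...)
    if (max(abs(g)) < tol * max(1, abs(fn(par, ...)))) break
    H <- try(stats::optimHess(par, fn, gr, ...), silent = TRUE)
    if (inherits(H, "try-error")) break
    step <- try(solve(H, g), silent = TRUE)
    if (inherits(step, "try-error") || any(!is.finite(step))) break
    # backtracking line search on the Newton direction
    f0 <- fn(par, ...)
    alpha <- 1
    repeat {
      cand <- par - alpha * step
      if (fn(cand, ...) <= f0 + 1e-12) { par <- cand; break }
      alpha <- alpha / 2
      if (alpha < 1e-6) break
    }
    if (alpha < 1e-6) break
  }
  par
}
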