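#' @keywords internal
"_PACKAGE"

# Run expr with a private RNG stream seeded by `seed`, restoring the caller's
# .Random.seed afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Truncated-normal draws by rejection; bounds are far from the mean for all
# presets so acceptance probability is high.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-target seed stream: combines a fixed stream id with a
# run-level base seed, keeping the result in 32-bit integer range.
acc_seed <- function(stream, base = 1L) {
  as.integer((as.numeric(stream) * 100003 + as.numeric(base)) %% 2147483647)
}

stop_capmorph <- function(fmt, ..., class = "capmorph_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
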