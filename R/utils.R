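# Seed plumbing.  Every stochastic stage (fold assignment, weight
# initialisation, epoch shuffling, synthetic generation) draws its own
# substream seed from a master seed so that stages are independently
# reproducible and reordering one stage cannot perturb another.

# Mix integer components into a substream seed < 2^31 - 1.  Uses exact
# double arithmetic (all intermediates < 2^53).
derive_seed <- function(seed, ...) {
  parts <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    s <- (s * 69069 + as.numeric(p) + 1) %% 2147483647
  }
  as.integer(s)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Z-score a numeric vector/matrix over all entries; zero-variance input is
# only centred (no division).
standardize_entries <- function(x, eps = 1e-12) {
  mu <- mean(x)
  s <- stats::sd(as.vector(x))
  if (!is.finite(s) || s < eps) {
    return(x - mu)
  }
  (x - mu) / s
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Short deterministic hash of a configuration list, for run manifests.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}
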