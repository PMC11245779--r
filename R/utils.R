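# Internal helpers: seeded RNG scoping, deterministic child seeds, periodic
# interpolation, and a tiny config hash.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never disturbs user RNG.
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
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seed from a root seed and arbitrary labels/integers.
# FNV-1a style accumulation over the UTF-8 bytes of the arguments, folded
# into [1, 2^31 - 2] so it is always a valid 32-bit R seed.
child_seed <- function(root, ...) {
  parts <- vapply(list(...), function(x) paste(as.character(x), collapse = "\r"),
                  character(1))
  bytes <- utf8ToInt(paste(parts, collapse = "\n"))
  h <- as.double(root %% 2147483647L)
  for (b in bytes) {
    h <- (h * 33 + b) %% 2147483629
  }
  as.integer(h %% 2147483645) + 1L
}

# Linear interpolation of a periodic curve sampled on grid [0, 100] (first and
# last grid values coincide).  `at` may lie outside [0, 100); wrapped mod 100.
interp_periodic <- function(grid, values, at) {
  at <- at %% 100
  approx(grid, values, xout = at, rule = 2)$y
}

# Small stable hash of an R object (used to tag pipeline outputs).
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
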