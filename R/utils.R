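# Internal helpers: classed conditions and seeded RNG scopes.

# Signal a classed error so callers can condition on failure modes
# (e.g. "ensdock_empty_selection") rather than on message text.
ens_stop <- function(class, msg, data = list(), call. = FALSE) {
  cond <- structure(
    class = c(paste0("ensdock_", class), "ensdock_error", "error", "condition"),
    c(list(message = msg, call = if (call.) sys.call(-1) else NULL), data)
  )
  stop(cond)
}

# Run `code` under a fixed RNG seed without disturbing the caller's
# random stream. All stochastic operations in the package go through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive `n` deterministic child seeds (< 2^31) from one parent seed, so
# independent sub-streams (chain, noise, jitter, ...) never interleave.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    ens_stop("invalid_argument",
             sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    ens_stop("invalid_argument",
             sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  as.numeric(x)
}
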