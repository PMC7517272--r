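# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded package functions never perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic seed splitting: all randomness in a multi-stage run flows
# from one user seed through this map. Streams are indexed by a small integer
# and kept inside the 32-bit range R requires of set.seed().
derive_seed <- function(base_seed, k) {
  if (is.null(base_seed)) return(NULL)
  as.integer((as.double(base_seed) * 48271 + 999983 * as.double(k)) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

stop_with <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "infodyn_error")))
}

default_labels <- function(M) paste0("Y", seq_len(M))
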