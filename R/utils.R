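# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never pollute the
# session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage of the pipeline receives its own sub-stream derived
#' deterministically from one master seed, so that stages can be re-run in
#' isolation and whole runs are reproducible end to end. The derivation is a
#' small multiplicative hash kept strictly below 2^31.
#'
#' @param master Integer master seed.
#' @param ... One or more integer indices naming the sub-stream (e.g. stage,
#'   subject, repetition).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(as.integer(master), vapply(list(...), as.integer, integer(1)))
  h <- 0
  for (k in idx) {
    h <- (h * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Stop with a message mentioning the calling contract that was violated.
abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
  invisible(NULL)
}

# Check that a data frame carries the named columns; error names the missing.
require_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  abort_if(
    length(missing) > 0,
    sprintf("%s is missing required column(s): %s", what,
            paste(missing, collapse = ", "))
  )
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
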