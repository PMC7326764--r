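# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Each stochastic sub-task (fold assignment, permutation stream, each
#' simulated SNP, ...) gets its own stream derived deterministically from one
#' top-level seed and a task counter, so tasks are independent and the whole
#' pipeline is reproducible from a single integer.
#'
#' @param seed master integer seed.
#' @param counter non-negative integer task index.
#' @return an integer seed below 2^31.
#' @keywords internal
child_seed <- function(seed, counter) {
  # splitmix-style integer hash, kept in [0, 2^31) via double arithmetic
  x <- (as.numeric(seed) * 2654435761 + as.numeric(counter) * 40503 + 12345)
  as.integer(x %% 2147483647)
}

#' Evaluate with a local RNG seed
#'
#' Runs `expr` under `set.seed(seed)` without disturbing the caller's RNG
#' state.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' log of binomial coefficient via lgamma
#' @keywords internal
lchoose_safe <- function(n, k) {
  ifelse(k < 0 | k > n, -Inf, lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1))
}

#' numerically stable log(sum(exp(x)))
#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

stop_strokenet <- function(..., class) {
  stop(structure(
    class = c(class, "strokenet_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

msg <- function(..., verbose = getOption("strokenet.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}
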