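#' @keywords internal
"_PACKAGE"

#' @useDynLib frontscape, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef lm rnorm rpois runif quantile sd vcov
#' @importFrom grDevices contourLines
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive reproducible child seeds below 2^31 from a base seed.
derive_seeds <- function(seed, n, salt = 0L) {
  (as.double(seed) * 48271 + salt * 1299721 + seq_len(n) * 7919) %% 2147483647
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be a positive finite number", name), call. = FALSE)
  }
}
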