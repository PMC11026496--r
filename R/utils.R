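#' @importFrom rlang .data
#' @import tibble
NULL

# Run code with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

clip01 <- function(x, lo = 0.01, hi = 0.99) pmin(pmax(x, lo), hi)

# Robust z-score: (x - median) / (1.4826 * MAD); zero-MAD guarded.
robust_z <- function(x) {
  m <- stats::median(x)
  s <- stats::mad(x)
  if (s < .Machine$double.eps) s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) {
    return(rep(0, length(x)))
  }
  (x - m) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_matrix_aligned <- function(..., what = "matrices") {
  mats <- list(...)
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L) {
    stop(sprintf("%s must share dimensions (got %s)", what,
                 paste(dims, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
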