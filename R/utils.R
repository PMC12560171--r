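#' @useDynLib csfproxy, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif var sd cor predict coef
#' @importFrom utils read.csv write.csv
NULL

DIAGNOSTIC_GROUPS <- c("CN", "sMCI", "pMCI", "AD")
MARKERS <- c("abeta", "ptau", "tau")

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed below 2^31 from a parent seed and a stream label.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 7919 + h * 104729 + 13) %% 2147483629)
}

assert_group <- function(group) {
  bad <- setdiff(unique(as.character(group)), DIAGNOSTIC_GROUPS)
  if (length(bad) > 0L) {
    stop("invalid diagnostic group(s): ", paste(bad, collapse = ", "),
         " (expected CN, sMCI, pMCI or AD)", call. = FALSE)
  }
  invisible(TRUE)
}
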