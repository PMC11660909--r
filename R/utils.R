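#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef cutree dist hclust lm median na.omit
#'   p.adjust pnorm power.t.test predict qnorm quantile rbinom rgeom rnorm
#'   runif sd setNames var wilcox.test
#' @importFrom utils head tail
#' @importFrom mclust Mclust mclustBIC adjustedRandIndex
NULL

# score metadata shared across modules: bounded ranges and the direction in
# which a score moves as symptoms worsen (+1 = increases, -1 = decreases)
score_info <- function() {
  tibble::tibble(
    score = c("mmse", "cdrsb", "faq"),
    min = c(0, 0, 0),
    max = c(30, 18, 30),
    worse_sign = c(-1, 1, 1)
  )
}

score_names <- function() score_info()$score

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# run code with a local RNG state derived from `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
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
    set.seed(as.integer(seed))
  }
  force(code)
}

# inverse-CDF truncated normal: deterministic given the RNG stream
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (any(sd == 0)) {
    out <- rep_len(mean, n)
    return(clamp(out, lo, hi))
  }
  a <- pnorm(lo, mean, sd)
  b <- pnorm(hi, mean, sd)
  qnorm(a + runif(n) * (b - a), mean, sd)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Adjusted Rand index between two partitions
#'
#' Convenience re-export of the standard pair-counting agreement measure,
#' used throughout to compare recovered subgroup labels with generator
#' ground truth.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
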