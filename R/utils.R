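#' @importFrom methods new validObject is slot
#' @importFrom stats wilcox.test dnorm sd var median quantile fft rnorm runif
#'   optim mad IQR ecdf cor aggregate setNames
#' @importFrom utils head tail write.csv read.csv
#' @importFrom graphics hist
NULL

# Evaluate `expr` under a private RNG stream; the caller's RNG state is
# untouched. All generator determinism contracts rely on this.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

stopIfNot2Classes <- function(labels) {
  cls <- unique(as.character(labels))
  if (length(cls) != 2L)
    stop("exactly 2 classes required, got ", length(cls), call. = FALSE)
  cls
}

# sample skewness / excess-free kurtosis (moment definitions)
momentSkewness <- function(x) {
  n <- length(x); m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}
momentKurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2
}
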