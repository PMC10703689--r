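#' @importFrom stats mad median sd lm coef pnorm setNames runif rnorm
#' @importFrom utils head tail read.table write.table
#' @importFrom tools file_ext
NULL

# Run `expr` under a fixed RNG seed without touching the caller's RNG state.
# Seeds are explicit arguments throughout the package, never global state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Centered running mean; ends are padded by replication so length is kept.
runningMean <- function(x, width = 5L) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(x)
  if (n <= width) return(rep(mean(x), n))
  h <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[n], h))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2L))[(h + 1L):(h + n)]
}

# Indices of strict interior local maxima of a vector.
localMaxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Robust per-sample noise scale from first differences (Var(diff) = 2 sigma^2
# for iid noise; insensitive to a smooth underlying curve).
noiseScale <- function(y) mad(diff(y)) / sqrt(2)

# Error function via the normal CDF.
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
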