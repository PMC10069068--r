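#' @useDynLib perivasc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rpois runif lm coef median sd complete.cases
#' @importFrom utils write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# derive a reproducible sub-seed for a pipeline stage
sub_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage) %% 2147483647L)
}

#' Otsu threshold of an intensity sample
#'
#' Maximises the between-class variance of a two-class split of the intensity
#' histogram. Used as the default automatic threshold wherever a fixed
#' threshold is not supplied.
#'
#' @param x numeric vector or array of intensities.
#' @param levels number of histogram bins.
#' @return threshold value; intensities `>= threshold` are foreground.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  r <- range(x)
  if (r[1] == r[2]) return(r[2] + .Machine$double.eps)
  breaks <- seq(r[1], r[2], length.out = levels + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = levels)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- counts / sum(counts)
  mu <- cumsum(w * mids)
  om <- cumsum(w)
  mu_t <- mu[levels]
  valid <- om > 0 & om < 1
  bcv <- (mu_t * om - mu)^2 / (om * (1 - om))
  bcv[!valid] <- -Inf
  k <- which.max(bcv)
  # threshold between the two classes: first bin edge above the argmax
  breaks[k + 1L]
}

# Parabolic (three-point) refinement of a peak position on a uniform grid.
# Returns the fractional index offset in (-0.5, 0.5) relative to `i`.
parabolic_offset <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  max(min(off, 0.5), -0.5)
}

# local maxima indices of a vector (plateau-safe: strictly greater than one
# side, greater-or-equal the other)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  i <- 2L:(n - 1L)
  i[(y[i] >= y[i - 1L] & y[i] > y[i + 1L]) |
      (y[i] > y[i - 1L] & y[i] >= y[i + 1L])]
}

# random unit vector (3D, isotropic)
runit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# an arbitrary unit vector perpendicular to u
perp_unit <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- c(u[2] * a[3] - u[3] * a[2],
         u[3] * a[1] - u[1] * a[3],
         u[1] * a[2] - u[2] * a[1])
  v / sqrt(sum(v^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# md5 of the canonical JSON serialization of a config list
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = FALSE)
  unname(tools::md5sum(f))
}
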