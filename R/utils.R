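#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so that callers' random streams are unaffected.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Sample an image at sub-pixel locations by bilinear interpolation
#'
#' Coordinates follow the image convention used throughout the package:
#' 0-based, `x` is the column index (rightward), `y` the row index
#' (downward). Locations outside the image are clamped to the border.
#'
#' @param img numeric matrix (rows x cols).
#' @param x,y numeric vectors of equal length, 0-based sub-pixel coords.
#' @return numeric vector of sampled intensities.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  # convert to 1-based linear indices of the four neighbours
  i00 <- (x0) * nr + y0 + 1
  v00 <- img[i00]; v10 <- img[i00 + nr]
  v01 <- img[i00 + 1]; v11 <- img[i00 + nr + 1]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

#' Discrete Gaussian kernel
#' @keywords internal
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian smoothing of a matrix (replicated borders)
#' @keywords internal
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  nr <- nrow(img); nc <- ncol(img)
  # pad by border replication, then accumulate shifted copies
  rows_idx <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  cols_idx <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  p <- img[rows_idx, , drop = FALSE]
  acc <- matrix(0, nr, nc)
  for (i in seq_along(k)) acc <- acc + k[i] * p[(i - 1L) + seq_len(nr), , drop = FALSE]
  p <- acc[, cols_idx, drop = FALSE]
  acc <- matrix(0, nr, nc)
  for (i in seq_along(k)) acc <- acc + k[i] * p[, (i - 1L) + seq_len(nc), drop = FALSE]
  acc
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("`%s` must be > 0", name)
  if (nonneg && x < 0) stopf("`%s` must be >= 0", name)
  invisible(x)
}
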