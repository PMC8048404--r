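## small shared internals: logging, padding, separable box filters

sf_log <- function(level, ...) {
  if (isTRUE(getOption("scanforge.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), level,
                  paste0(..., collapse = "")))
  invisible(NULL)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## replicate-pad a matrix by r pixels on each side
pad_replicate <- function(x, r) {
  if (r == 0L) return(x)
  n <- nrow(x); m <- ncol(x)
  ri <- c(rep(1L, r), seq_len(n), rep(n, r))
  ci <- c(rep(1L, r), seq_len(m), rep(m, r))
  x[ri, ci, drop = FALSE]
}

## box sum over a w x w window (w odd), replicate boundary, via integral image
box_sum <- function(x, w) {
  stopifnot(w %% 2L == 1L, w >= 1L)
  if (w == 1L) return(x)
  r <- (w - 1L) %/% 2L
  p <- pad_replicate(x, r)
  ii <- apply(apply(p, 2L, cumsum), 1L, cumsum) # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  n <- nrow(x); m <- ncol(x)
  i1 <- seq_len(n); j1 <- seq_len(m)
  ii[i1 + w, j1 + w, drop = FALSE] - ii[i1, j1 + w, drop = FALSE] -
    ii[i1 + w, j1, drop = FALSE] + ii[i1, j1, drop = FALSE]
}

box_mean <- function(x, w) box_sum(x, w) / (w * w)

## 3x3 Laplacian response with replicate padding (output size == input size)
laplacian_response <- function(x) {
  stopifnot(is.matrix(x))
  p <- pad_replicate(x, 1L)
  n <- nrow(x); m <- ncol(x)
  i <- 2:(n + 1); j <- 2:(m + 1)
  p[i - 1, j] + p[i + 1, j] + p[i, j - 1] + p[i, j + 1] - 4 * p[i, j]
}

## 2-D Gaussian blur with replicate boundary (separable, exact kernel)
gaussian_blur <- function(x, sigma, kernel_size = NULL) {
  if (sigma <= 0) return(x)
  k <- kernel_size %||% (2L * as.integer(ceiling(3 * sigma)) + 1L)
  stopifnot(k %% 2L == 1L)
  r <- (k - 1L) %/% 2L
  g <- exp(-((-r:r)^2) / (2 * sigma^2)); g <- g / sum(g)
  p <- pad_replicate(x, r)
  ## rows then columns
  p <- apply(p, 2L, function(col) stats::filter(col, g, sides = 2L))
  p <- t(apply(p, 1L, function(row) stats::filter(row, g, sides = 2L)))
  p[(r + 1):(r + nrow(x)), (r + 1):(r + ncol(x)), drop = FALSE]
}

fftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  x[c((floor(n / 2) + 1):n, 1:floor(n / 2)),
    c((floor(m / 2) + 1):m, 1:floor(m / 2)), drop = FALSE]
}

is_odd <- function(x) x %% 2L == 1L
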