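#' @keywords internal
"_PACKAGE"

# Shared small numerics used across modules.

#' Logistic gradient along the dorso-ventral axis
#'
#' Smooth transition from `p_max` at the ventral pole to `p_min` at the dorsal
#' pole. Elevation is in degrees, negative values ventral. The midpoint `e0`
#' sits inside the equatorial band by default and `s` (degrees) controls the
#' steepness of the transition.
#'
#' @param elevation numeric vector of elevations in degrees (negative = ventral).
#' @param p_min value approached at the dorsal pole.
#' @param p_max value approached at the ventral pole.
#' @param e0 midpoint elevation in degrees.
#' @param s slope scale in degrees (> 0).
#' @return numeric vector, same length as `elevation`.
#' @export
logistic_gradient <- function(elevation, p_min, p_max, e0 = -5, s = 15) {
  stopifnot(s > 0)
  p_min + (p_max - p_min) / (1 + exp((elevation - e0) / s))
}

# Separable Gaussian blur of a matrix via banded convolution matrices with
# reflected edges. Fast enough for the frame sizes used here (<= ~512 px).
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma >= 0)
  if (sigma == 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_mat <- function(n) {
    M <- matrix(0, n, n)
    for (off in (-half):half) {
      idx <- seq_len(n) + off
      # reflect out-of-range indices back into [1, n]
      idx <- ifelse(idx < 1L, 2L - idx, idx)
      idx <- ifelse(idx > n, 2L * n - idx, idx)
      M[cbind(seq_len(n), idx)] <- M[cbind(seq_len(n), idx)] + k[off + half + 1L]
    }
    M
  }
  conv_mat(nrow(img)) %*% img %*% t(conv_mat(ncol(img)))
}

# Otsu's threshold on a numeric vector (used for automatic label-intensity
# calling). Returns a cut value maximizing between-class variance.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  stopifnot(length(x) > 1)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, brk, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  # place the cut mid-way between the two classes rather than at the last
  # lower-class bin, so borderline points do not straddle the threshold
  lo <- max(x[x <= brk[k + 1L]])
  hi_set <- x[x > brk[k + 1L]]
  if (length(hi_set) == 0) return(mids[k])
  (lo + min(hi_set)) / 2
}

# Centers of a hexagonal lattice with `rows` x `cols` sites, nearest-neighbour
# distance `spacing`, offset so all coordinates are >= margin.
hex_lattice <- function(rows, cols, spacing, margin = spacing) {
  stopifnot(rows >= 1, cols >= 1, spacing > 0)
  g <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  x <- (g$c - 1) * spacing + ifelse(g$r %% 2 == 0, spacing / 2, 0) + margin
  y <- (g$r - 1) * spacing * sqrt(3) / 2 + margin
  data.frame(x = x, y = y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
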