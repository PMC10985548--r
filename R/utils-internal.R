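# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
## RNG state afterwards so simulations do not perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Vertex of the parabola through (x[i-1],y[i-1]), (x[i],y[i]), (x[i+1],y[i+1])
## for uniformly spaced x. Returns the refined x position; falls back to x[i]
## when the three points are collinear (denominator ~ 0).
parabolic_refine <- function(x, y, i) {
  if (i <= 1L || i >= length(y)) return(x[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (abs(denom) < .Machine$double.eps * max(1, abs(y[i]))) return(x[i])
  offset <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  offset <- max(-1, min(1, offset))
  x[i] + offset * (x[2L] - x[1L])
}

## Local maxima of a numeric vector with topographic prominence.
## A peak's prominence is its height minus the higher of the two key cols:
## the minimum between the peak and the nearest higher point on each side
## (series edge if none). Plateaus contribute their first index.
find_peaks <- function(x, prominence_min = 0, min_separation = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] > x[cand - 1L] & x[cand] >= x[cand + 1L]]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- h; j <- i - 1L
    while (j >= 1L && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1L }
    rmin <- h; j <- i + 1L
    while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= prominence_min]
  promk <- prom[prom >= prominence_min]
  if (min_separation > 1L && length(keep) > 1L) {
    ord <- order(promk, x[keep], decreasing = TRUE)
    chosen <- integer(0)
    for (i in keep[ord]) {
      if (!length(chosen) || all(abs(chosen - i) >= min_separation)) {
        chosen <- c(chosen, i)
      }
    }
    keep <- sort(chosen)
  }
  keep
}

## Sample skewness (biased, method-of-moments): m3 / m2^(3/2).
skewness <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^3) / m2^1.5
}

## Centered moving average with partial windows at the edges, so the output
## has the same length as the input. `w` is an odd window length in samples.
moving_average_partial <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Bilinear interpolation of image `img` (matrix, row-major pixel grid) at
## fractional 0-based coordinates (r, c). Points outside the grid return NA.
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1)
  v <- img[i00] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 2, c0 + 1)] * fr * (1 - fc) +
    img[cbind(r0 + 1, c0 + 2)] * (1 - fr) * fc +
    img[cbind(r0 + 2, c0 + 2)] * fr * fc
  out[ok] <- v
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x)

## Vertex of a least-squares quadratic through (x, y); x need not be evenly
## spaced. Returns NA when the fit is not concave.
quad_vertex <- function(x, y) {
  co <- tryCatch(stats::lm.fit(cbind(1, x, x^2), y)$coefficients,
                 error = function(e) NULL)
  if (is.null(co) || is.na(co[3]) || co[3] >= 0) return(NA_real_)
  unname(-co[2] / (2 * co[3]))
}
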