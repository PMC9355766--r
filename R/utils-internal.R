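# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library calls never perturb user
# simulations.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Axial (180-degree periodic) circular statistics on orientation angles in
# degrees, optionally weighted. Returns the weighted axial mean in
# [0, 180) and the circular sd of the doubled angles halved, capped at the
# 90-degree axial bound.
axialStats <- function(anglesDeg, weights = NULL) {
  phi2 <- deg2rad(2 * anglesDeg)
  if (is.null(weights)) weights <- rep(1, length(phi2))
  w <- weights / sum(weights)
  C <- sum(w * cos(phi2))
  S <- sum(w * sin(phi2))
  rbar <- min(sqrt(C^2 + S^2), 1)  # clamp fp round-off above 1
  meanDeg <- (rad2deg(atan2(S, C)) / 2) %% 180
  sdDeg <- if (rbar <= .Machine$double.eps) 90
           else min(90, rad2deg(sqrt(-2 * log(rbar)) / 2))
  list(mean = meanDeg, sd = sdDeg, rbar = rbar)
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
# Positions outside [1, nrow] x [1, ncol] return NA.
bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
  out <- rep(NA_real_, length(row))
  if (!any(ok)) return(out)
  r <- row[ok]; c <- col[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  out[ok] <- m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
  out
}

# Local minima of a 1-D profile with a prominence requirement, sub-pixel
# refined by parabolic interpolation. Prominence of a minimum is the
# smaller of the climbs to the highest point before descending below the
# minimum on either side (computed on the inverted profile in the standard
# way). Detection runs on `y` (typically median-filtered); the parabolic
# refinement uses `yRaw`, because a running-median flattens smooth valley
# bottoms and would quantize the positions to whole pixels. Returns
# fractional positions (indices).
findValleys <- function(y, prominence, yRaw = y) {
  n <- length(y)
  if (n < 3L) return(numeric(0))
  idx <- which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
  if (!length(idx)) return(numeric(0))
  keep <- vapply(idx, function(i) {
    v <- y[i]
    # climb leftwards until profile drops below v (or edge)
    left <- y[seq_len(i - 1)]
    below <- which(left < v)
    lbase <- if (length(below)) max(below) + 1L else 1L
    lclimb <- max(left[lbase:(i - 1)]) - v
    right <- y[(i + 1):n]
    below <- which(right < v)
    rbase <- if (length(below)) min(below) - 1L else length(right)
    rclimb <- max(right[seq_len(rbase)]) - v
    min(lclimb, rclimb) >= prominence
  }, logical(1))
  idx <- idx[keep]
  # parabolic sub-pixel refinement on the raw profile
  vapply(idx, function(i) {
    # re-localize on yRaw within one pixel of the filtered minimum
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    i <- (lo:hi)[which.min(yRaw[lo:hi])]
    if (i <= 1L || i >= n) return(as.numeric(i))
    denom <- yRaw[i - 1] - 2 * yRaw[i] + yRaw[i + 1]
    if (denom <= 0) return(as.numeric(i))
    delta <- 0.5 * (yRaw[i - 1] - yRaw[i + 1]) / denom
    i + max(-0.5, min(0.5, delta))
  }, numeric(1))
}

# Gaussian-smoothed unit-variance random field (matrix), used for smooth
# orientation jitter. `sigmaPx` is the smoothing scale in pixels.
smoothNoiseField <- function(nrow, ncol, sigmaPx) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  # brush cannot exceed the image; cap the radius on small fields
  radius <- min(2L * as.integer(ceiling(3 * sigmaPx)) + 1L,
                2L * ((min(nrow, ncol) - 1L) %/% 2L) - 1L)
  z <- EBImage::gblur(z, sigma = sigmaPx, radius = radius)
  z / stats::sd(as.vector(z))
}

fmtNum <- function(x) format(x, digits = 6, trim = TRUE)
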