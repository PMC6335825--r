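# Independent oracles and fixture builders. All fixtures are generated in
# code; the oracles deliberately use naive enumeration, not the package's
# own code paths.

# Brute-force GLCM: enumerate every ordered pixel pair at the offset with
# both endpoints in the mask; count into a dense table.
oracleGLCM <- function(img, mask, offset) {
  dx <- offset[1]; dy <- offset[2]
  nr <- nrow(img); nc <- ncol(img)
  counts <- matrix(0, 256, 256)
  n <- 0
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + dy; c2 <- c + dx
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          mask[r, c] && mask[r2, c2]) {
        counts[img[r, c] + 1, img[r2, c2] + 1] <-
          counts[img[r, c] + 1, img[r2, c2] + 1] + 1
        n <- n + 1
      }
    }
  }
  list(p = counts / n, n = n)
}

# Texture statistics straight from the definitions.
oracleTexture <- function(p) {
  lv <- seq_len(nrow(p)) - 1
  w <- 1 / (1 + outer(lv, lv, "-")^2)
  nz <- p > 0
  c(asm = sum(p^2), idm = sum(p * w),
    entropy = -sum(p[nz] * log(p[nz])))
}

# Brute-force inward band assignment: for every mask pixel, the minimum
# Euclidean distance to any background pixel that is 4-adjacent to the
# mask (the nearest background pixel always is), then the same half-pixel
# and band conventions as the package.
oracleShellLabels <- function(mask, pixelSizeUm, edgesNm) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  fgAdj <- !pad & (rbind(pad[-1, ], FALSE) | rbind(FALSE, pad[-(nr + 2), ]) |
                   cbind(pad[, -1], FALSE) | cbind(FALSE, pad[, -(nc + 2)]))
  # background pixels 4-adjacent to foreground, padded coords
  bgp <- which(fgAdj, arr.ind = TRUE)
  fg <- which(pad, arr.ind = TRUE)
  labels <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(fg))) {
    d2 <- (fg[k, 1] - bgp[, 1])^2 + (fg[k, 2] - bgp[, 2])^2
    dNm <- (sqrt(min(d2)) - 0.5) * pixelSizeUm * 1000
    labels[fg[k, 1] - 1, fg[k, 2] - 1] <-
      1L + sum(edgesNm < dNm)
  }
  labels
}

# Random star-convex polygon (independent of the package's contour
# sampler) and its rasterized mask.
randomStarPolygon <- function(size, nKnots = 10, meanR = 0.32,
                              jitter = 0.3) {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  kth <- seq(0, 2 * pi, length.out = nKnots + 1)
  kr <- size * meanR * (1 + jitter * (2 * runif(nKnots) - 1))
  r <- stats::spline(kth, c(kr, kr[1]), method = "periodic", xout = th)$y
  r <- pmax(r, size * 0.05)
  cbind(x = size / 2 + r * cos(th), y = size / 2 + r * sin(th))
}

randomStarMask <- function(size, ...) {
  polygonToMask(randomStarPolygon(size, ...), c(size, size))
}

# Render disjoint square "beads" of a given gray value; returns the image
# and the bead centre list.
renderSquareBeads <- function(size, centers, halfWidth = 1, value = 1000) {
  img <- matrix(0, size, size)
  for (k in seq_len(nrow(centers))) {
    rs <- (centers[k, 2] - halfWidth):(centers[k, 2] + halfWidth)
    cs <- (centers[k, 1] - halfWidth):(centers[k, 1] + halfWidth)
    img[rs, cs] <- value
  }
  img
}

# Shoelace area of a polygon (for mask-vs-analytic comparisons).
shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}
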