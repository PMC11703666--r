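## Visual-clutter measures in the style of Rosenholtz, Li & Nakano:
## Feature Congestion and Sub-band Entropy. Both operate on an opponent
## representation (CIELab: L = luminance, a/b = chrominance) and a small
## Gaussian pyramid, using separable filters with edge-replicating padding
## (so spatially constant images give exactly zero band-pass response).

## ---- separable filtering -------------------------------------------------

conv1d_margin <- function(m, k, margin) {
  r <- (length(k) - 1L) %/% 2L
  n <- dim(m)[margin]
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq_along(k)) {
    off <- t - r - 1L
    idx <- clip_range(seq_len(n) + off, 1L, n)   # replicate edges
    out <- out + k[t] * (if (margin == 1L) m[idx, , drop = FALSE]
                         else m[, idx, drop = FALSE])
  }
  out
}

conv_sep <- function(m, ky, kx) conv1d_margin(conv1d_margin(m, ky, 1L), kx, 2L)

gauss_k <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

dgauss_k <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  -x / sigma^2 * exp(-x^2 / (2 * sigma^2))   # antisymmetric, sums to 0
}

d2gauss_k <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- (x^2 / sigma^4 - 1 / sigma^2) * exp(-x^2 / (2 * sigma^2))
  k - mean(k)                                 # exact zero DC response
}

## 2x2 block-mean downsampling: exactly covariant with horizontal/vertical
## flips for even dimensions (decimation is not).
down2 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  if (H %% 2L == 1L) { m <- m[-H, , drop = FALSE]; H <- H - 1L }
  if (W %% 2L == 1L) { m <- m[, -W, drop = FALSE]; W <- W - 1L }
  (m[seq(1L, H, 2L), seq(1L, W, 2L), drop = FALSE] +
   m[seq(2L, H, 2L), seq(1L, W, 2L), drop = FALSE] +
   m[seq(1L, H, 2L), seq(2L, W, 2L), drop = FALSE] +
   m[seq(2L, H, 2L), seq(2L, W, 2L), drop = FALSE]) / 4
}

rgb_to_lab_channels <- function(px) {
  d <- dim(px)
  lab <- grDevices::convertColor(matrix(px / 255, ncol = 3L), from = "sRGB",
                                 to = "Lab")
  list(L = matrix(lab[, 1L], d[1L], d[2L]),
       a = matrix(lab[, 2L], d[1L], d[2L]),
       b = matrix(lab[, 3L], d[1L], d[2L]))
}

lab_pyramid <- function(px, levels) {
  ch <- rgb_to_lab_channels(px)
  g <- gauss_k(1)
  pyr <- vector("list", levels)
  for (lev in seq_len(levels)) {
    pyr[[lev]] <- ch
    if (lev < levels)
      ch <- lapply(ch, function(m) down2(conv_sep(m, g, g)))
  }
  pyr
}

## Steered second-derivative responses of a matrix at the four canonical
## orientations (0, 45, 90, 135 degrees).
oriented_bands <- function(m, sigma = 1) {
  g <- gauss_k(sigma); d1 <- dgauss_k(sigma); d2 <- d2gauss_k(sigma)
  fxx <- conv_sep(m, g, d2)
  fyy <- conv_sep(m, d2, g)
  fxy <- conv_sep(m, d1, d1)
  lapply(c(0, 45, 90, 135) * pi / 180, function(th) {
    cs <- cos(th); sn <- sin(th)
    cs^2 * fxx + 2 * cs * sn * fxy + sn^2 * fyy
  })
}

## ---- Feature Congestion --------------------------------------------------

#' Feature Congestion visual clutter
#'
#' A clutter scalar combining, at each of `levels` pyramid scales and each
#' pixel, three local feature "congestions" computed on CIELab channels:
#' the volume of the local chrominance (a, b) covariance ellipse, the local
#' luminance-contrast energy of a difference-of-Gaussians band, and the
#' spread (standard deviation) of oriented second-derivative energy over
#' four orientations. The three maps are combined linearly with fixed
#' weights and pooled by the mean over pixels (Minkowski order 1) and over
#' scales. A spatially constant image scores exactly 0.
#'
#' @inheritParams hsv_means
#' @param levels pyramid levels (default 3); the smaller image side must be
#'   at least `2^levels`.
#' @param weights length-3 named weights for the color, contrast and
#'   orientation feature maps. The defaults upweight contrast and
#'   orientation, whose raw magnitudes are small relative to the chroma
#'   covariance volume on 8-bit imagery.
#' @return non-negative scalar.
#' @export
feature_congestion <- function(image, levels = 3L,
                               weights = c(color = 1, contrast = 3,
                                           orientation = 1)) {
  px <- as_pixel_array(image)
  if (min(dim(px)[1:2]) < 2^levels)
    stop(sprintf("image too small for a %d-level pyramid: minimum side is %d",
                 levels, 2^levels), call. = FALSE)
  gc2 <- gauss_k(2)                      # local pooling window
  per_level <- vapply(lab_pyramid(px, levels), function(ch) {
    ## color: local covariance volume of the chroma plane
    mu_a <- conv_sep(ch$a, gc2, gc2); mu_b <- conv_sep(ch$b, gc2, gc2)
    saa <- pmax(conv_sep(ch$a^2, gc2, gc2) - mu_a^2, 0)
    sbb <- pmax(conv_sep(ch$b^2, gc2, gc2) - mu_b^2, 0)
    sab <- conv_sep(ch$a * ch$b, gc2, gc2) - mu_a * mu_b
    col_map <- pmax(saa * sbb - sab^2, 0)^0.25
    ## contrast: DoG band-pass energy of luminance
    bp <- conv_sep(ch$L, gauss_k(1), gauss_k(1)) -
          conv_sep(ch$L, gauss_k(2), gauss_k(2))
    con_map <- sqrt(pmax(conv_sep(bp^2, gc2, gc2), 0))
    ## orientation: spread of pooled oriented energies
    en <- lapply(oriented_bands(ch$L), function(f) conv_sep(f^2, gc2, gc2))
    m1 <- Reduce(`+`, en) / 4
    m2 <- Reduce(`+`, lapply(en, `^`, 2)) / 4
    ori_map <- sqrt(pmax(m2 - m1^2, 0))
    mean(weights[["color"]] * col_map + weights[["contrast"]] * con_map +
         weights[["orientation"]] * ori_map)
  }, 0)
  mean(per_level)
}

## ---- Sub-band Entropy ----------------------------------------------------

#' Shannon entropy of a probability vector
#'
#' `-sum(p * log2(p))` over strictly positive cells; `p` must be
#' non-negative and sum to 1 (tolerance 1e-6).
#'
#' @param p numeric vector of probabilities.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(p) {
  stopifnot(all(p >= 0))
  if (abs(sum(p) - 1) > 1e-6)
    stop("probabilities must sum to 1", call. = FALSE)
  p <- p[p > 0]
  -sum(p * log2(p))
}

## Entropy of equal-width-binned coefficients over the band's own range.
## Tying the bin grid to the range makes the statistic invariant to scaling
## all intensities by a constant, while the histogram *shape* (peaked vs
## spread coefficient distributions) drives the value. Points landing
## exactly on an interior edge are split half/half between the adjacent
## bins so the statistic is exactly mirror-symmetric.
band_entropy <- function(x, bins = 8L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- as.numeric(tabulate(idx, nbins = length(edges) - 1L))
  inner <- edges[-c(1L, length(edges))]
  for (e in seq_along(inner)) {
    neq <- sum(x == inner[e])
    if (neq > 0) {                 # findInterval put these in bin e + 1
      cnt[e + 1L] <- cnt[e + 1L] - neq / 2
      cnt[e] <- cnt[e] + neq / 2
    }
  }
  shannon_entropy(cnt / sum(cnt))
}

#' Sub-band Entropy visual clutter
#'
#' Decomposes the CIELab luminance and the two chrominance channels with a
#' `levels`-scale, four-orientation band-pass pyramid (steered second
#' derivatives of a Gaussian) and computes, per sub-band, the Shannon
#' entropy of the coefficient histogram (equal-width bins spanning each
#' band's coefficient range, so the statistic is invariant to global
#' intensity rescaling). The result is the
#' mean over luminance sub-bands plus `chroma_weight` times the mean over
#' chrominance sub-bands, in bits. A constant image scores 0.
#'
#' @inheritParams feature_congestion
#' @param chroma_weight weight of the chrominance term (default 0.0625).
#' @param bins number of quantile histogram bins per sub-band.
#' @return non-negative scalar in bits.
#' @export
subband_entropy <- function(image, levels = 3L, chroma_weight = 0.0625,
                            bins = 8L) {
  px <- as_pixel_array(image)
  if (min(dim(px)[1:2]) < 2^levels)
    stop(sprintf("image too small for a %d-level pyramid: minimum side is %d",
                 levels, 2^levels), call. = FALSE)
  pyr <- lab_pyramid(px, levels)
  ent <- function(channel) {
    unlist(lapply(pyr, function(ch)
      vapply(oriented_bands(ch[[channel]]), band_entropy, 0, bins = bins)))
  }
  lum <- ent("L")
  chrom <- c(ent("a"), ent("b"))
  mean(lum) + chroma_weight * mean(chrom)
}
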