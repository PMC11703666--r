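# Fixtures built in code: images, rating tables, and independent oracles.

# sparse edge-structured base image: flat regions with a few color blocks,
# the kind of band-pass-sparse structure real imagery has
structured_base <- function(side = 32L) {
  base <- array(90, c(side, side, 3L))
  q <- side %/% 4L
  base[(q + 1):(3 * q), (q + 1):(3 * q), 1] <- 200
  base[(2 * q + 1):side, 1:(2 * q), 2] <- 180
  base[1:q, (2 * q + 1):side, 3] <- 60
  base
}

noisy_image <- function(seed, sd, side = 32L, base = NULL) {
  if (is.null(base)) base <- array(128, c(side, side, 3L))
  withr::with_seed(seed,
    quantize_pixels(base + array(stats::rnorm(length(base), 0, sd), dim(base))))
}

random_image <- function(seed, side = 16L) {
  withr::with_seed(seed,
    quantize_pixels(array(stats::runif(side * side * 3L, 0, 255),
                          c(side, side, 3L))))
}

# minimal rating table: one row per (participant, layer)
make_rating_table <- function(layers, n_per_layer, arousal_fun, valence_fun,
                              seed = 1L) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_along(layers), function(i) {
      data.frame(participant_id = sprintf("P%02d", seq_len(n_per_layer)),
                 layer_name = layers[i],
                 seed_index = sample(0:4, n_per_layer, replace = TRUE),
                 arousal = arousal_fun(i, n_per_layer),
                 valence = valence_fun(i, n_per_layer),
                 presentation_order = seq_len(n_per_layer),
                 stringsAsFactors = FALSE)
    }))
  })
}

# independent per-pixel HSV oracle: scalar arithmetic, one pixel at a time
hsv_oracle_means <- function(px) {
  H <- dim(px)[1]; W <- dim(px)[2]
  hs <- ss <- vs <- numeric(0)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    r <- px[i, j, 1]; g <- px[i, j, 2]; b <- px[i, j, 3]
    mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
    h <- if (d == 0) 0
         else if (mx == r) 60 * (g - b) / d
         else if (mx == g) 120 + 60 * (b - r) / d
         else 240 + 60 * (r - g) / d
    if (h < 0) h <- h + 360
    hs <- c(hs, h / 2)
    ss <- c(ss, if (mx == 0) 0 else 255 * d / mx)
    vs <- c(vs, mx)
  }
  c(hue = round(mean(hs), 3), saturation = round(mean(ss), 3),
    brightness = round(mean(vs), 3))
}

# brute-force type-7 quartiles: manual interpolation over the sorted values
quartile_oracle <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
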