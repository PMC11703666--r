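#' Smoothed joint arousal-valence density
#'
#' Bins paired (arousal, valence) ratings on a `grid_size` x `grid_size`
#' grid over \code{[0, 100]^2} (arousal on rows), smooths with a separable
#' Gaussian kernel of standard deviation `bandwidth` rating units, and
#' renormalizes so the cells sum to 1. With `bandwidth` near zero the raw
#' histogram is recovered.
#'
#' @param arousal,valence paired numeric vectors in \code{[0, 100]}.
#' @param grid_size cells per axis (default 101).
#' @param bandwidth Gaussian kernel SD in rating units (default 4).
#' @return an object of class `density_grid`: list with `grid` (matrix
#'   summing to 1), `bandwidth`, `n`, `grid_size`.
#' @export
joint_density <- function(arousal, valence, grid_size = 101L, bandwidth = 4) {
  if (length(arousal) != length(valence))
    stop("arousal and valence must be paired (equal length)", call. = FALSE)
  stopifnot(length(arousal) >= 1L, grid_size >= 2L, bandwidth >= 0)
  if (any(arousal < 0 | arousal > 100 | valence < 0 | valence > 100))
    stop("ratings must lie in [0, 100]", call. = FALSE)
  edges <- seq(0, 100, length.out = grid_size + 1L)
  ia <- findInterval(arousal, edges, rightmost.closed = TRUE, all.inside = TRUE)
  iv <- findInterval(valence, edges, rightmost.closed = TRUE, all.inside = TRUE)
  grid <- matrix(0, grid_size, grid_size)
  for (k in seq_along(ia)) grid[ia[k], iv[k]] <- grid[ia[k], iv[k]] + 1
  cell <- 100 / grid_size
  sd_cells <- bandwidth / cell
  if (sd_cells > 1e-3) {
    k <- gauss_k(sd_cells)
    grid <- conv1d_zero(conv1d_zero(grid, k, 1L), k, 2L)
  }
  grid <- grid / sum(grid)
  structure(list(grid = grid, bandwidth = bandwidth,
                 n = length(arousal), grid_size = as.integer(grid_size)),
            class = "density_grid")
}

## separable convolution with zero padding (mass renormalized by the caller)
conv1d_zero <- function(m, k, margin) {
  r <- (length(k) - 1L) %/% 2L
  n <- dim(m)[margin]
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq_along(k)) {
    off <- t - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    if (margin == 1L) out[ok, ] <- out[ok, ] + k[t] * m[src[ok], , drop = FALSE]
    else out[, ok] <- out[, ok] + k[t] * m[, src[ok], drop = FALSE]
  }
  out
}

#' Shannon entropy of a density grid
#'
#' `-sum(p * log2(p))` over the strictly positive cells of a normalized
#' [joint_density()] grid, in bits; 0 for a point mass and
#' `log2(grid_size^2)` for the uniform grid.
#'
#' @param grid a `density_grid`.
#' @return entropy in bits.
#' @export
density_entropy <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  p <- as.numeric(grid$grid)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("density grid is not normalized", call. = FALSE)
  shannon_entropy(p / sum(p))
}

#' Rank layers by joint-density entropy
#'
#' Identifies three reference layers among per-layer joint arousal-valence
#' densities: the minimum-entropy layer (most repeatable, most "agreed"
#' response), the maximum-entropy layer (most diverse response), and a
#' balanced case minimizing the mean of min-max-normalized entropy and
#' min-max-normalized Euclidean distance of the layer's mean (arousal,
#' valence) point from the neutral point (50, 50). Ties are broken by the
#' order of `grids` (inventory order).
#'
#' @param grids named list of `density_grid` objects, one per layer.
#' @param layer_summaries data.frame from [layer_summaries()] covering the
#'   same layers (used for the mean points).
#' @return list with `scores` (data.frame: layer, entropy_bits,
#'   mean_arousal, mean_valence, dist_neutral, balanced_score), `lowest`,
#'   `highest`, `balanced` (layer names).
#' @export
rank_layers_by_entropy <- function(grids, layer_summaries) {
  stopifnot(length(grids) >= 2L, !is.null(names(grids)))
  ent <- vapply(grids, density_entropy, 0)
  sm <- layer_summaries[match(names(grids), layer_summaries$layer), ]
  if (anyNA(sm$layer))
    stop("layer_summaries is missing layers: ",
         paste(names(grids)[is.na(sm$layer)], collapse = ", "))
  dist_neutral <- sqrt((sm$arousal_mean - 50)^2 + (sm$valence_mean - 50)^2)
  norm01 <- function(x) if (diff(range(x)) == 0) rep(0, length(x))
                        else (x - min(x)) / diff(range(x))
  score <- (norm01(ent) + norm01(dist_neutral)) / 2
  scores <- data.frame(layer = names(grids), entropy_bits = ent,
                       mean_arousal = sm$arousal_mean,
                       mean_valence = sm$valence_mean,
                       dist_neutral = dist_neutral,
                       balanced_score = score,
                       stringsAsFactors = FALSE, row.names = NULL)
  list(scores = scores,
       lowest = names(grids)[which.min(ent)],    # which.min: first on ties
       highest = names(grids)[which.max(ent)],
       balanced = names(grids)[which.min(score)])
}

#' The eight affect-plane anchor points
#'
#' Four corners of the \code{[0, 100]^2} arousal-valence plane and four edge
#' midpoints (one scale extreme, the other neutral at 50).
#'
#' @return data.frame with columns `label`, `arousal`, `valence`.
#' @export
affect_anchors <- function() {
  data.frame(
    label = c("low arousal / low valence", "low arousal / neutral valence",
              "low arousal / high valence", "neutral arousal / high valence",
              "high arousal / high valence", "high arousal / neutral valence",
              "high arousal / low valence", "neutral arousal / low valence"),
    arousal = c(0, 0, 0, 50, 100, 100, 100, 50),
    valence = c(0, 50, 100, 100, 100, 50, 0, 0),
    stringsAsFactors = FALSE)
}

#' Layers nearest to the affect-plane anchors
#'
#' For each anchor point, returns the layer whose per-layer median (default)
#' or mean (arousal, valence) point minimizes Euclidean distance to the
#' anchor. Ties are broken by the row order of `layer_summaries`
#' (inventory order).
#'
#' @param layer_summaries data.frame from [layer_summaries()].
#' @param anchors data.frame of anchor coordinates; default [affect_anchors()].
#' @param stat `"median"` (default) or `"mean"` layer location.
#' @return `anchors` with added columns `layer`, `layer_arousal`,
#'   `layer_valence`, `distance`.
#' @export
nearest_to_anchors <- function(layer_summaries, anchors = affect_anchors(),
                               stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(nrow(layer_summaries) >= 1L)
  a <- layer_summaries[[paste0("arousal_", stat)]]
  v <- layer_summaries[[paste0("valence_", stat)]]
  out <- anchors
  out$layer <- NA_character_
  out$layer_arousal <- NA_real_
  out$layer_valence <- NA_real_
  out$distance <- NA_real_
  for (r in seq_len(nrow(anchors))) {
    d2 <- (a - anchors$arousal[r])^2 + (v - anchors$valence[r])^2
    i <- which.min(d2)
    out$layer[r] <- layer_summaries$layer[i]
    out$layer_arousal[r] <- a[i]
    out$layer_valence[r] <- v[i]
    out$distance[r] <- sqrt(d2[i])
  }
  out
}
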