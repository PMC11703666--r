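#' Mean hue, saturation and brightness in the 8-bit HSV dialect
#'
#' Converts each pixel from RGB to HSV using the 8-bit toolkit convention
#' (hue in half-degrees, \code{[0, 180)}; saturation and value in
#' \code{[0, 255]}) and returns the channel means rounded to three decimal
#' places. Hue of achromatic pixels is 0 and hue is averaged arithmetically;
#' means of a circular quantity in this dialect are convention-dependent, so
#' the dialect is part of the reported feature definition.
#'
#' @param image a [stimulus_image] or an H x W x 3 array with values in
#'   \code{[0, 255]}.
#' @return named numeric vector `c(hue, saturation, brightness)`.
#' @export
hsv_means <- function(image) {
  px <- as_pixel_array(image)
  r <- px[, , 1L]; g <- px[, , 2L]; b <- px[, , 3L]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b); d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  i <- d > 0 & mx == r
  h[i] <- 60 * (g[i] - b[i]) / d[i]
  i <- d > 0 & mx == g & mx != r
  h[i] <- 120 + 60 * (b[i] - r[i]) / d[i]
  i <- d > 0 & mx == b & mx != r & mx != g
  h[i] <- 240 + 60 * (r[i] - g[i]) / d[i]
  h[h < 0] <- h[h < 0] + 360
  s <- ifelse(mx == 0, 0, 255 * d / mx)
  c(hue = round(mean(h / 2), 3),
    saturation = round(mean(s), 3),
    brightness = round(mean(mx), 3))
}

#' JPEG compression percentage
#'
#' Encodes the image as a baseline JPEG at the given quality and reports the
#' encoded byte count as a percentage of the idealized raw size
#' `height x width x 3` bytes (1,920,000 bytes for an 800 x 800 stimulus).
#' Values above 100 are possible only pathologically and are flagged with a
#' warning.
#'
#' @inheritParams hsv_means
#' @param quality JPEG quality on the 0-100 scale (default 80).
#' @return percentage (scalar).
#' @export
jpeg_pct <- function(image, quality = 80) {
  px <- as_pixel_array(image)
  bytes <- tryCatch(jpeg::writeJPEG(px / 255, raw(), quality = quality / 100),
                    error = function(e)
                      stop("JPEG encoding failed: ", conditionMessage(e),
                           call. = FALSE))
  pct <- 100 * length(bytes) / prod(dim(px))
  if (pct > 100)
    warning(sprintf("JPEG larger than raw size (%.1f%%)", pct), call. = FALSE)
  pct
}

#' Compute the six-feature table for a stimulus set
#'
#' One row per (layer, seed) with mean hue, saturation and brightness,
#' JPEG compression percentage, Feature Congestion and Sub-band Entropy.
#' Accepts either the in-memory result of [generate_stimulus_set()] or a
#' directory of PNGs plus its manifest. Unreadable images are flagged (NA
#' feature cells, `error` column) and the run continues.
#'
#' @param stimuli result of [generate_stimulus_set()] with `keep_images`,
#'   or a directory path.
#' @param manifest manifest data.frame; defaults to the set's own manifest or
#'   `manifest.csv` inside the directory.
#' @param out_csv optional path to write the table as CSV.
#' @return data.frame with columns `layer`, `seed`, `hue`, `saturation`,
#'   `brightness`, `jpeg_pct`, `cfc`, `cse`, `error`.
#' @export
compute_feature_table <- function(stimuli, manifest = NULL, out_csv = NULL) {
  if (is.character(stimuli)) {
    dir <- stimuli
    if (is.null(manifest))
      manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                                  stringsAsFactors = FALSE)
    get_pixels <- function(f) png::readPNG(file.path(dir, f)) * 255
  } else {
    if (is.null(stimuli$images))
      stop("stimuli must carry images (use keep_images = TRUE) or be a directory")
    if (is.null(manifest)) manifest <- stimuli$manifest
    get_pixels <- function(f) as_pixel_array(stimuli$images[[f]])
  }
  n <- nrow(manifest)
  tab <- data.frame(layer = manifest$layer, seed = manifest$seed,
                    hue = NA_real_, saturation = NA_real_,
                    brightness = NA_real_, jpeg_pct = NA_real_,
                    cfc = NA_real_, cse = NA_real_, error = NA_character_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    px <- tryCatch(get_pixels(manifest$file[r]), error = function(e) e)
    if (inherits(px, "error") || is.null(px)) {
      tab$error[r] <- if (is.null(px)) "missing image" else conditionMessage(px)
      warning(sprintf("row %d (%s): %s", r, manifest$file[r], tab$error[r]),
              call. = FALSE)
      next
    }
    hsb <- hsv_means(px)
    tab$hue[r] <- hsb[["hue"]]
    tab$saturation[r] <- hsb[["saturation"]]
    tab$brightness[r] <- hsb[["brightness"]]
    tab$jpeg_pct[r] <- jpeg_pct(px)
    tab$cfc[r] <- feature_congestion(px)
    tab$cse[r] <- subband_entropy(px)
  }
  if (anyDuplicated(tab[c("layer", "seed")]))
    stop("duplicate (layer, seed) keys in manifest")
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}

#' Per-layer across-seed variances of the six image properties
#'
#' Sample variance (n - 1 denominator) of each feature across the seeds of
#' every layer, quantifying how repeatable the synthesized appearance is
#' across noise initialisations. Layers with fewer than two seeds are
#' excluded with a warning.
#'
#' @param table a feature table from [compute_feature_table()].
#' @return data.frame with columns `layer`, `n_seeds` and the variance of
#'   each of the six features.
#' @export
feature_variances <- function(table) {
  feats <- c("hue", "saturation", "brightness", "jpeg_pct", "cfc", "cse")
  stopifnot(all(feats %in% names(table)))
  split_tab <- split(table[feats], table$layer)
  counts <- vapply(split_tab, nrow, 0L)
  drop <- names(counts)[counts < 2L]
  if (length(drop))
    warning("excluding single-seed layers: ", paste(drop, collapse = ", "),
            call. = FALSE)
  keep <- setdiff(names(split_tab), drop)
  out <- data.frame(layer = keep,
                    n_seeds = counts[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  for (f in feats)
    out[[paste0("var_", f)]] <-
      vapply(split_tab[keep], function(d) stats::var(d[[f]]), 0)
  out
}
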