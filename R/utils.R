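# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clip_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Half-away-from-zero rounding; base round() is half-to-even.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stop_unknown_layer <- function(layer_name, available) {
  stop(sprintf("unknown layer '%s'; available layers: %s",
               layer_name, paste(available, collapse = ", ")), call. = FALSE)
}

as_pixel_array <- function(image) {
  if (inherits(image, "stimulus_image")) image <- image$pixels
  if (!(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3))
    stop("expected an RGB image: a height x width x 3 array", call. = FALSE)
  storage.mode(image) <- "double"
  image
}
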