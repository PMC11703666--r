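#' Synthesis configuration
#'
#' Parameters of the iterative activation-maximization loop. The defaults
#' reproduce the stimulus-generation protocol used throughout the package:
#' an 800 x 800 uniform mid-gray base image (gray level 128), additive
#' Gaussian noise with mean 0 and standard deviation 12.75 intensity units,
#' and gradient-ascent updates with a fixed step size of 2 intensity units
#' per iteration, with pixels clipped and rounded to integers in [0, 255]
#' after every update.
#'
#' @param image_size pixels per side of the (square) synthesized image.
#' @param base_gray integer gray level of the base image, in [0, 255].
#' @param noise_mean,noise_sd mean and SD of the additive Gaussian noise.
#' @param step_size intensity units added per iteration along the
#'   normalised gradient; must be positive.
#' @param max_iterations iteration cap; reaching it without a fixed point is
#'   reported with a warning, not an error.
#' @param seed non-negative integer seed for the noise draw.
#' @return an object of class `synthesis_config`.
#' @export
synthesis_config <- function(image_size = 800L, base_gray = 128L,
                             noise_mean = 0, noise_sd = 12.75,
                             step_size = 2, max_iterations = 1000L,
                             seed = 0L) {
  stopifnot(image_size >= 8, base_gray >= 0, base_gray <= 255,
            noise_sd >= 0, step_size > 0, max_iterations >= 1, seed >= 0)
  structure(list(image_size = as.integer(image_size),
                 base_gray = as.integer(base_gray),
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 step_size = step_size,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "synthesis_config")
}

#' Layer target
#'
#' Names the layer whose summed activations are maximised, with an optional
#' subset of neuron (linear) indices within that layer's activation array.
#'
#' @param layer_name layer identifier; must exist in the model adapter.
#' @param neuron_subset optional integer indices into the layer's activations.
#' @export
layer_target <- function(layer_name, neuron_subset = NULL) {
  stopifnot(is.character(layer_name), length(layer_name) == 1L)
  if (!is.null(neuron_subset))
    stopifnot(is.numeric(neuron_subset), all(neuron_subset >= 1))
  structure(list(layer_name = layer_name, neuron_subset = neuron_subset),
            class = "layer_target")
}

stimulus_image <- function(pixels, layer_name = NA_character_, seed = NA_integer_,
                           iterations_run = 0L, converged = NA) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  structure(list(pixels = pixels, layer_name = layer_name, seed = seed,
                 iterations_run = as.integer(iterations_run),
                 converged = converged),
            class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<stimulus_image> %dx%dx%d layer=%s seed=%s iterations=%d converged=%s\n",
              d[1], d[2], d[3], x$layer_name, x$seed, x$iterations_run,
              x$converged))
  invisible(x)
}

#' Quantize a continuous pixel grid to valid pixel values
#'
#' Clips element-wise to [0, 255] and rounds to the nearest integer, halves
#' away from zero, so the result is bit-reproducible across platforms.
#'
#' @param x a real-valued array.
#' @return an integer-valued array of the same shape.
#' @export
quantize_pixels <- function(x) {
  q <- round_half_away(clip_range(x, 0, 255))
  storage.mode(q) <- "integer"
  q
}

#' Generate the noisy gray base image
#'
#' Builds a uniform gray square image, adds i.i.d. Gaussian noise generated
#' from the configured seed, and quantizes the result. Deterministic per seed.
#'
#' @param config a [synthesis_config()].
#' @return a [stimulus_image] with `iterations_run = 0`.
#' @export
make_base_image <- function(config = synthesis_config()) {
  stopifnot(inherits(config, "synthesis_config"))
  n <- config$image_size
  noise <- withr::with_seed(config$seed,
    stats::rnorm(n * n * 3L, mean = config$noise_mean, sd = config$noise_sd))
  px <- quantize_pixels(array(config$base_gray + noise, c(n, n, 3L)))
  stimulus_image(px, seed = config$seed)
}

#' One gradient-ascent step
#'
#' Adds `step_size * g / mean(|g|)` to the image, where `g` is the gradient
#' of the summed target activations with respect to the pixels. The gradient
#' is normalised by its mean absolute value (plus 1e-8) so the step size is
#' expressed in pixel-intensity units regardless of the raw gradient scale;
#' a zero gradient leaves the image unchanged.
#'
#' @param image continuous pixel grid (not yet quantized).
#' @param model a [model_adapter()].
#' @param target a [layer_target()].
#' @param step_size intensity units per step.
#' @return the updated continuous pixel grid.
#' @export
ascent_step <- function(image, model, target, step_size = 2) {
  stopifnot(inherits(model, "model_adapter"), inherits(target, "layer_target"))
  if (!target$layer_name %in% model$layer_names)
    stop_unknown_layer(target$layer_name, model$layer_names)
  g <- model$gradient(target$layer_name, image, target$neuron_subset)
  stopifnot(identical(dim(g), dim(as_pixel_array(image))))
  image + step_size * g / (mean(abs(g)) + 1e-8)
}

#' Sum of target activations
#'
#' @inheritParams ascent_step
#' @return scalar sum of the (optionally subset) activations.
#' @export
activation_sum <- function(model, target, image) {
  stopifnot(inherits(model, "model_adapter"), inherits(target, "layer_target"))
  if (!target$layer_name %in% model$layer_names)
    stop_unknown_layer(target$layer_name, model$layer_names)
  sum(model$activations(target$layer_name, image, target$neuron_subset))
}

#' Synthesize a stimulus by iterative activation maximization
#'
#' Starting from [make_base_image()], alternates [ascent_step()] and
#' [quantize_pixels()] until the quantized image is identical on two
#' consecutive iterations (a fixed point of the update, `converged = TRUE`)
#' or `max_iterations` is reached (`converged = FALSE`, with a warning).
#'
#' @inheritParams ascent_step
#' @param config a [synthesis_config()].
#' @return a [stimulus_image] recording layer, seed, iterations and
#'   convergence status.
#' @export
synthesize <- function(model, target, config = synthesis_config()) {
  stopifnot(inherits(model, "model_adapter"), inherits(target, "layer_target"),
            inherits(config, "synthesis_config"))
  if (!target$layer_name %in% model$layer_names)
    stop_unknown_layer(target$layer_name, model$layer_names)
  img <- make_base_image(config)$pixels
  converged <- FALSE
  iters <- 0L
  for (k in seq_len(config$max_iterations)) {
    iters <- k
    nxt <- quantize_pixels(ascent_step(img, model, target, config$step_size))
    if (identical(nxt, img)) { converged <- TRUE; break }
    img <- nxt
  }
  if (!converged)
    warning(sprintf("layer '%s' seed %d: no fixed point within %d iterations",
                    target$layer_name, config$seed, config$max_iterations),
            call. = FALSE)
  stimulus_image(img, layer_name = target$layer_name, seed = config$seed,
                 iterations_run = iters, converged = converged)
}

#' Read a layer-name inventory
#'
#' One layer name per line; blank lines ignored; names must be unique.
#'
#' @param path text file path.
#' @return character vector of layer names.
#' @export
read_layer_inventory <- function(path) {
  nm <- readLines(path, warn = FALSE)
  nm <- nm[nzchar(trimws(nm))]
  if (anyDuplicated(nm)) stop("layer inventory contains duplicate names")
  if (length(nm) == 0L) stop("layer inventory is empty")
  nm
}

#' The packaged 144-name Inception-style layer inventory
#'
#' The ordered list of 144 layer and sub-layer names targeted in the full
#' replication run: the GoogLeNet-style stem (`conv2d0` ... `maxpool1`),
#' nine inception modules `mixed3a` ... `mixed5b` with their `1x1`, `3x3`,
#' `5x5`, bottleneck, pool and pool-reduce sub-layers (pre- and post-ReLU),
#' and the network head. Synthesizing five images for each name yields the
#' 720-stimulus design.
#'
#' @return character vector of length 144.
#' @export
inception_layer_inventory <- function() {
  nm <- read_layer_inventory(system.file("extdata", "inception_layers.txt",
                                         package = "dreamaffect", mustWork = TRUE))
  stopifnot(length(nm) == 144L)
  nm
}

#' Schedule the (layer, seed) stimulus jobs
#'
#' @param inventory character vector of layer names.
#' @param n_seeds number of noise seeds per layer (seeds `0 ... n_seeds - 1`).
#' @return data.frame with columns `layer`, `seed`, `file`.
#' @export
schedule_stimuli <- function(inventory, n_seeds = 5L) {
  stopifnot(length(inventory) >= 1L, n_seeds >= 1L)
  jobs <- expand.grid(seed = 0:(n_seeds - 1L), layer = inventory,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  jobs <- jobs[, c("layer", "seed")]
  jobs$file <- sprintf("%s_seed%d.png", jobs$layer, jobs$seed)
  rownames(jobs) <- NULL
  jobs
}

#' Generate a full stimulus set with manifest
#'
#' Synthesizes one image per (layer, seed) pair over the inventory, writing
#' 8-bit RGB PNGs and a `manifest.csv` when `out_dir` is given. Per-layer
#' failures are recorded in the manifest and the run continues.
#'
#' @param model a [model_adapter()].
#' @param inventory character vector of layer names.
#' @param config a [synthesis_config()]; its `seed` field is replaced by the
#'   per-image seed.
#' @param n_seeds seeds per layer, `0 ... n_seeds - 1`.
#' @param out_dir optional output directory for PNGs and the manifest.
#' @param keep_images keep the pixel arrays in the returned object.
#' @return list with `manifest` (data.frame: file, layer, seed, iterations,
#'   converged, error) and, if `keep_images`, `images` (named list).
#' @export
generate_stimulus_set <- function(model, inventory, config = synthesis_config(),
                                  n_seeds = 5L, out_dir = NULL,
                                  keep_images = is.null(out_dir)) {
  jobs <- schedule_stimuli(inventory, n_seeds)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- data.frame(file = jobs$file, layer = jobs$layer, seed = jobs$seed,
                         iterations = NA_integer_, converged = NA,
                         error = NA_character_, stringsAsFactors = FALSE)
  images <- if (keep_images) stats::setNames(vector("list", nrow(jobs)), jobs$file)
  for (r in seq_len(nrow(jobs))) {
    cfg <- config
    cfg$seed <- as.integer(jobs$seed[r])
    res <- tryCatch(
      withCallingHandlers(
        synthesize(model, layer_target(jobs$layer[r]), cfg),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(res, "error")) {
      manifest$error[r] <- conditionMessage(res)
      next
    }
    manifest$iterations[r] <- res$iterations_run
    manifest$converged[r] <- res$converged
    if (!is.null(out_dir))
      png::writePNG(res$pixels / 255, file.path(out_dir, jobs$file[r]))
    if (keep_images) images[[jobs$file[r]]] <- res
  }
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  out <- list(manifest = manifest)
  if (keep_images) out$images <- images
  out
}
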