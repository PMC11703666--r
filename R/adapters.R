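#' Model adapter contract
#'
#' A model adapter exposes a differentiable image model to the synthesis
#' engine through three things: an ordered list of named layers, an
#' `activations(layer_name, image, neuron_subset)` function returning the
#' numeric activation array of that layer, and a
#' `gradient(layer_name, image, neuron_subset)` function returning the
#' gradient of the *sum* of the (optionally subset) activations with respect
#' to each input pixel. The gradient must have the same shape as the image,
#' and repeated calls on identical input must return identical output.
#'
#' @param layer_names character vector of unique layer names, in network order.
#' @param activations function(layer_name, image, neuron_subset = NULL).
#' @param gradient function(layer_name, image, neuron_subset = NULL).
#' @return an object of class `model_adapter`.
#' @seealso [tiny_cnn_adapter()], [pixel_sum_adapter()], [constant_adapter()]
#' @export
model_adapter <- function(layer_names, activations, gradient) {
  stopifnot(is.character(layer_names), length(layer_names) >= 1L,
            !anyDuplicated(layer_names),
            is.function(activations), is.function(gradient))
  structure(list(layer_names = layer_names,
                 activations = activations,
                 gradient = gradient),
            class = "model_adapter")
}

#' @export
print.model_adapter <- function(x, ...) {
  cat("<model_adapter> ", length(x$layer_names), " layers: ",
      paste(utils::head(x$layer_names, 4), collapse = ", "),
      if (length(x$layer_names) > 4) ", ..." else "", "\n", sep = "")
  invisible(x)
}

## ---- minimal convolutional machinery (forward + input-gradient) ----------
## The fixture network is small enough that plain vectorised R loops over
## kernel taps are fast; no compiled code is needed.

conv2d_same <- function(x, w, b = NULL) {
  d <- dim(x); H <- d[1L]; W <- d[2L]
  kh <- dim(w)[1L]; kw <- dim(w)[2L]; cin <- dim(w)[3L]; cout <- dim(w)[4L]
  stopifnot(d[3L] == cin, kh %% 2L == 1L, kw %% 2L == 1L)
  rr <- (kh - 1L) %/% 2L; cc <- (kw - 1L) %/% 2L
  pad <- array(0, c(H + kh - 1L, W + kw - 1L, cin))
  pad[rr + seq_len(H), cc + seq_len(W), ] <- x
  out <- array(0, c(H, W, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(if (is.null(b)) 0 else b[co], H, W)
    for (i in seq_len(kh)) for (j in seq_len(kw)) for (ci in seq_len(cin))
      acc <- acc + w[i, j, ci, co] * pad[i:(i + H - 1L), j:(j + W - 1L), ci]
    out[, , co] <- acc
  }
  out
}

conv2d_same_grad_input <- function(g, w) {
  d <- dim(g); H <- d[1L]; W <- d[2L]
  kh <- dim(w)[1L]; kw <- dim(w)[2L]; cin <- dim(w)[3L]; cout <- dim(w)[4L]
  rr <- (kh - 1L) %/% 2L; cc <- (kw - 1L) %/% 2L
  dpad <- array(0, c(H + kh - 1L, W + kw - 1L, cin))
  for (co in seq_len(cout)) {
    gco <- g[, , co]
    for (i in seq_len(kh)) for (j in seq_len(kw)) for (ci in seq_len(cin))
      dpad[i:(i + H - 1L), j:(j + W - 1L), ci] <-
        dpad[i:(i + H - 1L), j:(j + W - 1L), ci] + w[i, j, ci, co] * gco
  }
  dpad[rr + seq_len(H), cc + seq_len(W), , drop = FALSE]
}

maxpool2 <- function(x) {
  d <- dim(x); H <- d[1L]; W <- d[2L]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  o <- array(-Inf, c(H %/% 2L, W %/% 2L, d[3L]))
  for (i in 1:2) for (j in 1:2)
    o <- pmax(o, x[seq(i, H, 2L), seq(j, W, 2L), , drop = FALSE])
  o
}

maxpool2_grad_input <- function(x, g) {
  d <- dim(x); H <- d[1L]; W <- d[2L]
  o <- maxpool2(x)
  dx <- array(0, d)
  taken <- array(FALSE, dim(o))
  for (i in 1:2) for (j in 1:2) {
    sub <- x[seq(i, H, 2L), seq(j, W, 2L), , drop = FALSE]
    hit <- (sub == o) & !taken          # first-max tie break, fixed scan order
    taken <- taken | hit
    tmp <- dx[seq(i, H, 2L), seq(j, W, 2L), , drop = FALSE]
    tmp[hit] <- g[hit]
    dx[seq(i, H, 2L), seq(j, W, 2L), ] <- tmp
  }
  dx
}

chain_forward <- function(specs, x, upto = length(specs)) {
  inputs <- vector("list", upto)
  for (k in seq_len(upto)) {
    inputs[[k]] <- x
    sp <- specs[[k]]
    x <- switch(sp$type,
                conv    = conv2d_same(x, sp$w, sp$b),
                relu    = pmax(x, 0),
                maxpool = maxpool2(x),
                stop("unknown layer type: ", sp$type))
  }
  list(out = x, inputs = inputs)
}

chain_gradient <- function(specs, x, upto, seed_grad) {
  fw <- chain_forward(specs, x, upto)
  g <- seed_grad
  for (k in rev(seq_len(upto))) {
    sp <- specs[[k]]
    g <- switch(sp$type,
                conv    = conv2d_same_grad_input(g, sp$w),
                relu    = g * (fw$inputs[[k]] > 0),
                maxpool = maxpool2_grad_input(fw$inputs[[k]], g))
  }
  g
}

seed_gradient <- function(act, neuron_subset = NULL) {
  if (is.null(neuron_subset)) return(array(1, dim(act)))
  stopifnot(all(neuron_subset >= 1L), all(neuron_subset <= length(act)))
  g <- array(0, dim(act))
  g[neuron_subset] <- 1
  g
}

#' Fixture convolutional network adapter
#'
#' A small two-block CNN (conv 3x3 -> ReLU -> maxpool 2x2, twice) whose
#' weights are drawn from a fixed seed, so tests and examples need no
#' pretrained download. Layer names follow the `*_pre_relu` convention of
#' Inception-style graphs: the convolution output is `convK_pre_relu`, its
#' rectified version `convK`, and the pooled map `poolK`. Input images must
#' be RGB with both sides a multiple of 4 (two 2x2 pools).
#'
#' @param seed integer seed for the weight draw.
#' @param channels integer vector of length 2: output channels of each block.
#' @return a [model_adapter()].
#' @export
tiny_cnn_adapter <- function(seed = 42L, channels = c(4L, 8L)) {
  draw <- withr::with_seed(seed, list(
    w1 = array(stats::rnorm(3 * 3 * 3 * channels[1], sd = 0.1),
               c(3, 3, 3, channels[1])),
    b1 = stats::rnorm(channels[1], sd = 0.01),
    w2 = array(stats::rnorm(3 * 3 * channels[1] * channels[2], sd = 0.1),
               c(3, 3, channels[1], channels[2])),
    b2 = stats::rnorm(channels[2], sd = 0.01)))
  specs <- list(
    list(name = "conv1_pre_relu", type = "conv", w = draw$w1, b = draw$b1),
    list(name = "conv1",          type = "relu"),
    list(name = "pool1",          type = "maxpool"),
    list(name = "conv2_pre_relu", type = "conv", w = draw$w2, b = draw$b2),
    list(name = "conv2",          type = "relu"),
    list(name = "pool2",          type = "maxpool"))
  nms <- vapply(specs, `[[`, "", "name")
  prep <- function(image) as_pixel_array(image) / 255
  model_adapter(
    layer_names = nms,
    activations = function(layer_name, image, neuron_subset = NULL) {
      k <- match(layer_name, nms)
      if (is.na(k)) stop_unknown_layer(layer_name, nms)
      act <- chain_forward(specs, prep(image), k)$out
      if (is.null(neuron_subset)) act else act[neuron_subset]
    },
    gradient = function(layer_name, image, neuron_subset = NULL) {
      k <- match(layer_name, nms)
      if (is.na(k)) stop_unknown_layer(layer_name, nms)
      x <- prep(image)
      act <- chain_forward(specs, x, k)$out
      chain_gradient(specs, x, k, seed_gradient(act, neuron_subset)) / 255
    })
}

#' Degenerate adapters for closed-form checks
#'
#' `pixel_sum_adapter()` exposes one layer, `pixel_sum`, whose single
#' "activation" is the sum of all input pixels; its gradient is uniformly 1,
#' so gradient ascent drives every pixel up by one (normalised) step per
#' iteration until the image saturates at 255. `constant_adapter()` exposes a
#' layer `const` whose activation ignores the input and whose gradient is
#' zero, so synthesis converges immediately on the base image.
#'
#' @param value activation value returned by the constant adapter.
#' @return a [model_adapter()].
#' @export
pixel_sum_adapter <- function() {
  model_adapter(
    layer_names = "pixel_sum",
    activations = function(layer_name, image, neuron_subset = NULL) {
      if (!identical(layer_name, "pixel_sum")) stop_unknown_layer(layer_name, "pixel_sum")
      array(sum(as_pixel_array(image)), c(1, 1, 1))
    },
    gradient = function(layer_name, image, neuron_subset = NULL) {
      if (!identical(layer_name, "pixel_sum")) stop_unknown_layer(layer_name, "pixel_sum")
      array(1, dim(as_pixel_array(image)))
    })
}

#' @rdname pixel_sum_adapter
#' @export
constant_adapter <- function(value = 1) {
  model_adapter(
    layer_names = "const",
    activations = function(layer_name, image, neuron_subset = NULL) {
      if (!identical(layer_name, "const")) stop_unknown_layer(layer_name, "const")
      array(value, c(1, 1, 1))
    },
    gradient = function(layer_name, image, neuron_subset = NULL) {
      if (!identical(layer_name, "const")) stop_unknown_layer(layer_name, "const")
      array(0, dim(as_pixel_array(image)))
    })
}
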