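test_that("base image generation is seeded and respects degenerate noise", {
  cfg0 <- synthesis_config(image_size = 16, noise_sd = 0, seed = 3)
  b0 <- make_base_image(cfg0)
  expect_true(all(b0$pixels == 128L))
  cfg <- synthesis_config(image_size = 16, seed = 9)
  expect_identical(make_base_image(cfg)$pixels, make_base_image(cfg)$pixels)
  cfg2 <- synthesis_config(image_size = 16, seed = 10)
  expect_false(identical(make_base_image(cfg)$pixels,
                         make_base_image(cfg2)$pixels))
})

test_that("quantization clips then rounds halves away from zero", {
  expect_identical(quantize_pixels(array(-5.4, c(1, 1, 3)))[1], 0L)
  expect_identical(quantize_pixels(array(260.2, c(1, 1, 3)))[1], 255L)
  expect_identical(quantize_pixels(array(127.5, c(1, 1, 3)))[1], 128L)
  expect_identical(quantize_pixels(array(0.5, c(1, 1, 3)))[1], 1L)
  x <- array(c(-3, 0, 1.49, 254.5, 300, 17.5), c(2, 1, 3))
  expect_identical(as.integer(quantize_pixels(x)),
                   c(0L, 0L, 1L, 255L, 255L, 18L))
})

test_that("ascent step normalises the gradient into intensity units", {
  img <- array(100, c(4, 4, 3))
  # zero gradient -> unchanged
  expect_equal(ascent_step(img, constant_adapter(), layer_target("const"), 2),
               img)
  # uniform gradient (mean |g| = 1) -> every pixel up by exactly step_size
  stepped <- ascent_step(img, pixel_sum_adapter(), layer_target("pixel_sum"),
                         step_size = 2)
  expect_equal(stepped, img + 2, tolerance = 1e-7)
  # first-order ascent on the fixture CNN with a small step
  m <- tiny_cnn_adapter()
  tgt <- layer_target("conv2_pre_relu")
  x <- random_image(4, side = 8)
  before <- activation_sum(m, tgt, x)
  after <- activation_sum(m, tgt, ascent_step(x, m, tgt, step_size = 0.01))
  expect_gt(after, before)
})

test_that("synthesis converges to fixed points", {
  # constant activations: gradient zero, base image is already a fixed point
  cfg <- synthesis_config(image_size = 8, seed = 1, max_iterations = 10)
  s <- synthesize(constant_adapter(), layer_target("const"), cfg)
  expect_true(s$converged)
  expect_identical(s$iterations_run, 1L)
  expect_identical(s$pixels, make_base_image(cfg)$pixels)
  # re-running one more iteration on a converged image returns it unchanged
  again <- quantize_pixels(ascent_step(s$pixels, constant_adapter(),
                                       layer_target("const"), cfg$step_size))
  expect_identical(again, s$pixels)
})

test_that("sum-of-pixels model saturates to all-255 in the closed-form count", {
  cfg <- synthesis_config(image_size = 8, noise_sd = 0, step_size = 2,
                          max_iterations = 200, seed = 0)
  s <- synthesize(pixel_sum_adapter(), layer_target("pixel_sum"), cfg)
  expect_true(s$converged)
  expect_true(all(s$pixels == 255L))
  # each pixel climbs by step_size per iteration until clipped, plus one
  # confirming iteration to detect the fixed point
  bound <- ceiling((255 - 128) / cfg$step_size) + 1
  expect_lte(s$iterations_run, bound)
  # fixed-point property after saturation
  again <- quantize_pixels(ascent_step(s$pixels, pixel_sum_adapter(),
                                       layer_target("pixel_sum"), 2))
  expect_identical(again, s$pixels)
})

test_that("synthesis is deterministic and every boundary image is valid", {
  m <- tiny_cnn_adapter()
  cfg <- synthesis_config(image_size = 8, seed = 2, max_iterations = 6)
  s1 <- suppressWarnings(synthesize(m, layer_target("conv1"), cfg))
  s2 <- suppressWarnings(synthesize(m, layer_target("conv1"), cfg))
  expect_identical(s1$pixels, s2$pixels)
  expect_true(all(s1$pixels == floor(s1$pixels)))
  expect_true(all(s1$pixels >= 0L & s1$pixels <= 255L))
  # hitting the cap warns and flags converged = FALSE
  cfg1 <- synthesis_config(image_size = 8, seed = 2, max_iterations = 1)
  expect_warning(s3 <- synthesize(m, layer_target("conv1"), cfg1),
                 "no fixed point")
  expect_false(s3$converged)
})

test_that("stimulus scheduling covers the full layer-by-seed design", {
  expect_identical(nrow(schedule_stimuli(inception_layer_inventory(), 5)),
                   720L)
  jobs <- schedule_stimuli(letters[1:6], 2)
  expect_identical(nrow(jobs), 12L)
  expect_false(anyDuplicated(jobs[c("layer", "seed")]) > 0)
})

test_that("generate_stimulus_set emits a consistent manifest and recovers from failures", {
  m <- tiny_cnn_adapter()
  cfg <- synthesis_config(image_size = 8, max_iterations = 4)
  out <- tempfile("stim")
  set <- suppressWarnings(generate_stimulus_set(
    m, c("conv1", "conv2"), cfg, n_seeds = 2, out_dir = out,
    keep_images = TRUE))
  expect_identical(nrow(set$manifest), 4L)
  expect_true(all(file.exists(file.path(out, set$manifest$file))))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  roundtrip <- png::readPNG(file.path(out, set$manifest$file[1])) * 255
  expect_equal(roundtrip, unname(set$images[[1]]$pixels), tolerance = 1e-9)
  # a bad layer is recorded, the run continues
  set2 <- suppressWarnings(generate_stimulus_set(
    m, c("conv1", "bogus"), cfg, n_seeds = 1, keep_images = TRUE))
  expect_match(set2$manifest$error[2], "available layers")
  expect_false(is.na(set2$manifest$iterations[1]))
})
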