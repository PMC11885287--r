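test_that("conv2d matches the quadruple-loop oracle and its contracts", {
  set.seed(8)
  x <- array(stats::rnorm(5 * 5 * 2), c(5, 5, 2))
  W <- array(stats::rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  b <- stats::rnorm(4)
  y <- conv2d(x, conv_layer(W, b, "identity"))
  expect_lt(max(abs(y - oracle_conv(x, W, b))), 1e-10)

  # 1x1 unit kernel, zero bias, identity activation reproduces the input
  one <- conv_layer(array(1, c(1, 1, 1, 1)), activation = "identity")
  img <- array(stats::rnorm(16), c(4, 4, 1))
  expect_equal(conv2d(img, one), img)

  # ReLU clamps at zero
  yr <- conv2d(x, conv_layer(W, b, "relu"))
  expect_gte(min(yr), 0)

  expect_error(conv2d(array(0, c(4, 4, 3)), conv_layer(W, b)),
               class = "avifuse_shape_error")
  expect_error(conv2d(array(0, c(2, 2, 2)), conv_layer(W, b)),
               class = "avifuse_shape_error")
})

test_that("max pooling matches a brute-force window scan", {
  expect_equal(as.vector(max_pool(matrix(c(1, 3, 2, 4), 2, 2), 2)), 4)
  const <- array(2.5, c(4, 4, 2))
  expect_true(all(max_pool(const, 2) == 2.5))
  set.seed(9)
  x <- array(stats::rnorm(7 * 7 * 3), c(7, 7, 3))
  expect_equal(max_pool(x, 3, 2), oracle_pool(x, 3, 2))
  expect_error(max_pool(matrix(0, 2, 2), 5), class = "avifuse_shape_error")
})

test_that("residual blocks add the shortcut and pass gradients", {
  set.seed(10)
  x <- array(stats::rnorm(6 * 6 * 2), c(6, 6, 2))
  zero_block <- residual_block(list(
    conv_layer(array(0, c(3, 3, 2, 2)), activation = "relu", pad = 1L),
    conv_layer(array(0, c(3, 3, 2, 2)), activation = "identity", pad = 1L)),
    final_relu = FALSE)
  expect_equal(residual_forward(x, zero_block), x)

  rnd_block <- residual_block(list(
    conv_layer(array(stats::rnorm(3 * 3 * 2 * 2, 0, 0.3), c(3, 3, 2, 2)),
               activation = "relu", pad = 1L),
    conv_layer(array(stats::rnorm(3 * 3 * 2 * 2, 0, 0.3), c(3, 3, 2, 2)),
               activation = "identity", pad = 1L)), final_relu = FALSE)
  out <- residual_forward(x, rnd_block)
  inner <- conv2d(conv2d(x, rnd_block$layers[[1]]), rnd_block$layers[[2]])
  expect_lt(max(abs((out - x) - inner)), 1e-10)

  # numerical gradient through the block: identity path present
  fw <- residual_forward(x, rnd_block, keep_cache = TRUE)
  dout <- array(stats::rnorm(length(fw)), dim = dim(fw))
  bwd <- avifuse:::residual_backward(dout, rnd_block, attr(fw, "cache"))
  f0 <- sum(fw * dout)
  eps <- 1e-5
  for (probe in list(c(1, 1, 1), c(3, 4, 2), c(6, 6, 1))) {
    x2 <- x
    x2[probe[1], probe[2], probe[3]] <- x2[probe[1], probe[2], probe[3]] + eps
    f1 <- sum(residual_forward(x2, rnd_block) * dout)
    expect_lt(abs((f1 - f0) / eps - bwd$dx[probe[1], probe[2], probe[3]]), 1e-4)
  }

  bad <- residual_block(list(conv_layer(array(0, c(3, 3, 2, 5)),
                                        activation = "identity", pad = 1L)))
  expect_error(residual_forward(x, bad), class = "avifuse_shape_error")
})

test_that("image preprocessing is bounded, deterministic and involutive", {
  set.seed(11)
  img <- array(stats::runif(48 * 40 * 3), c(48, 40, 3))
  p1 <- preprocess_image(img, size = 32)
  expect_equal(dim(p1), c(32, 32, 3))
  expect_gte(min(p1), 0)
  expect_lte(max(p1), 1)
  expect_identical(p1, preprocess_image(img, size = 32))

  # 8-bit input is rescaled
  p255 <- preprocess_image(img * 255, size = 32)
  expect_lte(max(p255), 1)

  # forced flip applied twice restores the original
  flip_only <- list(crop = FALSE, flip_p = 1, brightness = c(1, 1))
  f1 <- preprocess_image(img, size = 48, augment = flip_only, seed = 1)
  # feed the flipped image back through the same forced flip
  f2 <- preprocess_image(f1, size = 48, augment = flip_only, seed = 1)
  expect_equal(f2, preprocess_image(img, size = 48), tolerance = 1e-12)

  aug <- list(crop = TRUE, flip_p = 0.5, brightness = c(0.8, 1.2))
  a1 <- preprocess_image(img, size = 32, augment = aug, seed = 7)
  expect_identical(a1, preprocess_image(img, size = 32, augment = aug, seed = 7))
  expect_gte(min(a1), 0)
  expect_lte(max(a1), 1)

  expect_error(preprocess_image(matrix(0, 40, 40)), class = "avifuse_format_error")
  expect_error(preprocess_image(array(0, c(8, 8, 3))),
               class = "avifuse_format_error")
})

test_that("tiny backbone embeds deterministically at the configured width", {
  bk <- build_backbone(backbone_config("tiny", 24L, seed = 6))
  img <- array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  e1 <- visual_embed(img, bk)
  expect_length(e1, 24)
  expect_identical(attr(e1, "modality"), "visual")
  expect_identical(as.numeric(e1), as.numeric(visual_embed(img, bk)))
  # same config rebuilds the same weights
  e2 <- visual_embed(img, build_backbone(backbone_config("tiny", 24L, seed = 6)))
  expect_identical(as.numeric(e1), as.numeric(e2))
})

test_that("LSTM cell follows the gate equations exactly", {
  p <- lstm_params(3L, 5L, seed = 12)
  head <- dense_layer(diag(5))

  # all-zero parameters, one step: gates 0.5, candidate 0 => h = 0
  p0 <- p
  for (nm in c("W_f", "W_i", "W_C", "W_o")) p0[[nm]][] <- 0
  e0 <- lstm_encode(matrix(stats::rnorm(3), 1, 3), p0, head)
  expect_equal(as.numeric(e0), numeric(5))

  # random single step against the literal oracle
  x1 <- stats::rnorm(3)
  got <- lstm_encode(matrix(x1, 1, 3), p, head)
  want <- oracle_lstm_step(p, numeric(5), numeric(5), x1)$h
  expect_lt(max(abs(as.numeric(got) - want)), 1e-10)

  # two steps against the iterated oracle
  x2 <- stats::rnorm(3)
  s1 <- oracle_lstm_step(p, numeric(5), numeric(5), x1)
  s2 <- oracle_lstm_step(p, s1$h, s1$C, x2)
  got2 <- lstm_encode(rbind(x1, x2), p, head)
  expect_lt(max(abs(as.numeric(got2) - s2$h)), 1e-10)

  # order matters: swapping frames changes the encoding
  got_swapped <- lstm_encode(rbind(x2, x1), p, head)
  expect_gt(max(abs(as.numeric(got2) - as.numeric(got_swapped))), 1e-8)

  expect_error(lstm_encode(matrix(0, 2, 4), p, head),
               class = "avifuse_shape_error")
})

test_that("LSTM backward matches numerical gradients", {
  set.seed(13)
  p <- lstm_params(2L, 3L, seed = 14)
  s <- matrix(stats::rnorm(8), 4, 2)
  fw <- avifuse:::lstm_forward(s, p, keep_cache = TRUE)
  dh <- stats::rnorm(3)
  gr <- avifuse:::lstm_backward(p, fw$cache, dh)
  f0 <- sum(fw$h * dh)
  eps <- 1e-6
  for (nm in c("W_f", "W_C", "b_o")) {
    p2 <- p
    if (is.matrix(p2[[nm]])) {
      p2[[nm]][2, 1] <- p2[[nm]][2, 1] + eps
      want <- gr[[nm]][2, 1]
    } else {
      p2[[nm]][2] <- p2[[nm]][2] + eps
      want <- gr[[nm]][2]
    }
    f1 <- sum(avifuse:::lstm_forward(s, p2) * dh)
    expect_lt(abs((f1 - f0) / eps - want), 1e-5)
  }
})

test_that("GRU step follows its closed forms and the literal oracle", {
  p <- gru_params(3L, 4L, seed = 15)
  p0 <- p
  for (nm in c("W_z", "U_z", "W_r", "U_r", "W", "U")) p0[[nm]][] <- 0
  h_prev <- stats::rnorm(4)
  expect_equal(gru_step(stats::rnorm(3), h_prev, p0), 0.5 * h_prev)
  expect_equal(gru_step(stats::rnorm(3), numeric(4), p0), numeric(4))

  x <- stats::rnorm(3); h <- stats::rnorm(4)
  expect_lt(max(abs(gru_step(x, h, p) - oracle_gru_step(p, h, x))), 1e-10)
  expect_error(gru_step(stats::rnorm(5), h, p), class = "avifuse_shape_error")
})

test_that("attention normalizes rows and handles degenerate keys", {
  set.seed(16)
  # single key/value pair: output is that value row, whatever Q is
  V1 <- matrix(c(3, 7, 1), 1, 3)
  out1 <- attention(matrix(stats::rnorm(2), 1, 2), matrix(stats::rnorm(2), 1, 2), V1)
  expect_equal(as.vector(out1), as.vector(V1))

  # identical keys: uniform weights, output = column means of V
  K <- matrix(rep(c(0.3, -0.2), each = 4), 4, 2)
  V <- matrix(stats::rnorm(12), 4, 3)
  out <- attention(matrix(stats::rnorm(2), 1, 2), K, V)
  expect_lt(max(abs(as.vector(out) - colMeans(V))), 1e-12)

  Q <- matrix(stats::rnorm(10), 5, 2)
  K2 <- matrix(stats::rnorm(8), 4, 2)
  w <- attr(attention(Q, K2, V), "weights")
  expect_lt(max(abs(rowSums(w) - 1)), 1e-12)
  expect_error(attention(Q, K2, V[1:3, ]), class = "avifuse_shape_error")
})

test_that("positional encodings follow the sinusoid table", {
  pe <- positional_encoding(6L, 8L)
  expect_equal(dim(pe), c(6, 8))
  expect_equal(pe[1, ], rep(c(0, 1), 4))            # pos = 0
  expect_equal(pe[2, 1], sin(1))
  expect_equal(pe[2, 2], cos(1))
  expect_equal(pe[3, 3], sin(2 / 10000^(2 / 8)))
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positional_encoding(4L, 5L), class = "avifuse_invalid_config")
})
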