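## Layer-level behaviour of the network building blocks, checked against
## hand computations and closed forms.

test_that("the small-scale CNN block is a plain width-3 convolution", {
  conv <- radarecg:::nn_conv1d(1, 1, 3, pad_left = 1)
  conv$par$W[] <- 1
  conv$par$b[] <- 0
  x <- array(0, dim = c(1, 20, 1))
  x[1, 10, 1] <- 1                       # impulse
  y <- conv$forward(x, train = FALSE)
  expect_equal(as.numeric(y[1, , 1]),
               replace(rep(0, 20), 9:11, 1))   # width-3 boxcar
  expect_identical(dim(y), dim(x))
})

test_that("branch geometry is length-preserving at L = 1000", {
  for (scale in c("S", "M", "L")) {
    g <- radarecg:::branch_geometry(scale)
    conv <- radarecg:::nn_conv1d(1, 2, g$k, pad_left = g$pad,
                                 dilation = g$dil)
    y <- conv$forward(array(rnorm(1000), dim = c(1, 1000, 1)), FALSE)
    expect_identical(dim(y)[2], 1000L)
  }
})

test_that("receptive fields follow the dilation closed form", {
  ## single L-block effective extent: (7-1)*2 + 1 = 13 samples
  expect_identical(branch_receptive_field("L", n_blocks = 1)$samples, 13)
  expect_identical(branch_receptive_field("S", n_blocks = 4)$samples, 9)
  expect_identical(branch_receptive_field("M", n_blocks = 4)$samples, 25)
  expect_identical(branch_receptive_field("L", n_blocks = 4)$samples, 49)
})

test_that("causal convolution matches the hand-computed recursion", {
  conv <- radarecg:::nn_conv1d(1, 1, 3, pad_left = 2, pad_right = 0)
  conv$par$W[] <- 1
  conv$par$b[] <- 0
  y <- conv$forward(array(c(1, 2, 3, 4), dim = c(1, 4, 1)), FALSE)
  expect_equal(as.numeric(y), c(1, 3, 6, 9))
})

test_that("causal dilated convolutions never look ahead", {
  set.seed(1)
  k <- 3; d <- 2
  conv <- radarecg:::nn_conv1d(2, 2, k, pad_left = (k - 1) * d,
                               pad_right = 0, dilation = d)
  x1 <- array(rnorm(2 * 30), dim = c(2, 30, 1))
  x2 <- x1
  x2[, 16:30, ] <- rnorm(2 * 15)         # perturb only the future
  y1 <- conv$forward(x1, FALSE)
  y2 <- conv$forward(x2, FALSE)
  expect_equal(y1[, 1:15, ], y2[, 1:15, ])
  expect_false(isTRUE(all.equal(y1[, 16:30, ], y2[, 16:30, ])))
  ## impulse response support = 1 + (k-1)*d
  conv2 <- radarecg:::nn_conv1d(1, 1, k, pad_left = (k - 1) * d,
                                pad_right = 0, dilation = d)
  conv2$par$W[] <- 1; conv2$par$b[] <- 0
  imp <- array(0, dim = c(1, 20, 1)); imp[1, 5, 1] <- 1
  resp <- as.numeric(conv2$forward(imp, FALSE))
  expect_identical(diff(range(which(resp != 0))) + 1, 1 + (k - 1) * d)
})

test_that("softmax rows are probability distributions", {
  set.seed(2)
  s <- matrix(rnorm(50 * 50, sd = 4), 50)
  a <- radarecg:::softmax_rows(s)
  expect_equal(rowSums(a), rep(1, 50), tolerance = 1e-6)
  expect_true(all(a >= 0))
})

test_that("attention layer output is deterministic without dropout", {
  set.seed(3)
  mh <- radarecg:::nn_mhsa(8, 2)
  x <- array(rnorm(8 * 12 * 2), dim = c(8, 12, 2))
  expect_identical(mh$forward(x, FALSE), mh$forward(x, FALSE))
})

test_that("a saturated gate turns the feed-forward stage into identity", {
  set.seed(4)
  ffn <- radarecg:::nn_gated_ffn(6, 12)
  ffn$par$Wg2[] <- 0
  ffn$par$b2[] <- 50                     # sigmoid(50) == 1 numerically
  x <- array(rnorm(6 * 10 * 2), dim = c(6, 10, 2))
  ## reference expression: G == 1 => output equals the input exactly
  expect_equal(ffn$forward(x, FALSE), x, tolerance = 1e-12)
})

test_that("spectral attention reduces to 2x identity in the all-pass case", {
  set.seed(5)
  sa <- radarecg:::nn_sa_block(3, 100, 50, band = c(0, 26), mask_floor = 0.1)
  sa$wsa_override <- 1
  x <- array(rnorm(3 * 100 * 2), dim = c(3, 100, 2))
  y <- sa$forward(x, FALSE)
  expect_equal(y, 2 * x, tolerance = 1e-9)
  expect_true(is.numeric(y) && !is.complex(y))   # exactly real output
})

test_that("the frequency mask floors out-of-band tones and passes in-band", {
  t <- (0:999) / 100
  sa <- radarecg:::nn_sa_block(1, 1000, 100)
  sa$wsa_override <- 1
  sa$residual <- FALSE
  tone45 <- array(sin(2 * pi * 45 * t), dim = c(1, 1000, 1))
  out45 <- as.numeric(sa$forward(tone45, FALSE))
  amp <- function(x, f) {
    sp <- fft(x); 2 * Mod(sp[round(f * 10) + 1]) / length(x)
  }
  expect_equal(amp(out45, 45) / amp(as.numeric(tone45), 45), 0.1,
               tolerance = 1e-9)
  tone5 <- array(sin(2 * pi * 5 * t + 0.3), dim = c(1, 1000, 1))
  out5 <- sa$forward(tone5, FALSE)
  expect_lt(max(abs(out5 - tone5)), 1e-6)  # amplitude and phase preserved
})

test_that("the mask is evaluated on aliased bin frequencies", {
  m <- sa_frequency_mask(1000, 50, band = c(0.5, 40), floor = 0.1)
  freqs <- pmin(0:999, 1000 - (0:999)) * 50 / 1000
  expect_equal(m[freqs >= 0.5 & freqs <= 40], rep(1, sum(freqs >= 0.5 & freqs <= 40)))
  expect_equal(unique(m[freqs < 0.5 | freqs > 40]), 0.1)
  ## symmetric (m[j] == m[n - j + 2]), so filtering keeps signals real
  expect_equal(m[2:1000], rev(m[2:1000]))
})

test_that("loss functions match hand computations", {
  expect_equal(rmse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse_loss(c(2, 3, 4), c(1, 2, 3)), 1)     # constant offset
  expect_equal(rmse_loss(c(1, 2, 3), c(1, 1, 1)), sqrt(5 / 3),
               tolerance = 1e-10)
  expect_equal(round(rmse_loss(c(1, 2, 3), c(1, 1, 1)), 4), 1.291)
})

test_that("layer gradients agree with finite differences", {
  set.seed(6)
  check <- function(layer, in_dim, tol = 1e-4) {
    x <- array(rnorm(prod(in_dim)), dim = in_dim)
    y <- layer$forward(x, train = FALSE)
    gy <- array(rnorm(length(y)), dim = dim(y))
    for (nm in names(layer$par)) layer$grad[[nm]][] <- 0
    gx <- layer$backward(gy)
    f <- function(xx) sum(gy * layer$forward(xx, train = FALSE))
    for (i in sample(length(x), 5)) {
      xp <- x; xp[i] <- x[i] + 1e-6
      xm <- x; xm[i] <- x[i] - 1e-6
      num <- (f(xp) - f(xm)) / 2e-6
      expect_equal(gx[i], num, tolerance = tol * max(1, abs(num)))
    }
  }
  check(radarecg:::nn_conv1d(3, 4, 3, pad_left = 1), c(3, 16, 2))
  check(radarecg:::nn_mhsa(8, 2), c(8, 10, 2))
  check(radarecg:::nn_gated_ffn(6), c(6, 8, 2))
  check(radarecg:::nn_sa_block(2, 16, 50), c(2, 16, 2))
  check(radarecg:::nn_layernorm(5), c(5, 6, 2))
  check(radarecg:::nn_upsample2(), c(2, 8, 2))
})
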