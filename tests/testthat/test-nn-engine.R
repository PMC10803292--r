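# Finite-difference checks of the internal layers: the whole GAN/classifier
# stack rests on these gradients being exact.

num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

test_that("conv1d forward matches a direct sliding-window computation", {
  set.seed(1)
  ly <- ecglead:::nn_conv1d(2, 3, k = 4, stride = 2, pad = 1, init_sd = 0.5)
  x <- array(rnorm(2 * 9 * 2), c(2, 9, 2))
  y <- ecglead:::conv1d_fwd(ly, x, keep = FALSE)$y
  # direct computation for one output element: batch 2, channel 2, pos 3
  xp <- array(0, c(2, 11, 2)); xp[, 2:10, ] <- x
  win <- xp[, (3 - 1) * 2 + 1:4, 2]                  # (C_in, k)
  ref <- sum(ly$W[2, ] * as.vector(win)) + ly$b[2]   # rows ordered (c, j)
  expect_equal(y[2, 3, 2], ref, tolerance = 1e-12)
  expect_equal(dim(y), c(3L, 4L, 2L))                # floor((9+2-4)/2)+1
})

test_that("conv and transposed-conv gradients match finite differences", {
  set.seed(2)
  ly <- ecglead:::nn_conv1d(3, 4, 4, 2, 1, init_sd = 0.3)
  x <- array(rnorm(3 * 11 * 2), c(3, 11, 2))
  f <- ecglead:::conv1d_fwd(ly, x)
  dy <- cos(f$y)
  ecglead:::nn_zero_grad(list(ly))
  dx <- ecglead:::conv1d_bwd(ly, f$cache, dy)
  fx <- function(v) sum(sin(ecglead:::conv1d_fwd(ly, array(v, dim(x)),
                                                 keep = FALSE)$y))
  expect_lt(max(abs(dx - array(num_grad(fx, as.vector(x)), dim(x)))), 1e-7)
  W0 <- ly$W
  fW <- function(v) {
    ly$W <- matrix(v, nrow(W0))
    r <- sum(sin(ecglead:::conv1d_fwd(ly, x, keep = FALSE)$y))
    ly$W <- W0
    r
  }
  expect_lt(max(abs(ly$grad_W -
                    matrix(num_grad(fW, as.vector(W0)), nrow(W0)))), 1e-6)

  lt <- ecglead:::nn_convt1d(3, 2, 4, 2, 1, init_sd = 0.3)
  x2 <- array(rnorm(3 * 6 * 2), c(3, 6, 2))
  f2 <- ecglead:::convt1d_fwd(lt, x2)
  expect_equal(dim(f2$y), c(2L, 12L, 2L))            # (6-1)*2 - 2 + 4
  dy2 <- cos(f2$y)
  ecglead:::nn_zero_grad(list(lt))
  dx2 <- ecglead:::convt1d_bwd(lt, f2$cache, dy2)
  fx2 <- function(v) sum(sin(ecglead:::convt1d_fwd(lt, array(v, dim(x2)),
                                                   keep = FALSE)$y))
  expect_lt(max(abs(dx2 - array(num_grad(fx2, as.vector(x2)), dim(x2)))), 1e-7)
})

test_that("batch-norm gradients and running statistics behave", {
  set.seed(3)
  ly <- ecglead:::nn_bn1d(3)
  ly$gamma <- rnorm(3, 1, 0.2); ly$beta <- rnorm(3, 0, 0.2)
  x <- array(rnorm(3 * 7 * 2, 2, 3), c(3, 7, 2))
  f <- ecglead:::bn1d_fwd(ly, x, training = TRUE)
  # normalized activations have zero mean / unit variance per channel
  xm <- matrix((f$y - ly$beta) / ly$gamma, 3, 14)
  expect_lt(max(abs(rowMeans(xm))), 1e-10)
  dy <- cos(f$y)
  ecglead:::nn_zero_grad(list(ly))
  dx <- ecglead:::bn1d_bwd(ly, f$cache, dy)
  rm0 <- ly$run_mean; rv0 <- ly$run_var
  fx <- function(v) {
    ly$run_mean <- rm0; ly$run_var <- rv0
    sum(sin(ecglead:::bn1d_fwd(ly, array(v, dim(x)), training = TRUE,
                               keep = FALSE)$y))
  }
  expect_lt(max(abs(dx - array(num_grad(fx, as.vector(x)), dim(x)))), 1e-7)
  # eval mode uses running stats and is deterministic
  e1 <- ecglead:::bn1d_fwd(ly, x, training = FALSE, keep = FALSE)$y
  e2 <- ecglead:::bn1d_fwd(ly, x, training = FALSE, keep = FALSE)$y
  expect_identical(e1, e2)
})

test_that("whole-network gradients are exact end to end", {
  set.seed(4)
  cfg <- gan_config(enc_widths = c(4L, 6L), disc_widths = c(4L, 5L),
                    input_len = 16L, dropout = 0, seed = 3)
  gen <- gan_generator(cfg, "II")
  x <- array(rnorm(1 * 16 * 2), c(1, 16, 2))
  fw <- ecglead:::gen_fwd_internal(gen, x, training = TRUE,
                                   use_dropout = FALSE)
  dy <- cos(fw$y)
  ecglead:::nn_zero_grad(gen$layers)
  dx <- ecglead:::gen_bwd_internal(gen, fw$cache, dy)
  fx <- function(v) sum(sin(ecglead:::gen_fwd_internal(
    gen, array(v, dim(x)), training = TRUE, use_dropout = FALSE,
    keep = FALSE)$y))
  expect_lt(max(abs(dx - array(num_grad(fx, as.vector(x)), dim(x)))), 1e-6)

  disc <- gan_discriminator(cfg)
  y <- array(rnorm(1 * 16 * 3), c(1, 16, 3))
  x3 <- array(rnorm(1 * 16 * 3), c(1, 16, 3))
  fd <- ecglead:::disc_fwd_internal(disc, x3, y, training = TRUE)
  ds <- cos(fd$score)
  ecglead:::nn_zero_grad(disc$layers)
  din <- ecglead:::disc_bwd_internal(disc, fd$cache, ds)
  fy <- function(v) sum(sin(ecglead:::disc_fwd_internal(
    disc, x3, array(v, dim(y)), training = TRUE, keep = FALSE)$score))
  expect_lt(max(abs(din[[2]] - array(num_grad(fy, as.vector(y)), dim(y)))),
            1e-6)
})

test_that("Adam decreases a simple quadratic objective deterministically", {
  set.seed(6)
  ly <- ecglead:::nn_dense(4, 1, init_sd = 0.5)
  st <- ecglead:::nn_adam_state(list(ly))
  x <- matrix(rnorm(4 * 16), 4, 16)
  target <- matrix(colSums(x), 1, 16)
  loss0 <- NULL
  for (i in 1:200) {
    f <- ecglead:::dense_fwd(ly, x)
    r <- f$y - target
    if (i == 1) loss0 <- mean(r^2)
    ecglead:::nn_zero_grad(list(ly))
    ecglead:::dense_bwd(ly, f$cache, 2 * r / length(r))
    ecglead:::nn_adam_step(list(ly), st, 0.05)
  }
  loss1 <- mean((ecglead:::dense_fwd(ly, x, keep = FALSE)$y - target)^2)
  expect_lt(loss1, 0.01 * loss0)
})
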